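test_that("mean and peak u follow their definitions", {
  expect_equal(mean_u(rep(0.25, 40)), 0.25)
  expect_equal(mean_u(c(0.1, 0.3)), 0.2)
  set.seed(3)
  u <- runif(500)
  acc <- 0; for (x in u) acc <- acc + x # summation oracle
  expect_equal(mean_u(u), acc / 500, tolerance = 1e-12)

  # sort-and-average oracle: top ceil(0.25 * 4) = 1 value
  expect_equal(peak_u(c(0.1, 0.2, 0.3, 0.4), 0.25), 0.4)
  expect_equal(peak_u(u, 1.0), mean_u(u))
  expect_equal(peak_u(rep(0.3, 10), 0.1), 0.3)
  expect_error(mean_u(numeric(0)), class = "uvplume_empty_input")
  expect_error(peak_u(numeric(0)), class = "uvplume_empty_input")
})

test_that("peak u is monotone non-increasing in the fraction", {
  set.seed(11)
  for (i in 1:10) {
    u <- runif(sample(5:200, 1))
    ps <- vapply(c(0.1, 0.25, 0.5, 1.0), function(f) peak_u(u, f), numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
    expect_gte(peak_u(u, 0.5), mean_u(u))
  }
})

test_that("the three UV+ criteria are each necessary", {
  # all-zero pixel: fails the 3% UV-band criterion
  expect_false(uv_plus_pixel(0, 0, 0))
  # flat pixel: UV band equals, does not exceed, the visible minimum
  expect_false(uv_plus_pixel(0.10, 0.10, 0.10 / 0.99))
  # strong white-relative catch but no UV band
  expect_false(uv_plus_pixel(0.02, 0.01, 0.5))
  # genuine UV-yellow pixel passes all three
  expect_true(uv_plus_pixel(0.25, 0.08, 0.3))
})

test_that("UV+ flags on camera pixels agree with spectrum-level criteria", {
  w <- fixture_world()
  cal <- make_calibration(w, n = 250, seed = 5)
  mod <- fit_mapping(cal$channels, cal$catches)
  mk_pixel <- function(spec) {
    white <- camera_response(rep(1, 81), w)
    px <- tibble::as_tibble(as.list(camera_response(spec, w) / white))
    names(px) <- colnames(w$camera)
    px
  }
  # uv_plus_yellow: all three criteria hold by quadrature on the true spectrum
  s <- make_spectrum("uv_plus_yellow", w, uv = 0.3, vis = 0.5)
  u_rel <- quantum_catch(s, w)["u"] / quantum_catch(rep(1, 81), w)["u"]
  uv_band <- mean(s[w$wl <= 400])
  expect_true(u_rel > 0.05 && uv_band > 0.03 && uv_band > min(s[w$wl > 400]))
  expect_true(uv_plus_flags(mk_pixel(s), mod))
  # flat grey: no UV peak
  expect_false(uv_plus_flags(mk_pixel(make_spectrum("flat", w, level = 0.1)), mod))
  # carotenoid: long-wavelength colour without UV
  expect_false(uv_plus_flags(mk_pixel(make_spectrum("carotenoid", w, level = 0.5)),
                             mod))
})

test_that("presence thresholds are strict and monotone", {
  flags26 <- c(rep(TRUE, 26), rep(FALSE, 474))
  expect_equal(uv_plus_presence(flags26, 0.05),
               list(fraction = 0.052, present = TRUE))
  expect_false(uv_plus_presence(flags26, 0.10)$present)

  flags25 <- c(rep(TRUE, 25), rep(FALSE, 475))
  expect_equal(uv_plus_presence(flags25, 0.05)$fraction, 0.05)
  expect_false(uv_plus_presence(flags25, 0.05)$present) # strict >

  none <- rep(FALSE, 500)
  for (th in c(0.01, 0.05, 0.10)) {
    expect_equal(uv_plus_presence(none, th), list(fraction = 0, present = FALSE))
  }
  # monotone: present at 10% implies present at 5% implies present at 1%
  set.seed(21)
  for (i in 1:20) {
    fl <- runif(500) < runif(1, 0, 0.2)
    pres <- vapply(c(0.01, 0.05, 0.10), function(th)
      uv_plus_presence(fl, th)$present, logical(1))
    expect_true(all(diff(as.integer(pres)) <= 0))
  }
})

test_that("species aggregation averages specimens and drops side views", {
  rec <- tibble::tibble(
    species = c("sp1", "sp1", "sp1", "sp2"),
    sex = c("M", "M", "M", "F"),
    view = c("back", "back", "side", "belly"),
    mean_u = c(0.2, 0.4, 0.9, 0.3),
    uv_plus_present = c(TRUE, FALSE, TRUE, TRUE)
  )
  out <- species_aggregate(rec)
  expect_equal(sort(unique(out$view)), c("back", "belly"))
  row1 <- out[out$species == "sp1", ]
  expect_equal(row1$mean_u, 0.3) # side view excluded from the average
  expect_true(row1$uv_plus_present) # 1/2 specimens flagged: tie counts present
  row2 <- out[out$species == "sp2", ]
  expect_equal(row2$mean_u, 0.3)
  expect_equal(row2$n_specimens, 1L)
})
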