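chan_names <- c("visR", "visG", "visB", "uvR", "uvB")

test_that("grey-standard normalisation recovers nominal reflectances", {
  img <- fixture_image() # noise-free, gain 1.4
  nrm <- normalize_image(img)
  for (i in 1:5) {
    s <- img$standards[i, ]
    for (ch in chan_names) {
      reg <- nrm$channels[[ch]][s$row0:s$row1, s$col0:s$col1]
      expect_equal(mean(reg), s$nominal, tolerance = 1e-9)
    }
  }
})

test_that("normalisation cancels a global lighting gain", {
  w <- fixture_world()
  for (g in c(0.5, 1.0, 1.7, 2.0)) {
    img <- make_specimen_image(w, gain = g, noise_sd = 0, seed = 2)
    nrm <- normalize_image(img)
    ref <- normalize_image(fixture_image())
    for (ch in chan_names) {
      expect_lt(max(abs(nrm$channels[[ch]] - ref$channels[[ch]])), 1e-9)
    }
  }
})

test_that("non-monotone standard intensities are rejected", {
  img <- fixture_image()
  broken <- img
  s2 <- img$standards[2, ]; s3 <- img$standards[3, ]
  for (ch in chan_names) { # swap standards 2 and 3 in place
    m <- broken$channels[[ch]]
    tmp <- m[s2$row0:s2$row1, s2$col0:s2$col1]
    m[s2$row0:s2$row1, s2$col0:s2$col1] <- m[s3$row0:s3$row1, s3$col0:s3$col1]
    m[s3$row0:s3$row1, s3$col0:s3$col1] <- tmp
    broken$channels[[ch]] <- m
  }
  expect_error(normalize_image(broken), class = "uvplume_standard_order_error")
})

test_that("polynomial mapping reaches high accuracy and nests the linear case", {
  w <- fixture_world()
  cal <- make_calibration(w, n = 250, seed = 5)
  mod <- fit_mapping(cal$channels, cal$catches)
  expect_true(all(mod$r_squared > 0.99))

  # targets exactly linear in channels: R^2 = 1 to machine precision
  lin <- cal$channels %*% matrix(runif(20), 5, 4) + 0.3
  colnames(lin) <- c("u", "s", "m", "l")
  mlin <- fit_mapping(cal$channels, lin)
  expect_true(all(mlin$r_squared > 1 - 1e-10))

  # duplicating calibration rows leaves OLS coefficients unchanged
  m2 <- fit_mapping(rbind(cal$channels, cal$channels),
                    rbind(cal$catches, cal$catches))
  expect_equal(m2$coef, mod$coef, tolerance = 1e-8)

  # rank-deficient design (constant channel) is refused
  const_ch <- cal$channels; const_ch[, "uvB"] <- 0.5
  expect_error(fit_mapping(const_ch, cal$catches), class = "uvplume_singular_fit")
  expect_error(fit_mapping(cal$channels[1:40, ], cal$catches[1:40, ]),
               class = "uvplume_singular_fit")
})

test_that("applied mapping renormalises and tracks the quadrature oracle", {
  w <- fixture_world()
  cal <- make_calibration(w, n = 250, seed = 5)
  mod <- fit_mapping(cal$channels, cal$catches)
  pred <- apply_mapping(mod, cal$channels)
  expect_equal(unname(rowSums(pred$rel)), rep(1, 250), tolerance = 1e-12)

  # accuracy against the oracle-computed relative catches: tight for the
  # plumage-bright majority, bounded overall (relative error is amplified for
  # dim spectra whose u catch is only weakly constrained by the camera)
  err <- apply(abs(pred$rel - cal$catches_rel), 1, max)
  expect_gt(mean(err < 0.02), 0.80)
  expect_lt(stats::quantile(err, 0.95), 0.06)
  expect_lt(max(err), 0.25)

  # raw-scale bookkeeping: error at any training point is bounded by the
  # recorded worst training residual
  for (j in 1:4) {
    expect_lte(max(abs(pred$raw[, j] - cal$catches[, j])),
               mod$max_abs_residual[j] + 1e-12)
  }
})

test_that("sub-1% reflectance pixels are re-cited to the achromatic centre", {
  ch <- matrix(c(rep(0.005, 5), rep(0.5, 5), rep(0.01, 5)), 3, 5, byrow = TRUE,
               dimnames = list(NULL, chan_names))
  catches <- matrix(c(0.7, 0.1, 0.1, 0.1), 3, 4, byrow = TRUE,
                    dimnames = list(NULL, c("u", "s", "m", "l")))
  out <- recite_achromatic(ch, catches)
  expect_equal(unname(out$rel[1, ]), rep(0.25, 4)) # 0.5% -> achromatic
  expect_equal(unname(out$rel[2, ]), c(0.7, 0.1, 0.1, 0.1)) # bright: untouched
  expect_equal(unname(out$rel[3, ]), c(0.7, 0.1, 0.1, 0.1)) # exactly 1%: strict <
  expect_equal(out$n_recited, 1L)
})

test_that("aggregation picks the largest factor keeping enough cells", {
  w <- fixture_world()
  ch <- lapply(chan_names, function(x) matrix(runif(10000), 100, 100))
  names(ch) <- chan_names
  mask <- matrix(TRUE, 100, 100)
  s <- aggregate_and_sample(ch, mask, target = 500, seed = 1)
  # oracle: enumerate valid cell counts for every factor
  cells <- vapply(1:100, function(f) ceiling(100 / f)^2, numeric(1))
  expect_equal(attr(s, "factor"), max(which(cells >= 500)))
  expect_equal(attr(s, "factor"), 4) # 25^2 = 625 >= 500; 20^2 = 400 misses
  expect_equal(nrow(s), 500)
  # block means match a direct recomputation for a spot-checked cell
  cell <- s[17, ]
  rows <- cell$block_row * 4 + 1:4; cols <- cell$block_col * 4 + 1:4
  expect_equal(cell$visR, mean(ch$visR[rows, cols]))
})

test_that("aggregation handles exact-size, deterministic and short samples", {
  ch <- lapply(chan_names, function(x) matrix(runif(900), 30, 30))
  names(ch) <- chan_names
  mask <- matrix(FALSE, 30, 30)
  mask[1:25, 1:20] <- TRUE # exactly 500 plumage pixels
  s <- aggregate_and_sample(ch, mask, target = 500, seed = 3)
  expect_equal(attr(s, "factor"), 1)
  expect_equal(nrow(s), 500)

  s2 <- aggregate_and_sample(ch, mask, target = 500, seed = 3)
  expect_identical(s, s2) # same seed, same sample

  small <- matrix(FALSE, 30, 30); small[1:10, 1:10] <- TRUE
  expect_warning(s3 <- aggregate_and_sample(ch, small, target = 500, seed = 1),
                 class = "uvplume_short_sample")
  expect_equal(nrow(s3), 100)
  expect_lte(nrow(s3), 500)
})

test_that("end-to-end cone catches match the generating spectra on clean images", {
  w <- fixture_world()
  img <- fixture_image()
  cal <- make_calibration(w, n = 250, seed = 5)
  mod <- fit_mapping(cal$channels, cal$catches)
  nrm <- normalize_image(img)
  s <- aggregate_and_sample(nrm, img$truth_mask, seed = 9)
  stopifnot(attr(s, "factor") == 1) # cells are single pixels here
  rows <- range(which(rowSums(img$truth_mask) > 0))
  cols <- range(which(colSums(img$truth_mask) > 0))
  reg <- img$region_id[cbind(rows[1] + s$block_row, cols[1] + s$block_col)]
  catches <- apply_mapping(mod, as.matrix(s[chan_names]))
  tru <- t(vapply(img$spectra_table, true_cone_catch, numeric(4), world = w))
  err_u <- abs(catches$rel[, "u"] - tru[reg, "u"])
  expect_gt(mean(err_u < 0.02), 0.95)
})
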