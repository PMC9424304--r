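# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# shared fixtures (built once per test run)
fixture_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- make_world(1)
    w
  }
})

fixture_image <- local({
  img <- NULL
  function() {
    if (is.null(img)) {
      img <<- make_specimen_image(fixture_world(), gain = 1.4,
                                  noise_sd = 0, seed = 2)
    }
    img
  }
})

# random star-shaped (hence simple) polygons with continuous vertices, so a
# pixel centre landing exactly on an edge or vertex (where fill conventions
# could differ) has probability zero
random_simple_polys <- function(nr, nc, npoly) {
  label_polygon_set(lapply(seq_len(npoly), function(i) {
    nv <- sample(3:7, 1)
    x <- runif(nv, 0, nc)
    y <- runif(nv, 0, nr)
    ord <- order(atan2(y - mean(y), x - mean(x))) # sort by angle: simple
    list(class = sample(c("plumage", "non_plumage"), 1, prob = c(0.7, 0.3)),
         xy = cbind(x[ord], y[ord]))
  }))
}

# even-odd crossing-number point-in-polygon test, one point at a time
oracle_point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# rasterise a label polygon set by looping over every pixel centre
oracle_polygons_to_mask <- function(polys, shape) {
  nr <- shape[1]; nc <- shape[2]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      px <- j - 0.5; py <- i - 0.5
      in_plum <- FALSE; in_hole <- FALSE
      for (p in polys$polygons) {
        hit <- oracle_point_in_polygon(px, py, p$xy)
        if (p$class == "plumage") in_plum <- in_plum || hit
        else in_hole <- in_hole || hit
      }
      out[i, j] <- in_plum && !in_hole
    }
  }
  out
}

# per-pixel loop confusion tally
oracle_confusion <- function(pred, truth) {
  p_ii <- 0L; p_ij <- 0L; p_ji <- 0L; p_jj <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] && truth[k]) p_ii <- p_ii + 1L
    else if (!pred[k] && truth[k]) p_ij <- p_ij + 1L
    else if (pred[k] && !truth[k]) p_ji <- p_ji + 1L
    else p_jj <- p_jj + 1L
  }
  list(p_ii = p_ii, p_ij = p_ij, p_ji = p_ji, p_jj = p_jj)
}

# direct (non-separable) 2-D convolution with reflective borders
oracle_gauss_conv <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + K[di + r + 1, dj + r + 1] *
            m[refl(i + di, nr), refl(j + dj, nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# flood fill over 4-neighbours on an inclusion predicate matrix
oracle_flood_fill <- function(ok, seed_rc) {
  nr <- nrow(ok); nc <- ncol(ok)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(seed_rc)
  while (length(stack)) {
    rc <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    r <- rc[1]; c <- rc[2]
    if (r < 1 || r > nr || c < 1 || c > nc || seen[r, c] || !ok[r, c]) next
    seen[r, c] <- TRUE
    stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
  }
  seen
}

# midpoint-rule quadrature on the world grid, written as an explicit loop
oracle_band_integral <- function(f, world, lo = -Inf, hi = Inf) {
  acc <- 0
  for (i in seq_along(world$wl)) {
    if (world$wl[i] >= lo && world$wl[i] <= hi) acc <- acc + f[i] * world$delta
  }
  acc
}

# plain Bayesian probit regression by data augmentation (no phylo term):
# the reduced-scale independent implementation the binary sampler is checked
# against
oracle_probit_gibbs <- function(y, X, n_iter = 4000, burn = 500, seed = 1) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  R <- chol(XtXi)
  beta <- numeric(p)
  out <- matrix(NA_real_, n_iter - burn, p)
  for (it in seq_len(n_iter)) {
    mu <- drop(X %*% beta)
    pr <- pnorm(-mu)
    u <- runif(n)
    pq <- ifelse(y == 1, pr + u * (1 - pr), u * pr)
    z <- mu + qnorm(pmin(pmax(pq, 1e-12), 1 - 1e-12))
    bhat <- drop(XtXi %*% crossprod(X, z))
    beta <- bhat + drop(t(R) %*% rnorm(p)) # N(bhat, (X'X)^-1)
    if (it > burn) out[it - burn, ] <- beta
  }
  out
}
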