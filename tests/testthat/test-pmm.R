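test_that("phylogenetic correlation matrix has the right geometry", {
  # star tree: no shared paths, identity matrix
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, 6)
  expect_equal(unname(phylo_correlation(star)), diag(6))

  # two sisters splitting at height 0.5 of a unit-height three-tip tree
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  A <- phylo_correlation(tr)
  expect_equal(A["a", "b"], 0.5)
  expect_equal(A["a", "c"], 0)
  expect_equal(diag(A), c(a = 1, b = 1, c = 1))

  # any generated tree: positive semi-definite
  set.seed(13)
  for (i in 1:5) {
    tr <- ape::rphylo(sample(10:60, 1), 1, 0)
    expect_gte(min(eigen(phylo_correlation(tr), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("response preparation transforms and standardises as specified", {
  tab <- tibble::tibble(
    mean_u = c(0.01, 0.1, 1, 0.5, 0.2, 0.09),
    uv_plus_present = c(1, 0, 1, 1, 0, 0),
    uvb = rnorm(6), forest = c(0, 1, 0, 1, 1, 0)
  )
  prep <- prepare_response(tab, "mean_u", c("uvb", "forest"))
  expect_false(prep$binary)
  expect_equal(mean(prep$y), 0, tolerance = 1e-12)
  expect_equal(sd(prep$y), 1, tolerance = 1e-12)
  # log10 is applied before standardisation: {0.01, 0.1, 1} map to {-2, -1, 0}
  l10 <- log10(tab$mean_u)
  expect_equal(prep$y, (l10 - mean(l10)) / sd(l10), tolerance = 1e-12)
  expect_equal(colnames(prep$X), c("(Intercept)", "uvb", "forest"))
  expect_equal(unname(colMeans(prep$X[, 2:3])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(prep$X[, 2:3], 2, sd)), c(1, 1), tolerance = 1e-12)

  prep_b <- prepare_response(tab, "uv_plus_present")
  expect_true(prep_b$binary)
  expect_equal(prep_b$y, tab$uv_plus_present) # passes through untouched

  tab$mean_u[2] <- 0
  expect_error(prepare_response(tab, "mean_u"), class = "uvplume_transform_error")
})

test_that("gaussian sampler matches the conjugate regression posterior when A is inert", {
  set.seed(42)
  n <- 20
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- drop(X %*% c(1, -0.5)) + rnorm(n, 0, 0.7)
  fit <- fit_pmm_gaussian(
    y, X, diag(n),
    prior = pmm_prior(phylo_V = 1e-10, phylo_fix = TRUE),
    chain = chain_settings(6000, 1, 1000, seed = 7))
  # with a ~ 0, beta | y is multivariate t around the OLS solution
  bhat <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% bhat)^2) / (n - 2)
  se <- sqrt(s2 * diag(solve(crossprod(X))))
  for (j in 1:2) {
    z <- (fit$beta[, j] - bhat[j]) / se[j]
    expect_lt(suppressWarnings(ks.test(z, pt, df = n - 2)$statistic), 0.05)
  }
})

test_that("draw bookkeeping and degenerate fits behave", {
  set.seed(1)
  n <- 30
  A <- phylo_correlation(ape::rphylo(n, 1, 0))
  ch <- chain_settings(2000, 10, 500, seed = 2)
  fit <- fit_pmm_gaussian(rnorm(n), cbind("(Intercept)" = rep(1, n)), A,
                          chain = ch)
  expect_equal(length(fit$sigma2_a), (2000 - 500) / 10)
  expect_true(all(fit$sigma2_a > 0) && all(fit$sigma2_e > 0))

  # y identically 0 with the residual fixed: phylogenetic variance collapses
  # towards its prior floor
  fit0 <- fit_pmm_gaussian(rep(0, n), cbind("(Intercept)" = rep(1, n)), A,
                           prior = pmm_prior(residual_fix = TRUE,
                                             residual_V = 1),
                           chain = ch)
  expect_lt(median(fit0$sigma2_a), 0.1)

  # unbalanced designs are refused by the balanced fast path
  expect_error(
    fit_pmm_gaussian(rnorm(4), cbind(rep(1, 4)),
                     phylo_correlation(ape::rphylo(10, 1, 0)),
                     species = c(1L, 1L, 2L, 3L)),
    class = "uvplume_spec_error")
  # unknown tip labels are a label error
  expect_error(
    fit_pmm_gaussian(rnorm(n), cbind(rep(1, n)), A,
                     species = rep("nope", n)),
    class = "uvplume_label_error")
})

test_that("probit sampler matches an independent plain-probit implementation", {
  set.seed(8)
  n <- 150
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- as.integer(drop(X %*% c(0.3, 1)) + rnorm(n) > 0)
  fit <- fit_pmm_binary(
    y, X, diag(n),
    prior = pmm_prior(residual_fix = TRUE, phylo_V = 1e-10, phylo_fix = TRUE),
    chain = chain_settings(5000, 1, 1000, seed = 3))
  ref <- oracle_probit_gibbs(y, X, n_iter = 6000, burn = 1000, seed = 4)
  for (j in 1:2) {
    expect_equal(mean(fit$beta[, j]), mean(ref[, j]), tolerance = 0.12)
    expect_equal(sd(fit$beta[, j]), sd(ref[, j]), tolerance = 0.35)
  }
})

test_that("probit sampler flags separation and requires a fixed residual", {
  n <- 40
  A <- diag(n)
  X <- cbind("(Intercept)" = 1, x = c(rep(-1, 20), rep(1, 20)))
  y <- as.integer(X[, "x"] > 0) # x separates y perfectly
  expect_warning(
    fit_pmm_binary(y, X, A, chain = chain_settings(200, 1, 100, seed = 1)),
    class = "uvplume_separation")
  expect_warning(
    fit_pmm_binary(rep(1, n), X, A, chain = chain_settings(200, 1, 100, seed = 1)),
    class = "uvplume_separation")
  expect_error(fit_pmm_binary(y, X, A, prior = pmm_prior()),
               class = "uvplume_spec_error")
})

test_that("heritability estimates respond to the tree structure", {
  # equal variance draws: H2 exactly one half
  fake <- structure(list(beta = matrix(0, 100, 1), sigma2_a = rep(2, 100),
                         sigma2_e = rep(2, 100), tree_id = rep(1, 100),
                         family = "gaussian", n = 10), class = "pmm_draws")
  h <- estimate_H2(fake)
  expect_equal(h$median, 0.5)
  expect_equal(unname(h$ci), c(0.5, 0.5))

  # strongly heritable data on a real tree
  d <- make_comparative_dataset(150, sigma2_a = 0.8, sigma2_e = 0.2, seed = 5)
  A <- phylo_correlation(d$tree)
  f <- fit_pmm_gaussian(d$traits$y, cbind("(Intercept)" = rep(1, 150)), A,
                        species = d$traits$species,
                        chain = chain_settings(seed = 6))
  expect_equal(estimate_H2(f)$median, 0.8, tolerance = 0.15)

  # the same trait sizes on a star tree carry no phylogenetic signal
  star <- ape::stree(150, type = "star"); star$edge.length <- rep(1, 150)
  Astar <- phylo_correlation(star)
  set.seed(7)
  fstar <- fit_pmm_gaussian(rnorm(150), cbind("(Intercept)" = rep(1, 150)),
                            Astar, chain = chain_settings(seed = 8))
  expect_lt(estimate_H2(fstar)$median, 0.2)
})

test_that("pooling concatenates draws and is order-invariant", {
  mk <- function(val, k, id) structure(
    list(beta = matrix(val, k, 1, dimnames = list(NULL, "(Intercept)")),
         sigma2_a = rep(val, k), sigma2_e = rep(1, k), tree_id = rep(id, k),
         family = "gaussian", chain = chain_settings(), n = 10),
    class = "pmm_draws")
  a <- mk(0.3, 50, 1); b <- mk(0.9, 70, 2)
  pooled <- pool_over_trees(list(a, b))
  expect_equal(length(pooled$sigma2_a), 120)
  expect_equal(summary(pool_over_trees(list(a, a)))$median,
               summary(a)$median)
  # order invariance of summaries
  p1 <- summary(pool_over_trees(list(a, b)))
  p2 <- summary(pool_over_trees(list(b, a)))
  expect_equal(p1$median, p2$median)
  # pooled CI at least as wide as the narrowest per-tree CI
  w_pooled <- p1$upper - p1$lower
  w_each <- pmin(summary(a)$upper - summary(a)$lower,
                 summary(b)$upper - summary(b)$lower)
  expect_true(all(w_pooled >= w_each - 1e-12))
  # mismatched specifications are refused
  c_bad <- mk(0.3, 10, 3); colnames(c_bad$beta) <- "slope"
  expect_error(pool_over_trees(list(a, c_bad)), class = "uvplume_spec_error")
})

test_that("marginal and conditional R2 partition the posterior variance", {
  k <- 200
  X <- cbind("(Intercept)" = 1, x = rnorm(50))
  zero <- structure(list(beta = matrix(0, k, 2), sigma2_a = rep(1, k),
                         sigma2_e = rep(1, k), tree_id = rep(1, k),
                         family = "gaussian", n = 50), class = "pmm_draws")
  r0 <- r2_marginal_conditional(zero, X)
  expect_equal(unique(r0$marginal), 0)
  expect_equal(unique(r0$conditional), 0.5)

  nophylo <- zero; nophylo$sigma2_a <- rep(0, k)
  rn <- r2_marginal_conditional(nophylo, X)
  expect_equal(rn$marginal, rn$conditional)

  # known partition var_f = 1, s2a = 1, s2e = 2 -> R2m = 0.25, R2c = 0.5;
  # averaged over replicate simulations to tame posterior sampling noise
  meds <- vapply(1:4, function(i) {
    d <- make_comparative_dataset(200, beta = c(uvb = 1), sigma2_a = 1,
                                  sigma2_e = 2, seed = 30 + i)
    A <- phylo_correlation(d$tree)
    X2 <- cbind("(Intercept)" = 1, uvb = d$traits$uvb)
    f <- fit_pmm_gaussian(d$traits$y, X2, A, species = d$traits$species,
                          chain = chain_settings(seed = 130 + i))
    r <- r2_marginal_conditional(f, X2)
    c(median(r$marginal), median(r$conditional))
  }, numeric(2))
  expect_lt(abs(mean(meds[1, ]) - 0.25), 0.08)
  expect_lt(abs(mean(meds[2, ]) - 0.50), 0.10)
})
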