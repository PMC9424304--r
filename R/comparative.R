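#' Simulate a comparative dataset on a phylogeny
#'
#' Generates the inputs of the phylogenetic mixed models: a pure-birth tree
#' scaled to unit height, standardised ecological predictors, and a response
#' built as `y = X beta + a + e` with phylogenetic effects
#' `a ~ N(0, sigma2_a * A)` (A the shared-path correlation matrix under
#' Brownian motion) and iid residuals `e ~ N(0, sigma2_e)`. With
#' `binary = TRUE` the observed response is `as.integer(latent > 0)` and
#' `sigma2_e` is fixed at 1 (probit scale).
#'
#' Predictors mirror the ecological covariates of interest for UV plumage:
#' annual UVB irradiance, mean temperature and solar radiation (correlated
#' continuous variables), forest dependency (binary), foraging stratum index,
#' and visual system (UVS vs VS, binary). All are standardised to mean 0,
#' sd 1. Optionally each species is expanded to sex x view rows (back/belly,
#' M/F) sharing one phylogenetic effect, matching an observation-level layout
#' where sex and view enter as fixed effects.
#'
#' @param n_species number of tips (>= 10)
#' @param beta named numeric vector of fixed effects over
#'   `c("(Intercept)", predictors...)`; missing names get 0. Use NULL for an
#'   intercept-only model with intercept 0.
#' @param sigma2_a phylogenetic variance (>= 0)
#' @param sigma2_e residual variance (>= 0; forced to 1 when `binary`)
#' @param binary threshold the latent response at 0 into presence/absence?
#' @param expand_sex_view expand each species into 4 rows (M/F x back/belly)?
#' @param tree optional `phylo` to simulate on (rescaled to unit height);
#'   default NULL simulates a fresh pure-birth tree
#' @param seed integer seed
#' @return list of class `comparative_dataset`: `tree` (ape phylo, unit
#'   height), `traits` (tibble with species, predictors, response `y`),
#'   `true_params` (beta, sigma2_a, sigma2_e, h2)
#' @export
make_comparative_dataset <- function(n_species, beta = NULL,
                                     sigma2_a = 0.5, sigma2_e = 0.5,
                                     binary = FALSE,
                                     expand_sex_view = FALSE,
                                     tree = NULL,
                                     seed = 1L) {
  stopifnot(n_species >= 10, sigma2_a >= 0, sigma2_e >= 0)
  if (binary) sigma2_e <- 1
  set.seed(as.integer(seed))

  if (is.null(tree)) {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
  } else {
    stopifnot(inherits(tree, "phylo"), length(tree$tip.label) == n_species)
  }
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  A <- phylo_correlation(tree)
  sp <- tree$tip.label

  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  base_env <- stats::rnorm(n_species)           # latitude-like driver
  traits <- tibble::tibble(
    species = sp,
    uvb = std(0.8 * base_env + 0.6 * stats::rnorm(n_species)),
    temperature = std(0.7 * base_env + 0.7 * stats::rnorm(n_species)),
    solar = std(0.6 * base_env + 0.8 * stats::rnorm(n_species)),
    forest = std(stats::rbinom(n_species, 1, 0.5)),
    strata = std(stats::runif(n_species)),
    visual_system = std(stats::rbinom(n_species, 1, 0.4))
  )
  if (expand_sex_view) {
    grid <- expand.grid(sex = c("M", "F"), view = c("back", "belly"),
                        stringsAsFactors = FALSE)
    traits <- traits[rep(seq_len(n_species), each = nrow(grid)), ]
    traits$sex <- std(rep(as.integer(grid$sex == "M"), n_species))
    traits$view <- std(rep(as.integer(grid$view == "back"), n_species))
  }

  pred_names <- setdiff(names(traits), "species")
  X <- cbind("(Intercept)" = 1, as.matrix(traits[pred_names]))
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(beta)) {
    if (is.null(names(beta))) {
      uvp_stop("spec_error", "beta must be a named vector")
    }
    bad <- setdiff(names(beta), colnames(X))
    if (length(bad)) {
      uvp_stop("spec_error", paste("unknown beta names:",
                                   paste(bad, collapse = ", ")))
    }
    b[names(beta)] <- beta
  }

  a_sp <- if (sigma2_a > 0) {
    drop(MASS::mvrnorm(1, rep(0, n_species), sigma2_a * A))
  } else rep(0, n_species)
  names(a_sp) <- sp
  a <- a_sp[traits$species]
  e <- stats::rnorm(nrow(traits), 0, sqrt(sigma2_e))
  latent <- drop(X %*% b) + a + e
  traits$y <- if (binary) as.integer(latent > 0) else latent

  structure(list(
    tree = tree, traits = traits,
    true_params = list(beta = b, sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                       h2 = if (sigma2_a + sigma2_e > 0)
                         sigma2_a / (sigma2_a + sigma2_e) else NA_real_),
    binary = binary, seed = as.integer(seed)
  ), class = "comparative_dataset")
}
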