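#' Grey-standard normalisation
#'
#' Removes lighting variation using the five grey standards photographed in
#' every image. Per channel, the nominal reflectances (0.02, 0.40, 0.60, 0.80,
#' 0.99) are regressed by ordinary least squares on the mean pixel intensity
#' of each standard region, and the fitted line is applied to every pixel,
#' expressing intensities as dimensionless reflectance proportions
#' (1.0 = 100%-standard-equivalent). Multiplying the whole image by a common
#' lighting gain leaves the output unchanged.
#'
#' @param image a `specimen_image` (needs `channels` + `standards`)
#' @return object of class `normalized_pixels`: list with `channels` (named
#'   list of 5 reflectance matrices), `fit` (per-channel intercept/slope),
#'   `standard_means` (5 x 5 matrix: standard x channel)
#' @export
normalize_image <- function(image) {
  std <- image$standards
  stopifnot(nrow(std) == 5)
  nominal <- std$nominal
  means <- vapply(names(image$channels), function(ch) {
    m <- image$channels[[ch]]
    vapply(seq_len(5), function(i) {
      reg <- m[std$row0[i]:std$row1[i], std$col0[i]:std$col1[i]]
      if (length(reg) < 4) {
        uvp_stop("standard_order_error", "standard region smaller than 4 pixels")
      }
      mean(reg)
    }, numeric(1))
  }, numeric(5))
  # lighting must make brighter standards brighter in every channel
  if (any(apply(means, 2, function(x) any(diff(x) <= 0)))) {
    uvp_stop("standard_order_error",
             "standard mean intensities not increasing with nominal reflectance")
  }
  fit <- apply(means, 2, function(x) stats::coef(stats::lm(nominal ~ x)))
  rownames(fit) <- c("intercept", "slope")
  channels <- lapply(names(image$channels), function(ch) {
    fit["intercept", ch] + fit["slope", ch] * image$channels[[ch]]
  })
  names(channels) <- names(image$channels)
  structure(list(channels = channels, fit = fit, standard_means = means),
            class = "normalized_pixels")
}

#' Polynomial basis over the five camera channels
#'
#' Intercept, each channel, each squared channel, each pairwise product and
#' each three-way product of distinct channels (31 terms for 5 channels).
#' @param channels n x 5 numeric matrix
#' @return n x 31 design matrix with named columns
#' @noRd
poly_basis <- function(channels) {
  ch <- colnames(channels)
  stopifnot(!is.null(ch))
  out <- list("(Intercept)" = rep(1, nrow(channels)))
  for (i in seq_along(ch)) out[[ch[i]]] <- channels[, i]
  for (i in seq_along(ch)) out[[paste0(ch[i], "^2")]] <- channels[, i]^2
  cmb2 <- utils::combn(seq_along(ch), 2)
  for (k in seq_len(ncol(cmb2))) {
    i <- cmb2[1, k]; j <- cmb2[2, k]
    out[[paste(ch[i], ch[j], sep = ":")]] <- channels[, i] * channels[, j]
  }
  cmb3 <- utils::combn(seq_along(ch), 3)
  for (k in seq_len(ncol(cmb3))) {
    i <- cmb3[1, k]; j <- cmb3[2, k]; l <- cmb3[3, k]
    out[[paste(ch[i], ch[j], ch[l], sep = ":")]] <-
      channels[, i] * channels[, j] * channels[, l]
  }
  do.call(cbind, out)
}

#' Fit the cone-catch mapping functions
#'
#' Least-squares mapping from normalised camera channels to relative cone
#' catches, one model per receptor, over a polynomial basis with second-order
#' terms and three-way interactions between channels. The camera has no
#' usable UV green channel, so none enters the basis. On well-spread
#' calibration sets the fits reach R-squared above 0.99 for all four
#' receptors.
#'
#' @param channels n x 5 matrix of normalised channel reflectances
#' @param catches n x 4 matrix of true relative cone catches (u, s, m, l)
#' @return object of class `mapping_model`: `coef` (31 x 4), `r_squared`
#'   (named, per receptor), `max_abs_residual`
#' @export
fit_mapping <- function(channels, catches) {
  B <- poly_basis(channels)
  if (nrow(B) < 2 * ncol(B)) {
    uvp_stop("singular_fit",
             sprintf("need at least %d calibration samples for %d basis terms",
                     2 * ncol(B), ncol(B)))
  }
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    uvp_stop("singular_fit", "rank-deficient calibration design")
  }
  coefs <- qr.coef(qrB, catches)
  fitted <- B %*% coefs
  resid <- catches - fitted
  r2 <- 1 - colSums(resid^2) / colSums(sweep(catches, 2, colMeans(catches))^2)
  structure(list(coef = coefs, r_squared = r2,
                 max_abs_residual = apply(abs(resid), 2, max)),
            class = "mapping_model")
}

#' Apply a fitted cone-catch mapping to pixels
#'
#' Predicts raw catches from the polynomial per receptor, clips negatives at
#' zero and renormalises each pixel to sum to 1. Pixels whose raw catches are
#' all non-positive carry no usable chromatic signal and are re-cited to the
#' achromatic centre (0.25, 0.25, 0.25, 0.25); their count is recorded.
#'
#' @param model a `mapping_model`
#' @param channels n x 5 matrix of normalised channel reflectances
#' @return object of class `cone_catch_pixels`: `rel` (n x 4 matrix of
#'   relative catches summing to 1), `raw` (n x 4 clipped raw catches),
#'   `n_degenerate`
#' @export
apply_mapping <- function(model, channels) {
  raw <- pmax(poly_basis(channels) %*% model$coef, 0)
  tot <- rowSums(raw)
  bad <- tot <= 0
  rel <- raw
  rel[!bad, ] <- raw[!bad, , drop = FALSE] / tot[!bad]
  rel[bad, ] <- 0.25
  structure(list(rel = rel, raw = raw, n_degenerate = sum(bad)),
            class = "cone_catch_pixels")
}

#' Re-cite low-reflectance pixels to the achromatic centre
#'
#' Quantifying the colour of patches with very low overall reflectance is
#' unreliable, so any pixel whose mean normalised reflectance across the five
#' channels is strictly below `threshold` (default 1%) is assigned the
#' achromatic centre u = s = m = l = 0.25.
#'
#' @param channels n x 5 matrix of normalised channel reflectances
#' @param catches a `cone_catch_pixels` (or bare n x 4 matrix)
#' @param threshold reflectance proportion below which pixels are re-cited
#' @return `cone_catch_pixels` with re-cited rows and an `n_recited` field
#' @export
recite_achromatic <- function(channels, catches, threshold = 0.01) {
  rel <- if (inherits(catches, "cone_catch_pixels")) catches$rel else catches
  stopifnot(nrow(channels) == nrow(rel))
  low <- rowMeans(channels) < threshold
  rel[low, ] <- 0.25
  out <- if (inherits(catches, "cone_catch_pixels")) catches else
    list(rel = NULL, raw = NULL, n_degenerate = 0L)
  out$rel <- rel
  out$n_recited <- sum(low)
  structure(out, class = "cone_catch_pixels")
}

#' Block-aggregate masked pixels and sample a fixed number
#'
#' Individual pixel values are noisy and specimens differ in pixel counts, so
#' pixels are downsampled to a comparable resolution: candidate aggregation
#' factors are enumerated from 100 down to 1; for each factor `f` the mask's
#' bounding box is partitioned into `f x f` blocks (anchored top-left, partial
#' edge blocks allowed), a cell being valid if it contains at least one
#' plumage pixel, with value the mean over its plumage pixels per channel.
#' The first (largest) factor yielding at least `target` valid cells is
#' chosen — maximal denoising subject to retaining `target` cells — and
#' `target` cells are then sampled uniformly without replacement.
#'
#' @param norm a `normalized_pixels` (or named list of channel matrices)
#' @param mask logical plumage mask
#' @param target cells to sample (default 500)
#' @param factor_range integer range of candidate factors (default 1..100)
#' @param seed integer seed for the sampling step
#' @return tibble with `cell_id`, `block_row`, `block_col`, one column per
#'   channel, and attributes `factor` (chosen aggregation factor) and
#'   `n_valid_cells`; if fewer than `target` valid cells exist even at
#'   factor 1, all cells are returned with a `uvplume_short_sample` warning
#' @export
aggregate_and_sample <- function(norm, mask, target = 500L,
                                 factor_range = c(1L, 100L), seed = 1L) {
  channels <- if (inherits(norm, "normalized_pixels")) norm$channels else norm
  if (!any(mask)) uvp_stop("empty_segmentation", "mask contains no plumage pixel")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub_mask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub_ch <- lapply(channels, function(m) {
    m[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  })
  nr <- nrow(sub_mask); nc <- ncol(sub_mask)

  cells_for <- function(f) {
    br <- (row(sub_mask) - 1L) %/% f
    bc <- (col(sub_mask) - 1L) %/% f
    key <- br * (1L + (nc - 1L) %/% f) + bc
    length(unique(key[sub_mask]))
  }
  chosen <- NA_integer_
  for (f in seq(factor_range[2], factor_range[1])) {
    if (cells_for(f) >= target) { chosen <- f; break }
  }
  short <- is.na(chosen)
  if (short) chosen <- factor_range[1]

  br <- (row(sub_mask) - 1L) %/% chosen
  bc <- (col(sub_mask) - 1L) %/% chosen
  keep <- which(sub_mask)
  key <- (br * (1L + (nc - 1L) %/% chosen) + bc)[keep]
  agg <- lapply(sub_ch, function(m) {
    tapply(m[keep], key, mean)
  })
  uk <- sort(unique(key))
  tab <- tibble::tibble(
    cell_id = seq_along(uk),
    block_row = as.integer(uk %/% (1L + (nc - 1L) %/% chosen)),
    block_col = as.integer(uk %% (1L + (nc - 1L) %/% chosen))
  )
  for (ch in names(agg)) tab[[ch]] <- as.numeric(agg[[ch]][as.character(uk)])

  n_valid <- nrow(tab)
  if (short && n_valid < target) {
    uvp_warn("short_sample",
             sprintf("only %d valid cells (< %d target); returning all",
                     n_valid, target))
    out <- tab
  } else {
    set.seed(as.integer(seed))
    out <- tab[sort(sample.int(n_valid, target)), ]
  }
  attr(out, "factor") <- chosen
  attr(out, "n_valid_cells") <- n_valid
  out
}
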