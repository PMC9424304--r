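#' Mean relative UV cone catch
#'
#' Arithmetic mean of u across sampled plumage pixels: the average UV
#' reflectance of the whole plumage.
#'
#' @param u numeric vector of relative u catches (or a `cone_catch_pixels`)
#' @return proportion
#' @export
mean_u <- function(u) {
  u <- as_u(u)
  if (length(u) == 0) uvp_stop("empty_input", "no pixels")
  mean(u)
}

as_u <- function(u) {
  if (inherits(u, "cone_catch_pixels")) u <- u$rel[, "u"]
  as.numeric(u)
}

#' Peak relative UV cone catch
#'
#' Mean of the largest `ceil(fraction * n)` u values — sensitive to small,
#' strongly UV-reflective patches that the whole-plumage mean dilutes. The
#' default upper quarter (fraction 0.25) is bracketed by 0.50 and 0.10 in
#' sensitivity analyses. `peak_u(u, 1)` equals `mean_u(u)`.
#'
#' @param u numeric vector of relative u catches (or a `cone_catch_pixels`)
#' @param fraction upper fraction of pixels to average, in (0, 1]
#' @return proportion
#' @export
peak_u <- function(u, fraction = 0.25) {
  u <- as_u(u)
  if (length(u) == 0) uvp_stop("empty_input", "no pixels")
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(u))
  mean(sort(u, decreasing = TRUE)[seq_len(k)])
}

#' UV+ colouration test per pixel
#'
#' A pixel shows UV+ colouration — a detectable UV reflectance peak possibly
#' combined with other colours (UV-yellow, UV-red) — iff all three criteria
#' hold:
#' 1. its u quantum catch exceeds 0.05 of the u catch of a theoretical 100%
#'    white standard;
#' 2. its UV-band (300--400 nm) reflectance exceeds 3%;
#' 3. its UV-band reflectance exceeds the minimum reflectance over the
#'    visible range (400--700 nm) — so UV peaks count even when reflectance
#'    at other wavelengths dominates.
#'
#' In camera space the UV band is the mean of the two normalised UV channels
#' and the visible minimum is the minimum over the three normalised visible
#' channels.
#'
#' @param uv_band mean UV-band reflectance per pixel (proportion)
#' @param vis_min minimum visible-band reflectance per pixel (proportion)
#' @param u_rel_white u quantum catch relative to a 100% white standard
#' @return logical vector of UV+ flags
#' @export
uv_plus_pixel <- function(uv_band, vis_min, u_rel_white) {
  # strict inequality, with an epsilon guard so exact ties (a perfectly flat
  # pixel) never flip on floating-point noise
  u_rel_white > 0.05 & uv_band > 0.03 & (uv_band - vis_min) > 1e-9
}

#' UV+ flags for a sampled pixel table
#'
#' Convenience wrapper evaluating [uv_plus_pixel()] on a colour-pipeline pixel
#' table: UV band = mean(uvR, uvB), visible minimum = min(visR, visG, visB),
#' and the white-relative u catch from the mapping model's raw u prediction
#' for the pixel against its prediction for a flat 100% white (all channels
#' at 1).
#'
#' @param pixels tibble with the 5 normalised channel columns
#' @param model a `mapping_model`
#' @return logical vector
#' @export
uv_plus_flags <- function(pixels, model) {
  chans <- c("visR", "visG", "visB", "uvR", "uvB")
  m <- as.matrix(pixels[chans])
  white <- matrix(1, 1, 5, dimnames = list(NULL, chans))
  u_white <- apply_mapping(model, white)$raw[1, "u"]
  if (u_white <= 0) uvp_stop("degenerate_stimulus", "white u catch non-positive")
  u_raw <- apply_mapping(model, m)$raw[, "u"]
  uv_plus_pixel(uv_band = rowMeans(m[, c("uvR", "uvB"), drop = FALSE]),
                vis_min = pmin(m[, "visR"], m[, "visG"], m[, "visB"]),
                u_rel_white = u_raw / u_white)
}

#' UV+ colouration presence for a specimen view
#'
#' Fraction of sampled pixels flagged UV+, and presence iff that fraction
#' strictly exceeds the threshold (default 5%; 1% and 10% used as sensitivity
#' thresholds).
#'
#' @param flags logical vector of per-pixel UV+ flags
#' @param threshold presence threshold on the flagged fraction
#' @return list with `fraction` and `present`
#' @export
uv_plus_presence <- function(flags, threshold = 0.05) {
  if (length(flags) == 0) uvp_stop("empty_input", "no pixels")
  frac <- mean(flags)
  list(fraction = frac, present = frac > threshold)
}

#' Aggregate specimen-level UV metrics to species level
#'
#' Sex-specific species-level values per view are the arithmetic means of the
#' specimen-level values. Side views largely duplicate plumage captured by
#' back and belly views and are dropped. Presence flags are aggregated by
#' majority: mean of the specimen flags, thresholded at 0.5 (ties count as
#' present).
#'
#' @param records tibble with columns `species`, `sex`, `view`, continuous
#'   metric columns (e.g. `mean_u`, `peak_u`, `uv_plus_fraction`) and logical
#'   flag columns (e.g. `uv_plus_present`)
#' @return tibble keyed by species x sex x view (back/belly only)
#' @export
species_aggregate <- function(records) {
  stopifnot(all(c("species", "sex", "view") %in% names(records)))
  kept <- dplyr::filter(records, .data$view %in% c("back", "belly"))
  num_cols <- names(kept)[vapply(kept, is.numeric, logical(1))]
  flag_cols <- names(kept)[vapply(kept, is.logical, logical(1))]
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$species, .data$sex, .data$view),
    dplyr::across(dplyr::all_of(num_cols), mean),
    dplyr::across(dplyr::all_of(flag_cols), function(x) mean(x) >= 0.5),
    n_specimens = dplyr::n(),
    .groups = "drop"
  )
  out
}
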