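#' Geometry of a synthetic specimen photograph
#'
#' Describes the canvas and where things sit on it: a bird-shaped specimen
#' (body + head + tail ellipses) photographed against a near-black background,
#' with the five grey reflectance standards arranged left to right in
#' increasing reflectance (2, 40, 60, 80, 99%) in a row below the specimen.
#' Optional non-plumage features: an eye disc inside the head and a bright
#' label tag between specimen and standards (disconnected from both).
#'
#' @param nrow,ncol canvas size in pixels
#' @param eye include an eye disc (non-plumage) inside the head
#' @param label include a bright specimen label rectangle below the bird
#' @return list of geometry parameters, class `specimen_layout`
#' @export
specimen_layout <- function(nrow = 90, ncol = 150, eye = TRUE, label = FALSE) {
  stopifnot(nrow >= 60, ncol >= 120)
  sw <- 16L                      # standard width
  gap <- 10L
  x0 <- (ncol - (5L * sw + 4L * gap)) %/% 2L
  std_cols <- lapply(0:4, function(i) c(x0 + i * (sw + gap) + 1L,
                                        x0 + i * (sw + gap) + sw))
  structure(list(
    nrow = nrow, ncol = ncol,
    body = list(r = 0.38 * nrow, c = 0.50 * ncol, a = 0.14 * nrow, b = 0.20 * ncol),
    head = list(r = 0.28 * nrow, c = 0.30 * ncol, a = 0.10 * nrow, b = 0.065 * ncol),
    tail = list(r = 0.44 * nrow, c = 0.78 * ncol, a = 0.055 * nrow, b = 0.12 * ncol),
    eye = if (eye) list(r = 0.28 * nrow, c = 0.28 * ncol, rad = 0.025 * nrow + 1),
    label = if (label) list(rows = c(round(0.60 * nrow), round(0.69 * nrow)),
                            cols = c(round(0.64 * ncol), round(0.80 * ncol))),
    std_rows = c(nrow - 12L, nrow - 3L),
    std_cols = std_cols
  ), class = "specimen_layout")
}

#' Default specimen reflectance spectra
#'
#' Body is a UV-yellow (UV bump plus long-wavelength sigmoid), head a strongly
#' UV-reflective patch with a weaker visible component, tail a carotenoid-like
#' yellow with no UV; eye and background are near-black and the label tag is
#' bright white-ish card.
#'
#' @param world a `spectral_world`
#' @return named list of reflectance spectra on the world grid
#' @export
specimen_spectra <- function(world) {
  list(
    background = make_spectrum("dark", world, level = 0.005),
    body = make_spectrum("uv_plus_yellow", world, uv = 0.35, vis = 0.5),
    head = make_spectrum("uv_plus_yellow", world, uv = 0.55, vis = 0.35),
    tail = make_spectrum("carotenoid", world, level = 0.45),
    eye = make_spectrum("dark", world, level = 0.006),
    label = make_spectrum("flat", world, level = 0.85)
  )
}

STANDARD_NOMINAL <- c(0.02, 0.40, 0.60, 0.80, 0.99)

#' Render a synthetic specimen image with ground truth
#'
#' Renders every pixel through the camera forward model
#' ([camera_response()]) for its assigned reflectance spectrum, scaled by a
#' common lighting gain, plus optional zero-mean Gaussian sensor noise. The
#' five grey standards are rendered from flat spectra of their nominal
#' reflectances (2/40/60/80/99%). The ground-truth mask marks plumage pixels
#' only: body, head and tail, excluding the eye disc, label, standards and
#' background.
#'
#' @param world a `spectral_world`
#' @param layout a `specimen_layout`
#' @param spectra named spectra list as from [specimen_spectra()]
#' @param gain positive lighting gain (per-image lighting variation)
#' @param noise_sd sd of additive Gaussian sensor noise (0 = noise-free)
#' @param seed integer seed for the noise
#' @return object of class `specimen_image`: list with `channels` (named list
#'   of 5 matrices), `standards` (data.frame: nominal, row0, row1, col0, col1),
#'   `truth_mask` (logical matrix), `region_id` (integer matrix indexing
#'   `spectra_table`), `spectra_table` (list of spectra per region id),
#'   `gain`, `noise_sd`, `seed`
#' @export
make_specimen_image <- function(world, layout = specimen_layout(),
                                spectra = specimen_spectra(world),
                                gain = 1, noise_sd = 0, seed = 1L) {
  nr <- layout$nrow; nc <- layout$ncol
  rr <- matrix(seq_len(nr), nr, nc)         # row index grid
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  in_ellipse <- function(e) ((rr - e$r) / e$a)^2 + ((cc - e$c) / e$b)^2 <= 1
  in_rect <- function(rows, cols) rr >= rows[1] & rr <= rows[2] &
    cc >= cols[1] & cc <= cols[2]

  plumage <- in_ellipse(layout$body) | in_ellipse(layout$head) |
    in_ellipse(layout$tail)
  eye <- if (!is.null(layout$eye)) {
    (rr - layout$eye$r)^2 + (cc - layout$eye$c)^2 <= layout$eye$rad^2
  } else matrix(FALSE, nr, nc)
  label <- if (!is.null(layout$label)) {
    in_rect(layout$label$rows, layout$label$cols)
  } else matrix(FALSE, nr, nc)
  std <- lapply(layout$std_cols, function(sc) in_rect(layout$std_rows, sc))
  std_all <- Reduce(`|`, std)

  if (any(plumage & (std_all | label)) || any(label & std_all)) {
    uvp_stop("layout_error",
             "specimen, label and standard regions must not overlap")
  }

  # region ids: 1 background, 2 body, 3 head, 4 tail, 5 eye, 6 label, 7:11 standards
  region <- matrix(1L, nr, nc)
  region[in_ellipse(layout$tail)] <- 4L
  region[in_ellipse(layout$body)] <- 2L
  region[in_ellipse(layout$head)] <- 3L
  region[eye] <- 5L
  region[label] <- 6L
  for (i in 1:5) region[std[[i]]] <- 6L + i

  spectra_table <- c(
    list(spectra$background, spectra$body, spectra$head, spectra$tail,
         spectra$eye, spectra$label),
    lapply(STANDARD_NOMINAL, function(k) make_spectrum("flat", world, level = k))
  )

  resp <- t(vapply(spectra_table, camera_response, numeric(5),
                   world = world, gain = gain))
  colnames(resp) <- colnames(world$camera)

  set.seed(as.integer(seed))
  channels <- lapply(colnames(world$camera), function(ch) {
    m <- matrix(resp[region, ch], nr, nc)
    if (noise_sd > 0) m <- m + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    pmax(m, 0)
  })
  names(channels) <- colnames(world$camera)

  truth_mask <- (plumage & !eye)

  standards <- data.frame(
    nominal = STANDARD_NOMINAL,
    row0 = layout$std_rows[1], row1 = layout$std_rows[2],
    col0 = vapply(layout$std_cols, function(x) as.integer(x[1]), integer(1)),
    col1 = vapply(layout$std_cols, function(x) as.integer(x[2]), integer(1))
  )

  structure(
    list(channels = channels, standards = standards, truth_mask = truth_mask,
         region_id = region, spectra_table = spectra_table,
         gain = gain, noise_sd = noise_sd, seed = as.integer(seed),
         world_seed = world$seed),
    class = "specimen_image"
  )
}

#' @export
print.specimen_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "specimen_image: %d x %d px, 5 channels (%s)\n  gain %.3g, noise sd %.3g, %d plumage px\n",
    d[1], d[2], paste(names(x$channels), collapse = ","),
    x$gain, x$noise_sd, sum(x$truth_mask)))
  invisible(x)
}

#' Write / read a specimen image on disk
#'
#' Channels go to one 16-bit multi-page TIFF (one page per channel, intensities
#' scaled by a common factor recorded in the sidecar), the ground-truth mask to
#' an 8-bit PNG (0/255), and the provenance (standard rectangles, gain, noise,
#' seeds, scale) to a YAML sidecar.
#'
#' @param img a `specimen_image`
#' @param dir output directory (created if needed)
#' @param name file stem
#' @return (invisibly) the paths written
#' @export
write_specimen_image <- function(img, dir, name = "specimen") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(vapply(img$channels, max, numeric(1)), 1e-12)
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(lapply(img$channels, function(m) m / scale), tif,
                  bits.per.sample = 16L)
  msk <- file.path(dir, paste0(name, "_mask.png"))
  png::writePNG(img$truth_mask * 1, msk)
  meta <- file.path(dir, paste0(name, ".yml"))
  yaml::write_yaml(list(
    channels = names(img$channels), scale = scale, gain = img$gain,
    noise_sd = img$noise_sd, seed = img$seed, world_seed = img$world_seed,
    standards = lapply(seq_len(nrow(img$standards)), function(i)
      as.list(img$standards[i, ]))
  ), meta)
  invisible(c(image = tif, mask = msk, meta = meta))
}

#' @rdname write_specimen_image
#' @param stem path stem previously passed to [write_specimen_image()]
#'   (directory + name)
#' @export
read_specimen_image <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yml"))
  pages <- tiff::readTIFF(paste0(stem, ".tif"), all = TRUE)
  channels <- lapply(pages, function(p) p * meta$scale)
  names(channels) <- meta$channels
  mask <- png::readPNG(paste0(stem, "_mask.png")) > 0.5
  standards <- do.call(rbind, lapply(meta$standards, as.data.frame))
  structure(
    list(channels = channels, standards = standards, truth_mask = mask,
         region_id = NULL, spectra_table = NULL, gain = meta$gain,
         noise_sd = meta$noise_sd, seed = meta$seed,
         world_seed = meta$world_seed),
    class = "specimen_image"
  )
}
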