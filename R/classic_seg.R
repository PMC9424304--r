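#' Greyscale conversion for classic segmentation
#'
#' Unweighted mean of the three visible channels, linearly rescaled to 0--255
#' integers over the image's intensity range.
#'
#' @param image a `specimen_image`
#' @return integer-valued numeric matrix in 0..255
#' @export
to_grey <- function(image) {
  g <- (image$channels$visR + image$channels$visG + image$channels$visB) / 3
  rng <- range(g)
  if (diff(rng) <= 0) return(matrix(0, nrow(g), ncol(g)))
  round(255 * (g - rng[1]) / diff(rng))
}

#' Gaussian smoothing with reflective borders
#'
#' Separable 2-D Gaussian convolution, the standard denoising step applied
#' before each classic segmentation method. Borders are handled by symmetric
#' reflection, which preserves constant images exactly and the image mean to
#' within tolerance.
#'
#' @param channel numeric matrix
#' @param sigma kernel standard deviation in pixels (> 0)
#' @return smoothed matrix of the same shape
#' @export
gaussian_smooth <- function(channel, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    i
  }
  conv_rows <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (d in -r:r) {
      out <- out + k[d + r + 1L] * m[reflect(seq_len(n) + d, n), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(channel))))
}

#' Morphological close-then-open post-processing
#'
#' Closing fills segmentation holes, opening removes segmentation noise; both
#' use a square structuring element of side `2 * radius + 1`. Applied as the
#' global post-processing step of every classic segmentation method.
#'
#' @param mask logical matrix
#' @param radius structuring element radius (>= 1)
#' @return logical matrix
#' @export
morph_open_close <- function(mask, radius = 1L) {
  stopifnot(radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "box")
  m <- EBImage::opening(EBImage::closing(mask * 1, brush), brush)
  m > 0.5
}

#' 8-connected component labelling
#'
#' @param mask logical matrix
#' @return integer matrix of component labels (0 = background)
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  # neighbour offsets in column-major linear indexing
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  todo <- which(mask)
  cur <- 0L
  queue <- integer(length(todo))
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pr <- (p - 1L) %% nr + 1L
      for (o in offs) {
        q <- p + o
        if (q < 1L || q > nr * nc) next
        qr <- (q - 1L) %% nr + 1L
        if (abs(qr - pr) > 1L) next # wrapped over a column edge
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

#' Modal-threshold segmentation baseline
#'
#' The classic thresholding baseline: convert to greyscale, Gaussian-smooth,
#' binarise at the modal pixel value plus a positive offset of 15 (the
#' background dominates the histogram, so the mode tracks the background
#' level), apply close-then-open, and keep the most upper 8-connected
#' component — the specimen always sits above the reflectance standards, so
#' the component whose topmost pixel has the smallest row index is the bird
#' (ties broken towards larger area).
#'
#' @param image a `specimen_image`
#' @param sigma Gaussian smoothing sd (pixels)
#' @param offset threshold offset above the mode (default 15)
#' @param radius morphological structuring-element radius
#' @return logical plumage mask
#' @export
threshold_segment <- function(image, sigma = 1, offset = 15, radius = 1L) {
  grey <- round(gaussian_smooth(to_grey(image), sigma))
  counts <- tabulate(as.integer(grey) + 1L, nbins = 256L)
  mode_val <- which.max(counts) - 1L # which.max takes the first (smallest) tie
  bin <- grey > (mode_val + offset)
  if (!any(bin)) {
    uvp_stop("empty_segmentation", "no pixel exceeds the modal threshold")
  }
  bin <- morph_open_close(bin, radius)
  if (!any(bin)) {
    uvp_stop("empty_segmentation", "segmentation empty after morphology")
  }
  lab <- label_components(bin)
  ids <- seq_len(max(lab))
  toprow <- vapply(ids, function(i) min(row(lab)[lab == i]), numeric(1))
  areas <- vapply(ids, function(i) sum(lab == i), numeric(1))
  best <- ids[order(toprow, -areas)][1]
  lab == best
}

#' Seeded region growing baseline
#'
#' Breadth-first growth over 4-neighbours from each seed pixel: a pixel joins
#' the region if its (smoothed) grey value lies within
#' `[seed_grey - lower, seed_grey + upper]` of the *initial* seed value.
#' Regions from all seeds are unioned, then close-then-open post-processing is
#' applied. Default bounds (lower 6, upper 30 grey levels) are the
#' best-performing combination for specimen photographs.
#'
#' @param image a `specimen_image`
#' @param seeds integer matrix with columns (row, col), 1-based
#' @param lower,upper grey-level bounds around the seed value
#' @param sigma Gaussian smoothing sd
#' @param radius morphological structuring-element radius
#' @return logical plumage mask
#' @export
region_grow <- function(image, seeds, lower = 6, upper = 30,
                        sigma = 1, radius = 1L) {
  if (is.null(seeds) || NROW(seeds) == 0) {
    uvp_stop("seed_error", "region growing needs at least one seed pixel")
  }
  seeds <- matrix(as.integer(seeds), ncol = 2)
  grey <- round(gaussian_smooth(to_grey(image), sigma))
  nr <- nrow(grey); nc <- ncol(grey)
  if (any(seeds[, 1] < 1 | seeds[, 1] > nr | seeds[, 2] < 1 | seeds[, 2] > nc)) {
    uvp_stop("bounds_error", "seed outside image bounds")
  }
  mask <- matrix(FALSE, nr, nc)
  offs <- c(-1L, 1L, -nr, nr) # 4-connectivity
  queue <- integer(nr * nc)
  for (s in seq_len(nrow(seeds))) {
    p0 <- (seeds[s, 2] - 1L) * nr + seeds[s, 1]
    g0 <- grey[p0]
    lo <- g0 - lower; hi <- g0 + upper
    grown <- matrix(FALSE, nr, nc) # each seed grows independently, then union
    queue[1L] <- p0
    head <- 1L; tail <- 1L
    grown[p0] <- TRUE
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pr <- (p - 1L) %% nr + 1L
      for (o in offs) {
        q <- p + o
        if (q < 1L || q > nr * nc) next
        if (abs(o) == 1L && abs((q - 1L) %% nr + 1L - pr) > 1L) next
        if (!grown[q] && grey[q] >= lo && grey[q] <= hi) {
          grown[q] <- TRUE
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
    mask <- mask | grown
  }
  morph_open_close(mask, radius)
}
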