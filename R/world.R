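#' Build a synthetic spectral world
#'
#' Constructs the spectral scaffolding the whole pipeline runs on: a wavelength
#' grid over 300--700 nm, an illuminant, the four receptor sensitivity curves of
#' an average ultraviolet-sensitive (UVS) avian visual system (u, s, m, l), and
#' the five effective camera channel sensitivities (visR, visG, visB, uvR, uvB).
#'
#' Receptor and camera curves are Gaussian in shape, peaked near 370 (u),
#' 445 (s), 508 (m) and 565 (l) nm for the receptors. Camera UV channels pass
#' only 320--380 nm (a UV-pass filter, hard-zeroed above 400 nm) while the
#' visible channels are zeroed below 400 nm (UV/IR-cut filter). A UV-range
#' green channel is deliberately absent: camera green responses in the UV are
#' too weak to carry information. Receptor curves are normalised to unit
#' integral (midpoint rule) so that a flat stimulus under a flat illuminant
#' lands on the achromatic null u = s = m = l = 0.25.
#'
#' The seed perturbs the camera peak positions by a few nanometres, emulating
#' unit-to-unit variation in a real camera set-up; the receptor curves (the
#' "visual system") are deterministic.
#'
#' @param seed integer seed controlling camera curve perturbation
#' @param step grid step in nm (default 5, giving 81 wavelengths)
#' @return an object of class `spectral_world`: list with `wl`, `delta`,
#'   `illuminant`, `receptors` (matrix, columns u,s,m,l), `camera` (matrix,
#'   columns visR,visG,visB,uvR,uvB), `seed`
#' @examples
#' w <- make_world(1)
#' length(w$wl)  # 81
#' @export
make_world <- function(seed = 1L, step = 5) {
  wl <- seq(300, 700, by = step)
  n <- length(wl)

  gauss <- function(peak, sd) exp(-0.5 * ((wl - peak) / sd)^2)

  # flat illuminant: idealised illumination conditions
  illuminant <- rep(1, n)

  receptors <- cbind(
    u = gauss(370, 25),
    s = gauss(445, 32),
    m = gauss(508, 36),
    l = gauss(565, 40)
  )
  # unit integral by midpoint rule
  receptors <- sweep(receptors, 2, colSums(receptors) * step, "/")

  set.seed(as.integer(seed))
  jit <- stats::rnorm(5, 0, 2) # nm-scale unit-to-unit variation
  camera <- cbind(
    visR = gauss(600 + jit[1], 45),
    visG = gauss(540 + jit[2], 40),
    visB = gauss(460 + jit[3], 35),
    uvR  = gauss(350 + jit[4], 16),
    uvB  = gauss(365 + jit[5], 14)
  )
  camera[wl < 400, c("visR", "visG", "visB")] <- 0 # UV/IR-cut filter
  camera[wl > 400, c("uvR", "uvB")] <- 0           # UV-pass filter (320-380)
  camera[wl < 320 | wl > 380, c("uvR", "uvB")] <- 0

  structure(
    list(wl = wl, delta = step, illuminant = illuminant,
         receptors = receptors, camera = camera, seed = as.integer(seed)),
    class = "spectral_world"
  )
}

#' Parametric reflectance spectra
#'
#' Generates reflectance spectra on a world's wavelength grid. Available kinds:
#' \describe{
#'   \item{flat}{constant reflectance `level`.}
#'   \item{uv_peak}{Gaussian bump confined to 300--400 nm ("pure" UV colour),
#'     `height` at `center` (default 355 nm) with width `width`.}
#'   \item{carotenoid}{long-wavelength sigmoid rising at `cuton` (default
#'     500 nm) to `level` — a yellow/red pigment-like step.}
#'   \item{uv_plus_yellow}{sum of a UV bump (`uv`) and a long-wavelength
#'     sigmoid (`vis`) — UV reflectance combined with another colour (a
#'     "UV-yellow"-type spectrum).}
#'   \item{dark}{constant at `level`, which must stay below 1% — a
#'     near-black, non-reflective background material.}
#' }
#'
#' @param kind one of "flat", "uv_peak", "carotenoid", "uv_plus_yellow", "dark"
#' @param world a `spectral_world`
#' @param level,height,center,width,cuton,slope,uv,vis kind-specific
#'   parameters; all reflectance amplitudes must lie in \[0, 1\]
#' @return numeric vector of reflectances on the world grid, all in \[0, 1\]
#' @export
make_spectrum <- function(kind = c("flat", "uv_peak", "carotenoid",
                                   "uv_plus_yellow", "dark"),
                          world,
                          level = 0.1, height = 0.5, center = 355, width = 18,
                          cuton = 500, slope = 0.08, uv = 0.3, vis = 0.5) {
  kind <- match.arg(kind)
  wl <- world$wl
  chk01 <- function(x, what) {
    if (any(x < 0 | x > 1)) {
      uvp_stop("reflectance_range",
               sprintf("%s must lie in [0, 1], got %s", what,
                       paste(signif(range(x), 3), collapse = "..")))
    }
  }
  bump <- function(h) {
    b <- h * exp(-0.5 * ((wl - center) / width)^2)
    b[wl > 400] <- 0 # confined to the UV band
    b
  }
  sigm <- function(h) h / (1 + exp(-(wl - cuton) * slope))
  spec <- switch(kind,
    flat = {
      chk01(level, "level")
      rep(level, length(wl))
    },
    uv_peak = {
      chk01(height, "height")
      bump(height)
    },
    carotenoid = {
      chk01(level, "level")
      sigm(level)
    },
    uv_plus_yellow = {
      chk01(uv, "uv"); chk01(vis, "vis")
      pmin(bump(uv) + sigm(vis), 1)
    },
    dark = {
      chk01(level, "level")
      if (level >= 0.01) {
        uvp_stop("reflectance_range", "dark spectra must stay below 1% reflectance")
      }
      rep(level, length(wl))
    }
  )
  spec
}

#' Camera channel responses to a reflectance spectrum
#'
#' Forward model of image formation: each channel integrates
#' illuminant x reflectance x channel sensitivity over wavelength (midpoint
#' rule on the world grid), scaled by a lighting gain. Linear in both the gain
#' and the reflectance spectrum.
#'
#' @param spec reflectance spectrum on the world grid
#' @param world a `spectral_world`
#' @param gain positive lighting gain
#' @return named numeric vector of 5 channel intensities
#' @export
camera_response <- function(spec, world, gain = 1) {
  stopifnot(length(spec) == length(world$wl), gain > 0)
  drop(gain * crossprod(world$camera, world$illuminant * spec)) * world$delta
}

#' Relative cone catches of a reflectance spectrum
#'
#' Quantum catch per receptor class is the integral of
#' illuminant x reflectance x receptor sensitivity; relative catches divide by
#' their sum so u + s + m + l = 1. These are the "true" catches the polynomial
#' camera mapping is trained to recover.
#'
#' @param spec reflectance spectrum on the world grid
#' @param world a `spectral_world`
#' @return named numeric vector (u, s, m, l) summing to 1
#' @export
true_cone_catch <- function(spec, world) {
  raw <- quantum_catch(spec, world)
  s <- sum(raw)
  if (s <= 0) {
    uvp_stop("degenerate_stimulus",
             "all-zero quantum catches: relative cone catches undefined")
  }
  raw / s
}

#' Raw quantum catches of a reflectance spectrum
#'
#' The unnormalised integrals of illuminant x reflectance x receptor
#' sensitivity per receptor class — the quantities the polynomial camera
#' mapping is fitted to (relative catches are their ratio).
#'
#' @inheritParams true_cone_catch
#' @return named numeric vector (u, s, m, l), non-negative
#' @export
quantum_catch <- function(spec, world) {
  stopifnot(length(spec) == length(world$wl))
  drop(crossprod(world$receptors, world$illuminant * spec)) * world$delta
}

#' Calibration set for the cone-catch mapping
#'
#' Draws `n` random reflectance spectra (mixtures of the parametric kinds plus
#' smooth random spectra), and returns their camera channel responses expressed
#' as normalised reflectance (response relative to a 100% flat white) paired
#' with their raw quantum catches — the targets the polynomial mapping is
#' fitted to; relative catches are recovered by renormalising predictions.
#'
#' @param world a `spectral_world`
#' @param n number of calibration spectra (default 250)
#' @param seed integer seed
#' @return list with `channels` (n x 5 matrix), `catches` (n x 4 matrix of
#'   raw quantum catches), `catches_rel` (relative catches, rows sum to 1),
#'   `spectra` (list of the generating spectra)
#' @export
make_calibration <- function(world, n = 250, seed = 1L) {
  set.seed(as.integer(seed))
  wl <- world$wl
  white <- camera_response(rep(1, length(wl)), world, gain = 1)
  draw_spec <- function() {
    k <- sample(5, 1)
    if (k == 1) {
      make_spectrum("flat", world, level = stats::runif(1, 0.01, 0.99))
    } else if (k == 2) {
      make_spectrum("uv_peak", world, height = stats::runif(1, 0.05, 0.9),
                    center = stats::runif(1, 330, 380),
                    width = stats::runif(1, 10, 30))
    } else if (k == 3) {
      make_spectrum("carotenoid", world, level = stats::runif(1, 0.1, 0.95),
                    cuton = stats::runif(1, 450, 620))
    } else if (k == 4) {
      make_spectrum("uv_plus_yellow", world, uv = stats::runif(1, 0.05, 0.7),
                    vis = stats::runif(1, 0.1, 0.9),
                    cuton = stats::runif(1, 450, 620))
    } else {
      # smooth random spectrum: softmax-ish mixture of broad Gaussians
      centers <- stats::runif(3, 300, 700)
      amps <- stats::runif(3, 0, 0.9)
      sds <- stats::runif(3, 30, 120)
      s <- rowSums(vapply(1:3, function(i) {
        amps[i] * exp(-0.5 * ((wl - centers[i]) / sds[i])^2)
      }, numeric(length(wl))))
      pmin(s + stats::runif(1, 0.01, 0.1), 1)
    }
  }
  spectra <- replicate(n, draw_spec(), simplify = FALSE)
  channels <- t(vapply(spectra, function(s) {
    camera_response(s, world, gain = 1) / white
  }, numeric(5)))
  catches <- t(vapply(spectra, quantum_catch, numeric(4), world = world))
  catches_rel <- catches / rowSums(catches)
  colnames(channels) <- colnames(world$camera)
  colnames(catches) <- colnames(world$receptors)
  colnames(catches_rel) <- colnames(world$receptors)
  list(channels = channels, catches = catches, catches_rel = catches_rel,
       spectra = spectra)
}
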