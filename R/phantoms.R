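#' Specification of a piecewise-smooth phantom image
#'
#' The phantom family emulates the difficulty axes of the images the
#' model targets — low contrast between regions, smooth within-region
#' shading, thin elongated structures (vessel/"tail" analogues) and up
#' to four intensity classes for the multiphase case — without
#' simulating any modality physics. Regions are smooth star-shaped
#' nested blobs plus one thin sinusoidal stripe; each region carries a
#' base intensity level and a shared low-frequency smooth drift of
#' bounded amplitude.
#'
#' @param shape grid dimensions `c(H, W)`.
#' @param intensity_levels region base intensities on the 8-bit scale,
#'   in increasing order, one per phase (background first).
#' @param n_phases number of phases; must equal
#'   `length(intensity_levels)`.
#' @param gradient_amplitude total amplitude (intensity units) of the
#'   smooth within-region drift; 0 gives a piecewise-constant image.
#' @param contrast_gap minimum allowed separation between consecutive
#'   base levels; levels violating it are an error.
#' @param seed integer seed; phantoms are bit-reproducible for a fixed
#'   seed.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         intensity_levels = c(100, 140),
                         n_phases = length(intensity_levels),
                         gradient_amplitude = 20,
                         contrast_gap = 30,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 8L))
  if (n_phases != length(intensity_levels) || n_phases < 2L) {
    stop("phantom_spec: n_phases must equal length(intensity_levels), >= 2")
  }
  if (any(intensity_levels < 0 | intensity_levels > 255)) {
    stop("phantom_spec: intensity_levels must lie in [0, 255]")
  }
  if (is.unsorted(intensity_levels, strictly = TRUE)) {
    stop("phantom_spec: intensity_levels must be strictly increasing")
  }
  if (min(diff(intensity_levels)) < contrast_gap) {
    stop("phantom_spec: consecutive levels closer than contrast_gap")
  }
  if (gradient_amplitude < 0) stop("phantom_spec: gradient_amplitude must be >= 0")
  structure(list(shape = shape, n_phases = as.integer(n_phases),
                 intensity_levels = as.numeric(intensity_levels),
                 gradient_amplitude = gradient_amplitude,
                 contrast_gap = contrast_gap, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image with its ground-truth labels
#'
#' Draws the region geometry and drift from the seeded RNG and returns
#' the clean image together with its label map. The drift is a sum of
#' three random low-frequency cosines rescaled to span exactly
#' `gradient_amplitude`, so the intensity range inside any region is
#' bounded by that amplitude; the inter-region separation of base levels
#' is at least `contrast_gap` by validation of the spec.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `clean` (numeric matrix) and `labels` (integer
#'   matrix, phases `0 ... n_phases - 1`).
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(64, 64), seed = 7))
#' table(ph$labels)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$shape[1]
  W <- spec$shape[2]
  K <- spec$n_phases
  yy <- matrix((seq_len(H) - 0.5) / H, H, W)
  xx <- matrix(rep((seq_len(W) - 0.5) / W, each = H), H, W)

  labels <- matrix(0L, H, W)
  centre <- c(0.5, 0.5) + stats::runif(2, -0.03, 0.03)
  dx <- xx - centre[2]
  dy <- yy - centre[1]
  rad <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  base_r <- 0.36 * (1 - (seq_len(K - 1) - 1) / K)
  ring_gap <- 0.36 / K
  for (k in seq_len(K - 1)) {
    modes <- 2:4
    a <- stats::runif(length(modes), -1, 1)
    ph <- stats::runif(length(modes), 0, 2 * pi)
    pert <- Reduce(`+`, Map(function(m, am, p) am * cos(m * theta + p),
                            modes, a, ph))
    # keep the boundary wobble below a third of the ring gap so the
    # blobs stay strictly nested and every phase is non-empty
    pert <- pert / max(abs(pert)) * 0.3 * ring_gap
    inside <- rad <= base_r[k] + pert
    labels[inside] <- k
  }

  # thin elongated structure attached to phase 1 (vessel/tail analogue),
  # only over background so higher phases are not cut through
  y0 <- stats::runif(1, 0.12, 0.2)
  amp <- stats::runif(1, 0.03, 0.06)
  freq <- stats::runif(1, 2, 3)
  phs <- stats::runif(1, 0, 2 * pi)
  half_w <- 1.5 / H
  stripe <- abs(yy - y0 - amp * sin(2 * pi * freq * xx + phs)) <= half_w &
    xx >= 0.08 & xx <= 0.92
  labels[stripe & labels == 0L] <- 1L

  if (!all((seq_len(K) - 1L) %in% labels)) {
    stop("make_phantom: degenerate geometry, a phase came out empty")
  }

  clean <- matrix(spec$intensity_levels[labels + 1L], H, W)
  if (spec$gradient_amplitude > 0) {
    drift <- matrix(0, H, W)
    for (i in 1:3) {
      p <- stats::runif(1, 0.4, 1.4)
      q <- stats::runif(1, 0.4, 1.4)
      drift <- drift + stats::runif(1, -1, 1) *
        cos(2 * pi * (p * xx + q * yy) + stats::runif(1, 0, 2 * pi))
    }
    drift <- (drift - min(drift)) / (max(drift) - min(drift))
    clean <- clean + (drift - 0.5) * spec$gradient_amplitude
  }
  list(clean = clean, labels = labels)
}

#' Add seeded Gaussian noise
#'
#' Independent zero-mean Gaussian noise of standard deviation `sigma`
#' per pixel on the 8-bit intensity scale. No clipping by default: at
#' high noise levels (e.g. sigma = 100 on a binary mask) clipping to
#' `[0, 255]` would severely censor the noise distribution; set
#' `clip = TRUE` to get the censored variant.
#'
#' @param img scalar field (numeric matrix).
#' @param sigma noise standard deviation, `>= 0` (0 returns the input
#'   unchanged).
#' @param seed integer seed; the noise field is bit-reproducible.
#' @param clip clamp the result to `[0, 255]`.
#' @return the noisy image, same shape.
#' @export
add_noise <- function(img, sigma, seed = 1L, clip = FALSE) {
  assert_scalar_field(img, "img")
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(img)
  set.seed(as.integer(seed))
  out <- img + matrix(stats::rnorm(length(img), 0, sigma), nrow(img), ncol(img))
  if (clip) out <- pmin(pmax(out, 0), 255)
  out
}
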