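#' Stage two: threshold the smooth minimiser into a label map
#'
#' The segmentation is obtained from the stage-one minimiser `g` alone,
#' so any number of threshold choices can be tried without re-running
#' the solver. `threshold_binary()` labels a pixel 1 (foreground) where
#' `g >= tau` — ties go to the foreground by convention — and 0
#' otherwise. `apply_thresholds()` generalises to K phases: the label of
#' a pixel is the number of cuts less than or equal to its value, so
#' `K - 1` strictly increasing cuts induce labels `0 ... K-1`. With a
#' single cut the two functions agree bit for bit.
#'
#' @param g scalar field (numeric matrix), typically the stage-one
#'   output.
#' @param tau single threshold value.
#' @param cuts strictly increasing numeric vector of cut points.
#' @return an integer matrix of labels, same shape as `g`.
#' @examples
#' g <- matrix(c(10, 50, 90), 1)
#' apply_thresholds(g, c(30, 70))   # 0 1 2
#' @export
threshold_binary <- function(g, tau) {
  assert_scalar_field(g, "g")
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  lab <- matrix(as.integer(g >= tau), nrow(g), ncol(g))
  lab
}

#' @rdname threshold_binary
#' @export
apply_thresholds <- function(g, cuts) {
  assert_scalar_field(g, "g")
  if (!is.numeric(cuts) || length(cuts) < 1L || anyNA(cuts)) {
    stop("apply_thresholds: cuts must be a non-empty numeric vector")
  }
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("apply_thresholds: cuts must be strictly increasing")
  }
  # label = number of cuts <= value; findInterval counts exactly that
  lab <- matrix(findInterval(g, cuts), nrow(g), ncol(g))
  storage.mode(lab) <- "integer"
  lab
}

#' Automatic thresholds by 1-D k-means on intensities
#'
#' Runs k-means (k-means++-style seeded initialisation via `nstart`
#' restarts) on the intensity values of `g` and converts the clustering
#' into thresholds: the `K - 1` midpoints between consecutive sorted
#' cluster centres. Used for multiphase segmentation, where picking
#' `K - 1` manual cuts would be tedious; two-phase work typically uses a
#' manual `tau` instead, which tends to give better results.
#'
#' @param g scalar field whose intensities are clustered.
#' @param K number of phases (clusters), at least 2.
#' @param seed integer seed; fixed seed gives identical cuts across
#'   runs.
#' @param nstart number of random restarts.
#' @return numeric vector of `K - 1` strictly increasing cuts.
#' @export
kmeans_thresholds <- function(g, K, seed = 1L, nstart = 10L) {
  assert_scalar_field(g, "g")
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("kmeans_thresholds: K must be >= 2")
  vals <- as.vector(g)
  if (length(unique(vals)) < K) {
    stop("kmeans_thresholds: degenerate input, fewer than K distinct values")
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(vals, centers = K, nstart = nstart, iter.max = 200L)
  centres <- sort(as.vector(km$centers))
  cuts <- (centres[-K] + centres[-1L]) / 2
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("kmeans_thresholds: collapsed clusters produced non-increasing cuts")
  }
  cuts
}
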