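as_binary_mask <- function(m, name) {
  if (!is.matrix(m)) stop(name, " must be a matrix")
  if (!all(m %in% c(0L, 1L))) stop(name, " must be binary (values 0/1)")
  m != 0
}

#' Overlap scores between a segmentation and a ground truth
#'
#' Dice coefficient
#' \eqn{\mathrm{DICE} = 2|\Sigma \cap GT| / (|\Sigma| + |GT|)} and
#' Jaccard index \eqn{J = |\Sigma \cap GT| / |\Sigma \cup GT|}, with set
#' size the foreground pixel count. The two are linked by the identity
#' \eqn{J = D / (2 - D)}. Both are symmetric in their arguments and lie
#' in \eqn{[0, 1]}. When both masks are empty the score is undefined and
#' an error is raised rather than silently returning 0.
#'
#' @param seg,gt binary (0/1) integer matrices of one shape.
#' @return a single number in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' b <- matrix(c(1, 0, 1, 0), 2)
#' dice(a, b)
#' jaccard(a, b)
#' @export
dice <- function(seg, gt) {
  s <- as_binary_mask(seg, "seg")
  g <- as_binary_mask(gt, "gt")
  if (!identical(dim(s), dim(g))) stop("dice: shape mismatch")
  denom <- sum(s) + sum(g)
  if (denom == 0) stop("dice: undefined, both masks are empty")
  2 * sum(s & g) / denom
}

#' @rdname dice
#' @export
jaccard <- function(seg, gt) {
  s <- as_binary_mask(seg, "seg")
  g <- as_binary_mask(gt, "gt")
  if (!identical(dim(s), dim(g))) stop("jaccard: shape mismatch")
  uni <- sum(s | g)
  if (uni == 0) stop("jaccard: undefined, both masks are empty")
  sum(s & g) / uni
}

#' Summarise overlap scores over a collection of mask pairs
#'
#' Convenience wrapper mirroring per-dataset reporting: per-image Dice
#' and Jaccard plus their mean and standard deviation.
#'
#' @param segs,gts lists of binary matrices, matched by position.
#' @return a list with `per_image` (data frame) and `summary`
#'   (mean/sd per metric).
#' @export
overlap_report <- function(segs, gts) {
  stopifnot(length(segs) == length(gts), length(segs) >= 1L)
  d <- mapply(dice, segs, gts)
  j <- mapply(jaccard, segs, gts)
  list(per_image = data.frame(image = seq_along(d), dice = d, jaccard = j),
       summary = data.frame(metric = c("dice", "jaccard"),
                            mean = c(mean(d), mean(j)),
                            sd = c(stats::sd(d), stats::sd(j))))
}
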