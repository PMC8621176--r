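#' Field containers
#'
#' The solver works on three kinds of discrete fields over a regular
#' \eqn{H \times W} pixel grid:
#' \itemize{
#'   \item a *scalar field* is a plain numeric matrix (the image \eqn{f},
#'     the smooth approximation \eqn{g}, Bregman components, ...);
#'   \item a *vector field* pairs two scalar fields, interpreted as the
#'     \eqn{x} (along columns) and \eqn{y} (along rows) components of a
#'     gradient-like quantity such as \eqn{G = (G_x, G_y)};
#'   \item a *Jacobian field* holds the four first differences of a vector
#'     field: \eqn{\nabla G_x} and \eqn{\nabla G_y}, each a vector field.
#' }
#'
#' @param x,y numeric matrices of identical shape.
#' @return `vector_field()` returns a list with components `x` and `y` of
#'   class `"vector_field"`.
#' @examples
#' v <- vector_field(matrix(0, 4, 5), matrix(1, 4, 5))
#' field_shape(v)
#' @export
vector_field <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (!identical(dim(x), dim(y))) {
    stop("vector_field: components have mismatched shapes (",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"), ")")
  }
  structure(list(x = x, y = y), class = "vector_field")
}

#' @rdname vector_field
#' @param dGx,dGy `vector_field` objects holding \eqn{\nabla G_x} and
#'   \eqn{\nabla G_y}.
#' @return `jacobian_field()` returns a list with components `dGx` and
#'   `dGy` of class `"jacobian_field"`.
#' @export
jacobian_field <- function(dGx, dGy) {
  stopifnot(inherits(dGx, "vector_field"), inherits(dGy, "vector_field"))
  if (!identical(dim(dGx$x), dim(dGy$x))) {
    stop("jacobian_field: channels have mismatched shapes")
  }
  structure(list(dGx = dGx, dGy = dGy), class = "jacobian_field")
}

#' @rdname vector_field
#' @param f a scalar field (matrix), `vector_field` or `jacobian_field`.
#' @return `field_shape()` returns the common `c(H, W)` grid shape.
#' @export
field_shape <- function(f) {
  if (is.matrix(f)) return(dim(f))
  if (inherits(f, "vector_field")) return(dim(f$x))
  if (inherits(f, "jacobian_field")) return(dim(f$dGx$x))
  stop("field_shape: not a field object")
}

# zero fields of a given shape
zero_scalar <- function(shape) matrix(0, shape[1], shape[2])
zero_vector <- function(shape) vector_field(zero_scalar(shape), zero_scalar(shape))
zero_jacobian <- function(shape) jacobian_field(zero_vector(shape), zero_vector(shape))

# component-wise arithmetic on arbitrary field nests (matrix leaves)
field_map2 <- function(a, b, op) {
  if (is.matrix(a)) {
    if (!is.matrix(b) || !identical(dim(a), dim(b))) {
      stop("field arithmetic: shape mismatch")
    }
    return(op(a, b))
  }
  if (!identical(class(a), class(b)) || length(a) != length(b)) {
    stop("field arithmetic: incompatible field kinds")
  }
  out <- mapply(field_map2, a, b, MoreArgs = list(op = op), SIMPLIFY = FALSE)
  class(out) <- class(a)
  out
}

field_add <- function(a, b) field_map2(a, b, `+`)
field_sub <- function(a, b) field_map2(a, b, `-`)

# flatten a field nest to one numeric vector (for norms/residuals)
field_flat <- function(a) {
  if (is.matrix(a)) return(as.vector(a))
  unlist(lapply(a, field_flat), use.names = FALSE)
}

field_norm <- function(a) sqrt(sum(field_flat(a)^2))

field_finite <- function(a) all(is.finite(field_flat(a)))

assert_scalar_field <- function(u, name = "input") {
  if (!is.matrix(u) || !is.numeric(u)) {
    stop(name, " must be a 2-D numeric matrix")
  }
  invisible(u)
}
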