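#' Discrete gradient (backward differences, zero-Neumann boundary)
#'
#' Discretises \eqn{\nabla = (\nabla_x, \nabla_y)} with backward
#' differences: \eqn{(\nabla_x u)_{i,j} = u_{i,j} - u_{i,j-1}} along
#' columns and \eqn{(\nabla_y u)_{i,j} = u_{i,j} - u_{i-1,j}} along rows.
#' In the first column (resp. row) the backward neighbour falls outside
#' the grid and the difference is set to 0 (replicate padding), so
#' constants are exactly in the kernel — the discrete analogue of a
#' zero-Neumann boundary condition.
#'
#' @param u a scalar field (numeric matrix).
#' @return a [vector_field] `(grad_x u, grad_y u)` on the same grid.
#' @seealso [gradient_adjoint()] for the exact adjoint.
#' @export
gradient <- function(u) {
  assert_scalar_field(u)
  W <- ncol(u)
  H <- nrow(u)
  gx <- u - u[, c(1L, seq_len(W - 1L)), drop = FALSE]
  gy <- u - u[c(1L, seq_len(H - 1L)), , drop = FALSE]
  vector_field(gx, gy)
}

#' Adjoint of the discrete gradient
#'
#' The exact adjoint of [gradient()] under the Euclidean inner product:
#' \eqn{\langle \nabla u, p \rangle = \langle u, \nabla^T p \rangle}
#' holds to machine precision for every pair of fields. It is the matrix
#' transpose of the chosen backward-difference operator — a
#' forward-difference divergence with boundary rows matching the zeroed
#' first row/column of the gradient — not an independently discretised
#' divergence.
#'
#' @param p a [vector_field].
#' @return a scalar field \eqn{\nabla^T p} on the same grid.
#' @export
gradient_adjoint <- function(p) {
  if (!inherits(p, "vector_field")) stop("gradient_adjoint: need a vector_field")
  px <- p$x
  py <- p$y
  # row/column 1 of the gradient is identically zero, so the adjoint never
  # reads p there
  px[, 1L] <- 0
  py[1L, ] <- 0
  dx <- px - cbind(px[, -1L, drop = FALSE], 0)
  dy <- py - rbind(py[-1L, , drop = FALSE], 0)
  dx + dy
}

#' Eigenvalues of the discrete Laplacian \eqn{\nabla^T \nabla}
#'
#' Per-frequency symbol of the 5-point \eqn{\nabla^T\nabla} operator under
#' the chosen trigonometric transform. In `"periodic"` (DFT) mode the
#' symbol of the circulant Laplacian is
#' \deqn{2\,(2 - \cos(2\pi k/H) - \cos(2\pi l/W)),}
#' in `"symmetric"` (cosine-transform / Neumann) mode
#' \deqn{2\,(2 - \cos(\pi k/H) - \cos(\pi l/W)).}
#' The zero-frequency entry is exactly 0 (constants are in the null
#' space) and all entries are non-negative.
#'
#' @param shape integer vector `c(H, W)`, both at least 2.
#' @param mode `"periodic"` or `"symmetric"`.
#' @return an `H x W` matrix of non-negative eigenvalues.
#' @export
laplacian_symbol <- function(shape, mode = c("periodic", "symmetric")) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L)) {
    stop("laplacian_symbol: shape must be two dimensions, each >= 2")
  }
  H <- shape[1]
  W <- shape[2]
  step <- if (mode == "periodic") 2 * pi else pi
  sy <- 2 - 2 * cos(step * (seq_len(H) - 1L) / H)
  sx <- 2 - 2 * cos(step * (seq_len(W) - 1L) / W)
  outer(sy, sx, `+`)
}

# half-sample even extension of a matrix to 2H x 2W; restricting the
# periodic solve on the extension to the first block gives the exact
# Neumann solve for the backward-difference normal operator
even_extend <- function(u) {
  H <- nrow(u)
  W <- ncol(u)
  top <- cbind(u, u[, W:1, drop = FALSE])
  rbind(top, top[H:1, , drop = FALSE])
}

solve_periodic <- function(rhs, a, b) {
  sym <- laplacian_symbol(dim(rhs), "periodic")
  Re(stats::fft(stats::fft(rhs) / (a + b * sym), inverse = TRUE)) / length(rhs)
}

#' Screened-Poisson solve \eqn{(a I + b \nabla^T\nabla) x = \mathrm{rhs}}
#'
#' Solves the linear systems at the heart of both players' quadratic
#' sub-problems by diagonalising \eqn{\nabla^T\nabla} with a fast
#' transform: the DFT in `"periodic"` mode, and (equivalently to a
#' DCT-II) a half-sample even extension plus DFT in `"symmetric"` mode.
#' In symmetric mode the operator inverted is exactly
#' `a * x + b * gradient_adjoint(gradient(x))` for the package's
#' backward-difference [gradient()]; in periodic mode it is the circulant
#' 5-point Laplacian, matching the printed DFT update formulas.
#'
#' @param rhs scalar field (right-hand side).
#' @param a strictly positive screening constant (identity weight).
#' @param b non-negative Laplacian weight.
#' @inheritParams laplacian_symbol
#' @return the solution scalar field, to spectral accuracy.
#' @export
solve_screened <- function(rhs, a, b, mode = c("periodic", "symmetric")) {
  mode <- match.arg(mode)
  assert_scalar_field(rhs, "rhs")
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("solve_screened: 'a' must be a positive scalar (a <= 0 makes the ",
         "system singular or indefinite)")
  }
  if (!is.numeric(b) || length(b) != 1L || b < 0) {
    stop("solve_screened: 'b' must be a non-negative scalar")
  }
  if (mode == "periodic") {
    solve_periodic(rhs, a, b)
  } else {
    H <- nrow(rhs)
    W <- ncol(rhs)
    solve_periodic(even_extend(rhs), a, b)[seq_len(H), seq_len(W), drop = FALSE]
  }
}

# periodic Gaussian blur, used only for the optional pre-smoothing of f
# before taking nabla f in the second player's data term
gaussian_blur <- function(u, sigma) {
  if (sigma <= 0) return(u)
  H <- nrow(u)
  W <- ncol(u)
  ky <- c(0:(floor(H / 2)), -((ceiling(H / 2) - 1):1)) / H
  kx <- c(0:(floor(W / 2)), -((ceiling(W / 2) - 1):1)) / W
  ker <- outer(exp(-2 * pi^2 * sigma^2 * ky^2), exp(-2 * pi^2 * sigma^2 * kx^2))
  Re(stats::fft(stats::fft(u) * ker, inverse = TRUE)) / (H * W)
}
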