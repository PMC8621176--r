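#' Solver and model parameters
#'
#' Collects every model weight and algorithm constant used by the
#' two-player game solver and the first-order baseline. All weights act
#' on the native 8-bit intensity scale (images are processed as floats in
#' `[0, 255]` without normalisation, so that noise standard deviations
#' quoted on that scale keep their meaning; rescaling intensities
#' requires rescaling the `lambda` weights accordingly).
#'
#' Player one (the smooth approximation \eqn{g}) minimises
#' \deqn{E_1(g, G) = \tfrac{\lambda_1}{2}\|f-g\|_2^2 +
#'   \tfrac{\mu_1}{2}\|\nabla g\|_2^2 + \|\nabla g\|_1 +
#'   \tfrac{\xi_1}{2}\|G-\nabla g\|_2^2,}
#' player two (the gradient surrogate \eqn{G}) minimises
#' \deqn{E_2(G, g) = \tfrac{\lambda_2}{2}\|\nabla f-G\|_2^2 +
#'   \tfrac{\mu_2}{2}\|\nabla G\|_2^2 + \|\nabla G\|_1 +
#'   \tfrac{\xi_2}{2}\|G-\nabla g\|_2^2.}
#' The L1 terms carry unit weight; `rho1`/`rho2` are the split-Bregman
#' penalty parameters and double as the shrinkage thresholds
#' \eqn{\kappa = 1/\rho}.
#'
#' The game split exists precisely so the two players' weights can be
#' tuned independently. The neutral default sets every weight to 1; for
#' denoising-driven segmentation `lambda1` should scale roughly inversely
#' with the noise level (see [suggest_params()]).
#'
#' @param lambda1,mu1,xi1,rho1 positive weights of the g-player: data
#'   fidelity, quadratic smoothness, coupling to `G`, Bregman penalty.
#' @param lambda2,mu2,xi2,rho2 positive weights of the G-player: gradient
#'   data fidelity, quadratic smoothness of `G`, coupling, Bregman
#'   penalty.
#' @param max_outer maximum number of outer (alternating) iterations.
#' @param tol relative-change stopping threshold on `g`.
#' @param transform_mode `"periodic"` (DFT, matches the printed update
#'   formulas) or `"symmetric"` (cosine transform, consistent with the
#'   zero-Neumann discretisation; with it every linear update is the
#'   exact minimiser of its sub-problem).
#' @param jacobian_norm `"anisotropic"` (component-wise L1 of the full
#'   4-channel Jacobian of `G`; consistent with the solver's shrinkage
#'   step) or `"divergence"` (L1 of \eqn{\nabla_x G_x + \nabla_y G_y};
#'   affects only the reported `E2` diagnostic, never the iteration).
#' @param presmooth_sigma standard deviation (pixels) of an optional
#'   Gaussian blur applied to `f` only where \eqn{\nabla f} feeds the
#'   G-player's data term; 0 (default) differentiates the raw input.
#' @param seed integer seed forwarded to seeded downstream steps
#'   (k-means thresholding); stage one itself is deterministic.
#' @return an object of class `"solver_params"` (a validated named list).
#' @examples
#' p <- solver_params(lambda1 = 0.05, mu1 = 0.1)
#' p$lambda1
#' @export
solver_params <- function(lambda1 = 1, mu1 = 1, xi1 = 1, rho1 = 1,
                          lambda2 = 1, mu2 = 1, xi2 = 1, rho2 = 1,
                          max_outer = 500L, tol = 1e-4,
                          transform_mode = c("periodic", "symmetric"),
                          jacobian_norm = c("anisotropic", "divergence"),
                          presmooth_sigma = 0,
                          seed = 1L) {
  transform_mode <- match.arg(transform_mode)
  jacobian_norm <- match.arg(jacobian_norm)
  p <- list(lambda1 = lambda1, mu1 = mu1, xi1 = xi1, rho1 = rho1,
            lambda2 = lambda2, mu2 = mu2, xi2 = xi2, rho2 = rho2,
            max_outer = as.integer(max_outer), tol = tol,
            transform_mode = transform_mode, jacobian_norm = jacobian_norm,
            presmooth_sigma = presmooth_sigma, seed = as.integer(seed))
  weights <- c("lambda1", "mu1", "xi1", "rho1",
               "lambda2", "mu2", "xi2", "rho2")
  for (w in weights) {
    v <- p[[w]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("solver_params: '", w, "' must be a positive finite scalar")
    }
  }
  if (!is.numeric(p$tol) || p$tol <= 0) stop("solver_params: tol must be > 0")
  if (is.na(p$max_outer) || p$max_outer < 1L) {
    stop("solver_params: max_outer must be >= 1")
  }
  if (!is.numeric(p$presmooth_sigma) || p$presmooth_sigma < 0) {
    stop("solver_params: presmooth_sigma must be >= 0")
  }
  structure(p, class = "solver_params")
}

#' @export
print.solver_params <- function(x, ...) {
  cat("solver_params:\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Suggested parameters for a given noise level
#'
#' The model weights were never published alongside the method, so these
#' are this package's own calibration on piecewise-smooth phantoms: the
#' data weight of the g-player decreases with the noise standard
#' deviation (on the 8-bit scale), the quadratic smoothness terms stay
#' small so that the L1 terms keep edges, and the Bregman penalties sit
#' near the L1 weights for fast shrinkage convergence.
#'
#' @param sigma expected noise standard deviation on the 0-255 scale.
#' @param ... overrides forwarded to [solver_params()].
#' @return a `"solver_params"` object.
#' @export
suggest_params <- function(sigma, ...) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  lam <- 2 / (1 + max(sigma, 1))
  defaults <- list(lambda1 = lam, mu1 = 0.05, xi1 = 0.1, rho1 = 0.1,
                   lambda2 = 0.1, mu2 = 0.05, xi2 = 0.1, rho2 = 0.1)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(solver_params, defaults)
}

# flat key=value serialisation -------------------------------------------

#' Read or write a flat key-value parameter file
#'
#' One `key = value` pair per line, keys exactly the field names of
#' [solver_params()]; blank lines and `#` comments are ignored. Unknown
#' keys are an error so that typos never silently fall back to defaults.
#'
#' @param path file path.
#' @param params a `"solver_params"` object.
#' @return `read_params()` returns a `"solver_params"` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("read_params: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("read_params: malformed line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(solver_params))
  if (any(!keys %in% known)) {
    stop("read_params: unknown key(s): ",
         paste(setdiff(keys, known), collapse = ", "))
  }
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- setdiff(known, c("transform_mode", "jacobian_norm"))
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  do.call(solver_params, args)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "solver_params"))
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    sprintf("%s = %s", k,
            if (is.character(v)) v else format(v, digits = 17))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# energies ----------------------------------------------------------------

l2sq <- function(a) sum(field_flat(a)^2)

iso_l1 <- function(v) sum(sqrt(v$x^2 + v$y^2))

jacobian <- function(G) jacobian_field(gradient(G$x), gradient(G$y))

jac_l1 <- function(J, which = c("anisotropic", "divergence")) {
  which <- match.arg(which)
  if (which == "anisotropic") {
    sum(abs(J$dGx$x)) + sum(abs(J$dGx$y)) + sum(abs(J$dGy$x)) + sum(abs(J$dGy$y))
  } else {
    sum(abs(J$dGx$x + J$dGy$y))
  }
}

check_same_shape <- function(a, b, what) {
  if (!identical(field_shape(a), field_shape(b))) {
    stop(what, ": shape mismatch")
  }
}

#' Player energies and the first-order baseline energy
#'
#' `energy_e1()` and `energy_e2()` evaluate the two coupled convex
#' energies of the game (see [solver_params()] for the formulas);
#' `energy_ccz()` evaluates the first-order two-stage baseline
#' \eqn{\tfrac{\lambda}{2}\|f-g\|_2^2 + \tfrac{\mu}{2}\|\nabla g\|_2^2 +
#' \|\nabla g\|_1}, reusing `lambda1`/`mu1` as its two weights.
#' \eqn{\|\nabla g\|_1} is the isotropic sum
#' \eqn{\sum_i \sqrt{(\nabla_x g)_i^2 + (\nabla_y g)_i^2}};
#' \eqn{\|\nabla G\|_1} follows `params$jacobian_norm`. These are
#' diagnostics: the solver never evaluates them to iterate.
#'
#' @param g scalar field, the smooth approximation.
#' @param G [vector_field], the gradient surrogate.
#' @param f scalar field, the observed image.
#' @param params a [solver_params()] object.
#' @return a single non-negative number.
#' @export
energy_e1 <- function(g, G, f, params) {
  assert_scalar_field(g, "g")
  check_same_shape(g, f, "energy_e1")
  check_same_shape(g, G, "energy_e1")
  dg <- gradient(g)
  params$lambda1 / 2 * l2sq(f - g) +
    params$mu1 / 2 * l2sq(dg) +
    iso_l1(dg) +
    params$xi1 / 2 * l2sq(field_sub(G, dg))
}

#' @rdname energy_e1
#' @export
energy_e2 <- function(G, g, f, params) {
  check_same_shape(G, g, "energy_e2")
  check_same_shape(G, f, "energy_e2")
  df <- gradient(if (params$presmooth_sigma > 0)
    gaussian_blur(f, params$presmooth_sigma) else f)
  dG <- jacobian(G)
  params$lambda2 / 2 * l2sq(field_sub(df, G)) +
    params$mu2 / 2 * l2sq(dG) +
    jac_l1(dG, params$jacobian_norm) +
    params$xi2 / 2 * l2sq(field_sub(G, gradient(g)))
}

#' @rdname energy_e1
#' @export
energy_ccz <- function(g, f, params) {
  assert_scalar_field(g, "g")
  check_same_shape(g, f, "energy_ccz")
  dg <- gradient(g)
  params$lambda1 / 2 * l2sq(f - g) +
    params$mu1 / 2 * l2sq(dg) +
    iso_l1(dg)
}
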