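#' @rdname run_game
#' @param g,G,v,b1,w,b2 solver variables; see Details.
#' @param iteration outer-iteration counter.
#' @export
game_state <- function(g, G, v, b1, w, b2, iteration = 0L) {
  shape <- field_shape(g)
  for (fld in list(G, v, b1, w, b2)) {
    if (!identical(field_shape(fld), shape)) {
      stop("game_state: all fields must share one grid shape")
    }
  }
  structure(list(g = g, G = G, v = v, b1 = b1, w = w, b2 = b2,
                 iteration = as.integer(iteration)),
            class = "game_state")
}

#' One linear update of the g-player
#'
#' Exact minimiser of the augmented g sub-problem: solves
#' \deqn{(\lambda_1 I + (\mu_1+\xi_1+\rho_1)\nabla^T\nabla)\,g =
#'   \lambda_1 f + \xi_1 \nabla^T G + \rho_1 \nabla^T(v - b_1)}
#' via [solve_screened()] in the configured transform mode.
#'
#' @param state a [game_state()] holding the current iterates.
#' @param f the observed image (scalar field).
#' @param params a [solver_params()] object.
#' @return the updated scalar field `g`.
#' @export
update_g <- function(state, f, params) {
  if (params$lambda1 <= 0) stop("update_g: lambda1 must be positive")
  rhs <- params$lambda1 * f +
    params$xi1 * gradient_adjoint(state$G) +
    params$rho1 * gradient_adjoint(field_sub(state$v, state$b1))
  solve_screened(rhs, params$lambda1,
                 params$mu1 + params$xi1 + params$rho1,
                 params$transform_mode)
}

#' Shrinkage (proximal) operators of the L1 terms
#'
#' `shrink_isotropic()` is the closed-form solution of
#' \eqn{\arg\min_v \kappa\|v\|_{2,1} + \tfrac12\|v - s\|_2^2} applied per
#' pixel: with magnitude \eqn{m = \sqrt{s_x^2 + s_y^2}}, the output is
#' \eqn{\max(m-\kappa,0)\,(s_x,s_y)/m} and exactly \eqn{(0,0)} where
#' \eqn{m = 0}. `shrink_anisotropic()` soft-thresholds each of the four
#' Jacobian channels independently:
#' \eqn{\mathrm{sign}(r)\max(|r|-\kappa, 0)}. In the solver
#' \eqn{\kappa = 1/\rho_1} (resp. \eqn{1/\rho_2}) because the L1 terms
#' carry unit weight.
#'
#' @param s a [vector_field] (typically \eqn{\nabla g + b_1}).
#' @param r a [jacobian_field] (typically \eqn{\nabla G + b_2}).
#' @param kappa positive threshold.
#' @return a field of the same kind as the input.
#' @export
shrink_isotropic <- function(s, kappa) {
  if (!inherits(s, "vector_field")) stop("shrink_isotropic: need a vector_field")
  if (!is.numeric(kappa) || kappa <= 0) stop("shrink_isotropic: kappa must be > 0")
  m <- sqrt(s$x^2 + s$y^2)
  scale <- ifelse(m > 0, pmax(m - kappa, 0) / m, 0)
  vector_field(scale * s$x, scale * s$y)
}

#' @rdname shrink_isotropic
#' @export
shrink_anisotropic <- function(r, kappa) {
  if (!inherits(r, "jacobian_field")) {
    stop("shrink_anisotropic: need a jacobian_field")
  }
  if (!is.numeric(kappa) || kappa <= 0) {
    stop("shrink_anisotropic: kappa must be > 0")
  }
  soft <- function(x) sign(x) * pmax(abs(x) - kappa, 0)
  jacobian_field(vector_field(soft(r$dGx$x), soft(r$dGx$y)),
                 vector_field(soft(r$dGy$x), soft(r$dGy$y)))
}

#' One linear update of the G-player
#'
#' Each component of `G` solves the screened system
#' \deqn{((\lambda_2+\xi_2) I + (\mu_2+\rho_2)\nabla^T\nabla)\,G_c =
#'   [\lambda_2 \nabla f + \xi_2 \nabla g + \rho_2 \nabla^T(w - b_2)]_c}
#' via [solve_screened()], applied component-wise. If
#' `params$presmooth_sigma > 0`, \eqn{\nabla f} is taken on a
#' Gaussian-blurred copy of `f` (differentiating very noisy input is
#' otherwise violent); the default differentiates the raw image.
#'
#' @inheritParams update_g
#' @return the updated [vector_field] `G`.
#' @export
update_G <- function(state, f, params) {
  a <- params$lambda2 + params$xi2
  if (a <= 0) stop("update_G: lambda2 + xi2 must be positive")
  b <- params$mu2 + params$rho2
  df <- gradient(if (params$presmooth_sigma > 0)
    gaussian_blur(f, params$presmooth_sigma) else f)
  dg <- gradient(state$g)
  wb <- field_sub(state$w, state$b2)
  rhs_x <- params$lambda2 * df$x + params$xi2 * dg$x +
    params$rho2 * gradient_adjoint(wb$dGx)
  rhs_y <- params$lambda2 * df$y + params$xi2 * dg$y +
    params$rho2 * gradient_adjoint(wb$dGy)
  vector_field(solve_screened(rhs_x, a, b, params$transform_mode),
               solve_screened(rhs_y, a, b, params$transform_mode))
}

#' Bregman (dual) update
#'
#' Accumulates the residual of the split constraint:
#' `b + target - auxiliary`, component-wise, where `target` is the
#' constrained derivative (\eqn{\nabla g} or \eqn{\nabla G}) and
#' `auxiliary` the split variable (`v` or `w`). Works on
#' [vector_field] and [jacobian_field] alike.
#'
#' @param b,target,auxiliary fields of one common kind and shape.
#' @return the updated field, same kind as `b`.
#' @export
bregman_update <- function(b, target, auxiliary) {
  field_add(b, field_sub(target, auxiliary))
}

# augmented (split-Bregman) sub-problem objectives, used for the descent
# diagnostics; the quadratic terms only are affected by the linear updates
aug_objective_g <- function(g, state, f, params) {
  dg <- gradient(g)
  params$lambda1 / 2 * l2sq(f - g) +
    params$mu1 / 2 * l2sq(dg) +
    params$xi1 / 2 * l2sq(field_sub(state$G, dg)) +
    params$rho1 / 2 * l2sq(field_sub(field_sub(state$v, dg), state$b1))
}

aug_objective_G <- function(G, state, f, params) {
  df <- gradient(if (params$presmooth_sigma > 0)
    gaussian_blur(f, params$presmooth_sigma) else f)
  dG <- jacobian(G)
  params$lambda2 / 2 * l2sq(field_sub(df, G)) +
    params$mu2 / 2 * l2sq(dG) +
    params$xi2 / 2 * l2sq(field_sub(G, gradient(state$g))) +
    params$rho2 / 2 * l2sq(field_sub(field_sub(state$w, dG), state$b2))
}

check_finite_step <- function(x, step) {
  if (!field_finite(x)) {
    stop("numerical divergence in step '", step,
         "' (non-finite values); reduce weights or check the input")
  }
  x
}

new_solve_report <- function(iterations_run, relative_changes,
                             E1_trace, E2_trace, converged, diagnostics = NULL) {
  structure(list(iterations_run = iterations_run,
                 relative_changes = relative_changes,
                 E1_trace = E1_trace, E2_trace = E2_trace,
                 converged = converged, diagnostics = diagnostics),
            class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("solve_report: %d iteration(s), %s (last rel. change %.3g)\n",
              x$iterations_run,
              if (x$converged) "converged" else "NOT converged",
              if (x$iterations_run > 0)
                x$relative_changes[x$iterations_run] else NA_real_))
  invisible(x)
}

#' Stage one: alternating split-Bregman solver for the two-player game
#'
#' Computes the Nash equilibrium of the coupled convex energies
#' \eqn{E_1(g, G)} and \eqn{E_2(G, g)} (see [solver_params()]) by one
#' Gauss-Seidel sweep per player per outer iteration:
#' [update_g()] \eqn{\to} isotropic shrinkage of \eqn{\nabla g + b_1}
#' giving `v` \eqn{\to} Bregman update of `b1` \eqn{\to} [update_G()]
#' \eqn{\to} anisotropic shrinkage of \eqn{\nabla G + b_2} giving `w`
#' \eqn{\to} Bregman update of `b2`. Initialisation is \eqn{g = f} with
#' all other variables zero. Iteration stops when *both* players are
#' stationary — the larger of the relative changes
#' \eqn{\|g^{(k+1)}-g^{(k)}\|/\|g^{(k)}\|} and
#' \eqn{\|G^{(k+1)}-G^{(k)}\|/\|G^{(k)}\|} drops to `params$tol` — or
#' after `params$max_outer` sweeps; a Nash equilibrium is a fixed point
#' of both players, and monitoring `g` alone leaves the much smaller
#' field `G` visibly non-stationary at stopping time. The whole of
#' stage one is deterministic: identical `f` and `params` reproduce `g`
#' bit for bit.
#'
#' @param f the observed image as a numeric matrix on the 0-255 scale.
#' @param params a [solver_params()] object.
#' @param diagnostics if `TRUE`, record the augmented sub-problem
#'   objectives of each player before and after its own linear update
#'   (descent certificates) in `report$diagnostics`.
#' @return a list with components `state` (a `"game_state"`: final `g`,
#'   `G`, split and Bregman variables) and `report` (a `"solve_report"`:
#'   iteration count, relative changes, `E1`/`E2` traces, convergence
#'   flag).
#' @examples
#' f <- matrix(100, 16, 16)
#' out <- run_game(f, solver_params(max_outer = 5))
#' out$report$converged
#' max(abs(out$state$g - f)) < 1e-8
#' @export
run_game <- function(f, params, diagnostics = FALSE) {
  assert_scalar_field(f, "f")
  if (!field_finite(f)) stop("run_game: f must be finite")
  stopifnot(inherits(params, "solver_params"))
  shape <- dim(f)
  state <- game_state(g = f, G = zero_vector(shape), v = zero_vector(shape),
                      b1 = zero_vector(shape), w = zero_jacobian(shape),
                      b2 = zero_jacobian(shape))
  rel <- E1 <- E2 <- numeric(0)
  diag_list <- if (diagnostics) {
    list(aug_g_before = numeric(0), aug_g_after = numeric(0),
         aug_G_before = numeric(0), aug_G_after = numeric(0))
  }
  converged <- FALSE
  denom_floor <- sqrt(.Machine$double.eps)
  for (k in seq_len(params$max_outer)) {
    g_old <- state$g
    G_old <- state$G
    if (diagnostics) {
      diag_list$aug_g_before <- c(diag_list$aug_g_before,
                                  aug_objective_g(g_old, state, f, params))
    }
    state$g <- check_finite_step(update_g(state, f, params), "update_g")
    if (diagnostics) {
      diag_list$aug_g_after <- c(diag_list$aug_g_after,
                                 aug_objective_g(state$g, state, f, params))
    }
    dg <- gradient(state$g)
    state$v <- check_finite_step(
      shrink_isotropic(field_add(dg, state$b1), 1 / params$rho1), "shrink_v")
    state$b1 <- bregman_update(state$b1, dg, state$v)
    if (diagnostics) {
      diag_list$aug_G_before <- c(diag_list$aug_G_before,
                                  aug_objective_G(state$G, state, f, params))
    }
    state$G <- check_finite_step(update_G(state, f, params), "update_G")
    if (diagnostics) {
      diag_list$aug_G_after <- c(diag_list$aug_G_after,
                                 aug_objective_G(state$G, state, f, params))
    }
    dG <- jacobian(state$G)
    state$w <- check_finite_step(
      shrink_anisotropic(field_add(dG, state$b2), 1 / params$rho2), "shrink_w")
    state$b2 <- bregman_update(state$b2, dG, state$w)
    state$iteration <- k
    rel_g <- field_norm(state$g - g_old) / max(field_norm(g_old), denom_floor)
    rel_G <- field_norm(field_sub(state$G, G_old)) /
      max(field_norm(G_old), denom_floor)
    rel_k <- max(rel_g, rel_G)
    rel <- c(rel, rel_k)
    E1 <- c(E1, energy_e1(state$g, state$G, f, params))
    E2 <- c(E2, energy_e2(state$G, state$g, f, params))
    if (rel_k <= params$tol) {
      converged <- TRUE
      break
    }
  }
  list(state = state,
       report = new_solve_report(state$iteration, rel, E1, E2, converged,
                                 diag_list))
}

#' Stage one baseline: first-order two-stage model
#'
#' Solves the convex first-order (Mumford-Shah-type) smoothing problem
#' \eqn{\min_g \tfrac{\lambda}{2}\|f-g\|_2^2 +
#' \tfrac{\mu}{2}\|\nabla g\|_2^2 + \|\nabla g\|_1}
#' with the same split-Bregman machinery as [run_game()] but a single
#' player: the g-update runs with the coupling weight \eqn{\xi_1}
#' effectively 0 and no `G`/`w` steps. `lambda1`/`mu1`/`rho1` of
#' `params` supply \eqn{\lambda}/\eqn{\mu}/\eqn{\rho}.
#'
#' @inheritParams run_game
#' @return a list with components `g` (the smooth minimiser) and
#'   `report` (a `"solve_report"`; `E1_trace` carries the
#'   [energy_ccz()] trace and `E2_trace` is empty).
#' @export
run_ccz <- function(f, params, diagnostics = FALSE) {
  assert_scalar_field(f, "f")
  if (!field_finite(f)) stop("run_ccz: f must be finite")
  stopifnot(inherits(params, "solver_params"))
  shape <- dim(f)
  g <- f
  v <- b1 <- zero_vector(shape)
  rel <- Ecz <- numeric(0)
  converged <- FALSE
  denom_floor <- sqrt(.Machine$double.eps)
  iters <- 0L
  for (k in seq_len(params$max_outer)) {
    g_old <- g
    rhs <- params$lambda1 * f + params$rho1 * gradient_adjoint(field_sub(v, b1))
    g <- check_finite_step(
      solve_screened(rhs, params$lambda1, params$mu1 + params$rho1,
                     params$transform_mode), "update_g")
    dg <- gradient(g)
    v <- shrink_isotropic(field_add(dg, b1), 1 / params$rho1)
    b1 <- bregman_update(b1, dg, v)
    iters <- k
    rel_k <- field_norm(g - g_old) / max(field_norm(g_old), denom_floor)
    rel <- c(rel, rel_k)
    Ecz <- c(Ecz, energy_ccz(g, f, params))
    if (rel_k <= params$tol) {
      converged <- TRUE
      break
    }
  }
  list(g = g,
       report = new_solve_report(iters, rel, Ecz, numeric(0), converged))
}
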