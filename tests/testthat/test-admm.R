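# dense oracles for the two linear updates, assembled per transform mode
dense_update_g <- function(state, f, p) {
  H <- nrow(f); W <- ncol(f)
  L <- laplacian_matrix(H, W, p$transform_mode)
  M <- p$lambda1 * diag(H * W) + (p$mu1 + p$xi1 + p$rho1) * L
  rhs <- p$lambda1 * f + p$xi1 * gradient_adjoint(state$G) +
    p$rho1 * gradient_adjoint(vector_field(state$v$x - state$b1$x,
                                           state$v$y - state$b1$y))
  matrix(solve(M, as.vector(rhs)), H, W)
}

dense_update_G <- function(state, f, p) {
  H <- nrow(f); W <- ncol(f)
  L <- laplacian_matrix(H, W, p$transform_mode)
  M <- (p$lambda2 + p$xi2) * diag(H * W) + (p$mu2 + p$rho2) * L
  df <- gradient(f)
  dg <- gradient(state$g)
  comp <- function(dfc, dgc, wc, bc) {
    rhs <- p$lambda2 * dfc + p$xi2 * dgc +
      p$rho2 * gradient_adjoint(vector_field(wc$x - bc$x, wc$y - bc$y))
    matrix(solve(M, as.vector(rhs)), H, W)
  }
  vector_field(comp(df$x, dg$x, state$w$dGx, state$b2$dGx),
               comp(df$y, dg$y, state$w$dGy, state$b2$dGy))
}

test_that("update_g solves the printed linear system exactly", {
  f0 <- matrix(9, 8, 8)
  st <- game_state(g = f0, G = vector_field(matrix(0, 8, 8), matrix(0, 8, 8)),
                   v = vector_field(matrix(0, 8, 8), matrix(0, 8, 8)),
                   b1 = vector_field(matrix(0, 8, 8), matrix(0, 8, 8)),
                   w = jacobian_field(vector_field(matrix(0, 8, 8),
                                                   matrix(0, 8, 8)),
                                      vector_field(matrix(0, 8, 8),
                                                   matrix(0, 8, 8))),
                   b2 = jacobian_field(vector_field(matrix(0, 8, 8),
                                                    matrix(0, 8, 8)),
                                       vector_field(matrix(0, 8, 8),
                                                    matrix(0, 8, 8))))
  for (mode in c("periodic", "symmetric")) {
    p <- solver_params(transform_mode = mode)
    expect_equal(update_g(st, f0, p), f0, tolerance = 1e-12)
  }

  set.seed(6)
  for (mode in c("periodic", "symmetric")) {
    p <- solver_params(lambda1 = 0.8, mu1 = 1.7, xi1 = 0.3, rho1 = 2.2,
                       transform_mode = mode)
    st <- rand_state(8, 8)
    f <- rand_field(8, 8)
    g_new <- update_g(st, f, p)
    expect_equal(g_new, dense_update_g(st, f, p), tolerance = 1e-8)
  }
})

test_that("update_g is the minimiser of its sub-problem (symmetric mode)", {
  set.seed(7)
  p <- solver_params(lambda1 = 0.8, mu1 = 0.5, xi1 = 0.4, rho1 = 1.1,
                     transform_mode = "symmetric")
  st <- rand_state(8, 8)
  f <- rand_field(8, 8)
  # quadratic sub-problem objective, written out independently
  obj <- function(g) {
    dg <- gradient(g)
    p$lambda1 / 2 * sum((f - g)^2) + p$mu1 / 2 * sum(dg$x^2 + dg$y^2) +
      p$xi1 / 2 * sum((st$G$x - dg$x)^2 + (st$G$y - dg$y)^2) +
      p$rho1 / 2 * sum((st$v$x - dg$x - st$b1$x)^2 +
                         (st$v$y - dg$y - st$b1$y)^2)
  }
  g_new <- update_g(st, f, p)
  base <- obj(g_new)
  for (i in 1:100) {
    expect_lt(base, obj(g_new + rand_field(8, 8, sd = 0.1)))
  }
})

test_that("shrinkage operators match the numerical proximal oracles", {
  z <- vector_field(matrix(0, 4, 4), matrix(0, 4, 4))
  out <- shrink_isotropic(z, 1)
  expect_equal(out$x, matrix(0, 4, 4))
  expect_equal(out$y, matrix(0, 4, 4))

  s <- vector_field(matrix(3, 1, 1), matrix(4, 1, 1))
  out <- shrink_isotropic(s, 1)
  expect_equal(out$x[1, 1], 2.4)
  expect_equal(out$y[1, 1], 3.2)

  jz <- jacobian_field(z, z)
  outj <- shrink_anisotropic(jz, 1)
  expect_equal(outj$dGx$x, matrix(0, 4, 4))
  r <- jacobian_field(vector_field(matrix(2.5, 1, 1), matrix(-0.5, 1, 1)),
                      vector_field(matrix(0, 1, 1), matrix(-3, 1, 1)))
  outj <- shrink_anisotropic(r, 1)
  expect_equal(outj$dGx$x[1, 1], 1.5)
  expect_equal(outj$dGx$y[1, 1], 0)
  expect_equal(outj$dGy$y[1, 1], -2)

  set.seed(8)
  for (kappa in c(0.1, 1, 10)) {
    sx <- rnorm(70, sd = 3); sy <- rnorm(70, sd = 3)
    got <- shrink_isotropic(vector_field(matrix(sx, 7), matrix(sy, 7)), kappa)
    for (i in seq_along(sx)) {
      ref <- prox_iso_numeric(c(sx[i], sy[i]), kappa)
      expect_equal(c(as.vector(got$x)[i], as.vector(got$y)[i]), ref,
                   tolerance = 1e-6)
    }
    rv <- rnorm(70, sd = 3)
    gotj <- shrink_anisotropic(
      jacobian_field(vector_field(matrix(rv, 7), matrix(rv, 7)),
                     vector_field(matrix(rv, 7), matrix(rv, 7))), kappa)
    for (i in seq_along(rv)) {
      expect_equal(as.vector(gotj$dGx$x)[i], prox_aniso_numeric(rv[i], kappa),
                   tolerance = 1e-6)
    }
  }
  expect_error(shrink_isotropic(z, 0), "kappa")
  expect_error(shrink_anisotropic(jz, -1), "kappa")
})

test_that("update_G solves its linear system and decreases its objective", {
  set.seed(9)
  for (mode in c("periodic", "symmetric")) {
    p <- solver_params(lambda2 = 0.6, mu2 = 1.4, xi2 = 0.9, rho2 = 0.7,
                       transform_mode = mode)
    st <- rand_state(8, 8)
    f <- rand_field(8, 8)
    G_new <- update_G(st, f, p)
    ref <- dense_update_G(st, f, p)
    expect_equal(G_new$x, ref$x, tolerance = 1e-8)
    expect_equal(G_new$y, ref$y, tolerance = 1e-8)
  }

  # zero RHS: constant f and g, zero splits
  f0 <- matrix(5, 8, 8)
  st <- rand_state(8, 8)
  st$g <- f0
  st$w <- jacobian_field(vector_field(matrix(0, 8, 8), matrix(0, 8, 8)),
                         vector_field(matrix(0, 8, 8), matrix(0, 8, 8)))
  st$b2 <- st$w
  p <- solver_params()
  G_new <- update_G(st, f0, p)
  expect_equal(G_new$x, matrix(0, 8, 8))
  expect_equal(G_new$y, matrix(0, 8, 8))

  # descent of the augmented G objective (symmetric mode is exact)
  p <- solver_params(transform_mode = "symmetric")
  st <- rand_state(8, 8)
  f <- rand_field(8, 8)
  obj <- function(G) {
    df <- gradient(f)
    dGx <- gradient(G$x); dGy <- gradient(G$y)
    p$lambda2 / 2 * sum((df$x - G$x)^2 + (df$y - G$y)^2) +
      p$mu2 / 2 * sum(dGx$x^2 + dGx$y^2 + dGy$x^2 + dGy$y^2) +
      p$xi2 / 2 * sum((G$x - gradient(st$g)$x)^2 +
                        (G$y - gradient(st$g)$y)^2) +
      p$rho2 / 2 * sum((st$w$dGx$x - dGx$x - st$b2$dGx$x)^2 +
                         (st$w$dGx$y - dGx$y - st$b2$dGx$y)^2 +
                         (st$w$dGy$x - dGy$x - st$b2$dGy$x)^2 +
                         (st$w$dGy$y - dGy$y - st$b2$dGy$y)^2)
  }
  expect_lt(obj(update_G(st, f, p)), obj(st$G))
})

test_that("bregman_update accumulates the constraint residual", {
  z <- vector_field(matrix(1, 3, 3), matrix(1, 3, 3))
  t3 <- vector_field(matrix(3, 3, 3), matrix(3, 3, 3))
  a2 <- vector_field(matrix(2, 3, 3), matrix(2, 3, 3))
  out <- bregman_update(z, t3, a2)
  expect_equal(out$x, matrix(2, 3, 3))
  out0 <- bregman_update(vector_field(matrix(0, 3, 3), matrix(0, 3, 3)),
                         t3, t3)
  expect_equal(out0$x, matrix(0, 3, 3))
  jf <- jacobian_field(z, z)
  outj <- bregman_update(jf, jacobian_field(t3, t3), jacobian_field(a2, a2))
  expect_equal(outj$dGy$y, matrix(2, 3, 3))
  expect_error(bregman_update(z, t3, vector_field(matrix(0, 2, 2),
                                                  matrix(0, 2, 2))),
               "shape")
})

test_that("run_game: constant fixed point, determinism, descent, residuals", {
  f <- matrix(77, 16, 16)
  out <- run_game(f, solver_params())
  expect_lte(out$report$iterations_run, 2L)
  expect_true(out$report$converged)
  expect_equal(out$state$g, f, tolerance = 1e-12)
  expect_equal(out$state$G$x, matrix(0, 16, 16), tolerance = 1e-10)
  expect_equal(out$state$v$x, matrix(0, 16, 16), tolerance = 1e-10)

  fx <- fixture_two_phase(shape = c(64L, 64L), sigma = 25, seed = 11L)
  p <- suggest_params(25)
  r1 <- run_game(fx$noisy, p)
  r2 <- run_game(fx$noisy, p)
  expect_identical(r1$state$g, r2$state$g)   # bit-identical
  expect_identical(r1$state$G, r2$state$G)

  expect_true(r1$report$converged)
  expect_lte(r1$report$relative_changes[r1$report$iterations_run], p$tol)
  # E1+E2 strictly below its value at the initialisation (g = f, G = 0)
  init <- energy_e1(fx$noisy,
                    vector_field(matrix(0, 64, 64), matrix(0, 64, 64)),
                    fx$noisy, p) +
    energy_e2(vector_field(matrix(0, 64, 64), matrix(0, 64, 64)),
              fx$noisy, fx$noisy, p)
  final <- energy_e1(r1$state$g, r1$state$G, fx$noisy, p) +
    energy_e2(r1$state$G, r1$state$g, fx$noisy, p)
  expect_lt(final, init)

  # split-constraint residual shrinks below its value after iteration 1
  p1 <- suggest_params(25, max_outer = 1)
  first <- run_game(fx$noisy, p1)
  res_of <- function(st) {
    dg <- gradient(st$g)
    sqrt(sum((dg$x - st$v$x)^2 + (dg$y - st$v$y)^2))
  }
  expect_lt(res_of(r1$state), res_of(first$state))

  expect_error(run_game(matrix(c(1, NA, 2, 3), 2, 2), p), "finite")
})

test_that("run_ccz converges and respects the data-term limit", {
  f <- matrix(12, 16, 16)
  out <- run_ccz(f, solver_params())
  expect_equal(out$g, f, tolerance = 1e-12)

  fx <- fixture_two_phase(shape = c(32L, 32L), sigma = 25, seed = 13L)
  p_big <- solver_params(lambda1 = 1e4, mu1 = 0.05, rho1 = 0.1,
                         max_outer = 200)
  out <- run_ccz(fx$noisy, p_big)
  expect_lt(sqrt(sum((out$g - fx$noisy)^2)) / sqrt(sum(fx$noisy^2)), 0.01)

  p <- suggest_params(25)
  out <- run_ccz(fx$noisy, p)
  expect_lt(energy_ccz(out$g, fx$noisy, p),
            energy_ccz(fx$noisy, fx$noisy, p))
})
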