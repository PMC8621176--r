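# Independent dense-matrix oracles for the discrete operators.
# Fields are vectorised column-major (R's as.vector), pixel (i, j) -> (j-1)*H + i.

# 1-D backward difference with zeroed first row (Neumann/replicate)
diff1d_neumann <- function(n) {
  B <- diag(n)
  B[cbind(2:n, 1:(n - 1))] <- -1
  B[1, 1] <- 0
  B
}

# 1-D backward difference with periodic wrap
diff1d_periodic <- function(n) {
  C <- diag(n)
  C[cbind(2:n, 1:(n - 1))] <- -1
  C[1, n] <- -1
  C
}

# 2-D difference operators as dense matrices on the flattened field
grad_matrices <- function(H, W, mode = c("neumann", "periodic")) {
  mode <- match.arg(mode)
  B <- if (mode == "neumann") diff1d_neumann else diff1d_periodic
  list(Dx = kronecker(B(W), diag(H)),   # along columns (x)
       Dy = kronecker(diag(W), B(H)))   # along rows (y)
}

# dense grad^T grad in either boundary convention
laplacian_matrix <- function(H, W, mode) {
  m <- if (mode == "periodic") "periodic" else "neumann"
  D <- grad_matrices(H, W, m)
  t(D$Dx) %*% D$Dx + t(D$Dy) %*% D$Dy
}

rand_field <- function(H, W, sd = 1) matrix(rnorm(H * W, sd = sd), H, W)

rand_vfield <- function(H, W) vector_field(rand_field(H, W), rand_field(H, W))

rand_jfield <- function(H, W) {
  jacobian_field(rand_vfield(H, W), rand_vfield(H, W))
}

rand_state <- function(H, W) {
  game_state(g = rand_field(H, W), G = rand_vfield(H, W),
             v = rand_vfield(H, W), b1 = rand_vfield(H, W),
             w = rand_jfield(H, W), b2 = rand_jfield(H, W))
}

# numerical proximal oracles (independent of the shrinkage formulas):
# isotropic: argmin_v kappa*||v||_2 + 0.5*||v - s||^2 over v in R^2
prox_iso_numeric <- function(s, kappa) {
  fn <- function(v) kappa * sqrt(sum(v^2)) + 0.5 * sum((v - s)^2)
  best <- c(0, 0)
  for (start in list(s, s / 2, c(0, 0) + 1e-3)) {
    o <- optim(start, fn, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
    if (o$value < fn(best)) best <- o$par
  }
  if (fn(c(0, 0)) <= fn(best)) best <- c(0, 0)
  best
}

# anisotropic: argmin_w kappa*|w| + 0.5*(w - r)^2 over w in R
prox_aniso_numeric <- function(r, kappa) {
  fn <- function(w) kappa * abs(w) + 0.5 * (w - r)^2
  o <- optimize(fn, interval = c(-abs(r) - 1, abs(r) + 1), tol = 1e-10)
  if (fn(0) <= o$objective) 0 else o$minimum
}

# md5 of an in-memory object, via its serialised bytes on disk
object_md5 <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

# standard two-phase / four-phase noisy phantom fixtures
fixture_two_phase <- function(shape = c(64L, 64L), sigma = 25, seed = 11L) {
  sp <- phantom_spec(shape = shape, intensity_levels = c(100, 140),
                     gradient_amplitude = 20, contrast_gap = 30, seed = seed)
  ph <- make_phantom(sp)
  list(clean = ph$clean, labels = ph$labels,
       noisy = add_noise(ph$clean, sigma, seed = seed + 1L))
}
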