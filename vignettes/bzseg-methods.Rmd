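---
title: "bzseg: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bzseg: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzseg)
```

## The problem and the model

Segmenting an image whose regions have *piecewise-smooth* intensities
and *low contrast* defeats two standard tool families at once:
piecewise-constant models (Chan–Vese and relatives) split a shaded
region into spurious phases, and first-order smoothness (Mumford–Shah
type) staircases intensity ramps and blurs weak gradient
discontinuities. Second-order (Blake–Zisserman type) regularisation
penalises the Hessian off two discontinuity sets — intensity edges and
gradient edges — but is not directly computable.

`bzseg` implements a convex relaxation of that second-order idea. The
boundary-length terms are replaced by L1 norms of first differences,
and the fourth-order problem in the smooth approximation $g$ is split
by introducing a surrogate $G \approx \nabla g$, giving two coupled
convex energies

$$E_1(g, G) = \tfrac{\lambda_1}{2}\|f-g\|_2^2 +
  \tfrac{\mu_1}{2}\|\nabla g\|_2^2 + \|\nabla g\|_1 +
  \tfrac{\xi_1}{2}\|G-\nabla g\|_2^2,$$

$$E_2(G, g) = \tfrac{\lambda_2}{2}\|\nabla f-G\|_2^2 +
  \tfrac{\mu_2}{2}\|\nabla G\|_2^2 + \|\nabla G\|_1 +
  \tfrac{\xi_2}{2}\|G-\nabla g\|_2^2,$$

treated as a two-player Nash game: a pair $(g^*, G^*)$ at which neither
energy can be improved unilaterally. Each energy is strictly convex in
its own variable, which yields existence and uniqueness of the
equilibrium and is the property the package certifies *numerically*: at
convergence one extra update of either player moves its variable by
less than $10\,\mathrm{tol}$ in relative norm (the fixed-point
certificate in the acceptance suite). The theory itself
(function-space analysis, the existence proof) is outside the scope of
the package.

$\|\nabla g\|_1$ is the isotropic norm
$\sum_i \sqrt{(\nabla_x g)_i^2 + (\nabla_y g)_i^2}$ — the matching
shrinkage step is the generalised (vectorial) one. For $\|\nabla G\|_1$
two readings circulate: a divergence-like scalar
$\sum_i |(\nabla_x G_x)_i + (\nabla_y G_y)_i|$, and the component-wise
L1 of the full four-channel Jacobian. The solver's own G-update applies
$(\mu_2+\rho_2)\nabla^T\nabla$ component-wise and shrinks all four
Jacobian channels independently, which is only consistent with the
Jacobian reading; `bzseg` therefore defaults to
`jacobian_norm = "anisotropic"` and offers the divergence form purely
as an alternative *diagnostic* (it never changes the iteration).

**Stage two** thresholds $g$: manually (`threshold_binary()`,
`apply_thresholds()`) or via seeded 1-D k-means on the intensities
(`kmeans_thresholds()`, cluster-centre midpoints as cuts). Because
stage two reads only $g$, any number of thresholds can be tried without
re-solving — the package enforces and tests this separation
byte-for-byte.

## Numerical scheme

Each outer iteration performs one split-Bregman sweep per player, in
the order: $g$-solve, isotropic shrinkage giving $v$, Bregman update of
$b_1$, $G$-solve, anisotropic shrinkage giving $w$, Bregman update of
$b_2$. The linear solves are screened-Poisson systems

$$(\lambda_1 I + (\mu_1+\xi_1+\rho_1)\nabla^T\nabla)\,g =
  \lambda_1 f + \xi_1\nabla^T G + \rho_1\nabla^T(v-b_1),$$

$$((\lambda_2+\xi_2) I + (\mu_2+\rho_2)\nabla^T\nabla)\,G_c =
  [\lambda_2\nabla f + \xi_2\nabla g + \rho_2\nabla^T(w-b_2)]_c,$$

solved spectrally. The shrinkage thresholds are fixed at $1/\rho_1$
(isotropic) and $1/\rho_2$ (anisotropic) because the L1 terms carry
unit weight. The Bregman update for $b_1$ uses $\nabla g^{(k+1)}$ — the
iterate $v$ was shrunk from — which is the standard split-Bregman form;
an index-slipped variant using the previous iterate breaks the
Bregman-iteration bookkeeping and is not offered.

### Boundary conventions: one operator, two transforms

The gradient is discretised with backward differences whose first
row/column is zero (replicate padding): constants are exactly in the
kernel, the discrete version of a zero-Neumann boundary. The adjoint is
the literal matrix transpose of that operator — not an independently
discretised divergence — so the identity
$\langle\nabla u, p\rangle = \langle u, \nabla^T p\rangle$ holds to
rounding, which the ADMM derivation assumes.

The update formulas are stated with the DFT, which diagonalises only
*periodic* operators; a zero-Neumann discretisation calls for a cosine
transform instead. Both are provided behind
`transform_mode`:

* `"periodic"` (default): circulant $\nabla^T\nabla$ with symbol
  $2(2-\cos(2\pi k/H)-\cos(2\pi l/W))$ — literal fidelity to the DFT
  update formulas, at the price of a boundary-convention mismatch with
  the Neumann difference operator used on the right-hand sides.
* `"symmetric"`: the Neumann-consistent mode. Implemented as a
  half-sample even extension to a $2H \times 2W$ grid followed by the
  periodic solve (algebraically a DCT-II solve); restricted to the
  original block this inverts **exactly**
  $a\,x + b\,\nabla^T\nabla x$ for the package's own gradient/adjoint
  pair, so each linear update is the exact minimiser of its
  sub-problem. The symbol question (stencil DFT symbol vs $|\omega|^2$
  of the continuum operator) is resolved in favour of the stencil
  symbol, since the operator is *defined* by finite differences.

The per-step descent and minimiser-property tests run in symmetric
mode, where exactness is a theorem; in periodic mode the same descent
is observed on the test fixtures but is not guaranteed at the boundary,
which is exactly why both modes are exposed.

### Stopping rule and initialisation

Initialisation is the conventional split-Bregman start $g = f$, all
auxiliary variables zero (a constant image is then an exact fixed point:
the solver returns $g = f$, $G = 0$ in one sweep). Iteration stops when
**both** players are stationary:
$\max\big(\|\Delta g\|/\|g\|,\ \|\Delta G\|/\|G\|\big) \le \mathrm{tol}$
(default $10^{-4}$, cap 500 sweeps). A $g$-only rule was tried first
and rejected: because $\|G\| \ll \|g\|$, stopping on $g$ alone leaves
$G$'s fixed-point residual at roughly $27\,\mathrm{tol}$ at *any*
tolerance — a stopped iteration, not an equilibrium. A Nash equilibrium
is a fixed point of both players, so the monitor must watch both. The
scheduling is one Gauss–Seidel sweep per player per outer iteration
(no nested inner loops): it matches the update superscripts, keeps the
cost linear per iteration, and the fixed-point certificates confirm it
reaches stationarity.

Degenerate inputs: `solve_screened()` requires $a > 0$ (the symbol is
$\ge 0$ with a zero at frequency zero, so $a = 0$ is singular);
shrinkage at magnitude zero returns exactly zero (the $0/0$ guard);
relative changes use a $\sqrt{\varepsilon}$ denominator floor so an
all-zero image cannot divide by zero; any non-finite intermediate stops
the run with the offending step named.

## Parameters

All weights act on the native 0–255 intensity scale — images are never
normalised, so noise levels quoted on the 8-bit scale stay meaningful;
rescaling intensities requires rescaling the $\lambda$ weights.

| parameter | role | default | notes |
|---|---|---|---|
| `lambda1` | data fidelity of $g$ | 1 | decrease with noise; `suggest_params()` uses $2/(1+\sigma)$ |
| `mu1`, `mu2` | quadratic smoothness | 1 | keep small (0.05) or edges blur |
| `xi1`, `xi2` | $G \leftrightarrow \nabla g$ coupling | 1 | moderate values; the game stays stable across a wide range |
| `lambda2` | fidelity of $G$ to $\nabla f$ | 1 | differentiating raw noise is violent; see `presmooth_sigma` |
| `rho1`, `rho2` | Bregman penalties | 1 | double as shrinkage thresholds $\kappa = 1/\rho$ |
| `tol`, `max_outer` | stopping | $10^{-4}$, 500 | joint two-player criterion |

No weight values were ever published for the method, so the defaults
are necessarily this package's own: the neutral all-ones set, plus
`suggest_params(sigma)` as a documented calibration
($\lambda_1 = 2/(1+\sigma)$, $\mu = 0.05$, $\xi = \rho = 0.1$,
$\lambda_2 = 0.1$) chosen once from a coarse sweep on the phantom
world described below — every sweep point with
$\lambda_1 \in [0.01, 0.1]$ met the recovery criteria, so the
calibration is a convenience, not a knife-edge. `presmooth_sigma`
optionally Gaussian-blurs $f$ *only* where $\nabla f$ enters the
$G$-player's data term; it is off by default because hiding the choice
would be worse than exposing it.

## The phantom world

Real counterparts of the target images (ultrasound, vessels, brain MRI)
cannot ship with the package, so the fixture generator reproduces their
*difficulty axes* rather than their appearance: star-shaped nested
blobs (region geometry), one thin curved stripe about 3 px wide (the
vessel/"tail" case), base intensity levels on the 8-bit scale with a
configurable minimum contrast gap, a shared low-frequency drift of
bounded amplitude (piecewise-smooth shading; the bound makes the
within-region intensity range auditable), and seeded additive Gaussian
noise at the protocol levels $\sigma = 10, 17, 25, 100$. Noise is not
clipped by default: at $\sigma = 100$ on near-binary images clipping
would censor the distribution severely; a flag provides the censored
variant.

What a green phantom test does establish: the full pipeline recovers a
known piecewise-smooth partition through heavy noise (two-phase Dice
$\ge 0.95$ at $\sigma = 25$; $\ge 90\,\%$ correct phases for $K = 4$ at
$\sigma = 17$), deterministically and without stage-one recomputation
across thresholds. What it does not establish: superiority over the
first-order baseline on *these* phantoms — smooth-blob phantoms with a
global drift contain few genuine gradient discontinuities, so
first-order smoothing performs comparably (the README reports 0.974 vs
0.972 best Dice on one instance); modality-specific physics (speckle,
bias fields, blur) are deliberately not simulated; and no claim is made
about the external retinal-vessel benchmark, whose reproduction needs a
download and unpublished weights and is explicitly out of scope.

## Evaluation metrics

Dice $2|\Sigma\cap GT|/(|\Sigma|+|GT|)$ and Jaccard
$|\Sigma\cap GT|/|\Sigma\cup GT|$, linked by $J = D/(2-D)$ — an
identity the tests enforce to $10^{-12}$. A circulating variant of the
Jaccard formula with the *union* in the numerator is identically 1 by
inclusion–exclusion and is an evident typo; published score pairs
(e.g. Dice 0.950 with Jaccard 0.905) satisfy the standard identity,
confirming the definition implemented here. Two empty masks raise an
explicit undefined-score error instead of a silent 0.

## Known limitations

* 2-D single-channel grids only; spectral solves assume uniform spacing
  (no multigrid/CG path).
* The periodic default trades boundary consistency for formula
  fidelity; results on images with strong content at the frame border
  differ slightly between modes, and only symmetric mode carries the
  exact-minimiser guarantee.
* Whether the alternating sweep always reaches the unique equilibrium
  is not proved; the package certifies fixed-point residuals on its
  fixtures only.
* k-means stage two clusters $g$ alone (not $(g, G_x, G_y)$ jointly) —
  the smoother is the segmentation carrier; $G$ is exposed for
  inspection and figure panels.
* TIFF I/O is not provided (no TIFF reader in the dependency set);
  16-bit PNG and lossless `.rds` fields cover high-depth input.

```{r example, eval = FALSE}
# end-to-end: phantom -> solve -> threshold -> score
spec  <- phantom_spec(shape = c(128, 128), intensity_levels = c(100, 140),
                      gradient_amplitude = 20, contrast_gap = 30, seed = 42)
ph    <- make_phantom(spec)
noisy <- add_noise(ph$clean, sigma = 25, seed = 43)
res   <- segment_image(noisy, suggest_params(25), stage_two = "manual",
                       tau = 120)
dice(res$labels, matrix(as.integer(ph$labels > 0), 128, 128))
```
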