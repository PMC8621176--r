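# bzseg

Two-stage variational segmentation of **low-contrast images with
piecewise-smooth intensities** — ultrasound-like objects with faint
"tails", vessels buried in heavy noise, multi-class MRI slices — where
models that assume piecewise-*constant* regions either split smooth
features into spurious phases or miss weak edges entirely.

## The model

Classical region-based segmentation minimises a Mumford–Shah energy,
penalising `|∇g|²` off an edge set; its second-order refinement of
Blake–Zisserman type penalises the *Hessian* off two discontinuity sets,
capturing gradient discontinuities ("edges of the second kind") and
avoiding the staircasing that first-order total variation produces on
intensity ramps. Neither is directly computable, so stage one solves a
convex relaxation split into a two-player Nash game over a smooth
approximation `g` of the image `f` and a surrogate `G ≈ ∇g`:

    min_g E1(g, G) = λ1/2 ‖f − g‖² + μ1/2 ‖∇g‖² + ‖∇g‖₁ + ξ1/2 ‖G − ∇g‖²
    min_G E2(G, g) = λ2/2 ‖∇f − G‖² + μ2/2 ‖∇G‖² + ‖∇G‖₁ + ξ2/2 ‖G − ∇g‖²

Each energy is strictly convex in its own variable, so the game has a
unique equilibrium, and — the practical point of the splitting — the two
players' weights can be tuned independently. The solver alternates one
split-Bregman (ADMM) sweep per player: each L1 term becomes a
closed-form shrinkage step and each quadratic sub-problem a
screened-Poisson solve `(a·I + b·∇ᵀ∇)x = rhs`, diagonalised by FFT
(periodic mode) or a cosine transform (Neumann mode).

Stage two thresholds `g` — manually for two-phase work, or with 1-D
k-means for multiphase — and can be repeated with any number of
thresholds without re-running the solver.

The package also provides the first-order two-stage baseline
(`run_ccz()`), Dice/Jaccard evaluation, a seeded generator of
piecewise-smooth phantoms with Gaussian noise, and a CLI.

## Worked example

```r
library(bzseg)

# a 128x128 two-phase phantom: smooth blobs + a thin curved structure,
# base levels 100/140, within-region drift of amplitude 20, noise sd 25
spec  <- phantom_spec(shape = c(128, 128), intensity_levels = c(100, 140),
                      gradient_amplitude = 20, contrast_gap = 30, seed = 42)
ph    <- make_phantom(spec)
noisy <- add_noise(ph$clean, sigma = 25, seed = 43)

params <- suggest_params(sigma = 25)          # lambda1 scales ~ 1/sigma
res <- segment_image(noisy, params, stage_two = "manual", tau = 120)
res$report
#> solve_report: 63 iteration(s), converged (last rel. change 9.68e-05)

gt <- matrix(as.integer(ph$labels > 0), 128, 128)
dice(res$labels, gt)        #> 0.9718
jaccard(res$labels, gt)     #> 0.9452

# stage two is free to change: k-means picks essentially the same cut
res2 <- rethreshold(res, stage_two = "kmeans", K = 2)
res2$cuts                   #> 119.33
dice(res2$labels, gt)       #> 0.9718
```

The Dice score of 0.97 means the thresholded mask overlaps the ground
truth almost perfectly despite the noise standard deviation (25) being
close to the inter-region contrast (40); Jaccard is the stricter
intersection-over-union view of the same overlap (J = D/(2−D)). On this
phantom family the first-order baseline performs comparably (best Dice
0.9742 vs 0.9718 over a 41-threshold sweep) — see the methods vignette
for why smooth-blob phantoms do not discriminate strongly between
first- and second-order regularisation.

### Command line

```sh
Rscript inst/cli/bzseg.R phantom  --outdir ph --shape 128x128 --levels 100,140 --sigma 25 --seed 5
Rscript inst/cli/bzseg.R segment  --input ph/noisy.rds --outdir out --mode manual --tau 120 --gt ph/mask.png
Rscript inst/cli/bzseg.R evaluate --seg out/labels.png --gt ph/mask.png
```

`segment` writes the figure panels `g.png`, `Gx.png`, `Gy.png`
(min–max rescaled views), lossless `.rds` copies, the label map and a
run report; stage-one results are cached in the output directory, so
re-running with a different `--tau` never re-runs the solver.

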