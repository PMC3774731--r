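# furrowvm

An apical-surface vertex model of *Drosophila* ventral furrow formation, for
developmental biologists and tissue biophysicists who want a tested,
replayable simulator of joint apical constriction in the ventral epithelium
— and a metrics layer (eccentricity, rates, stagnation periods, rate-lag
correlation) that applies equally to simulated traces and to tracked cells
from live imaging.

## The model

The ventral epithelium in surface view is a sheet of hexagonal cells
(standard size 15 × 24, fixed boundary, non-contractile high-tension margin
columns delimiting the furrow). Vertex positions `x_v` minimise

    E = Σ_cells K/2 (A_i − A0)²  +  Σ_edges Λ_e l_e  +  Σ_cells Γ_i(t̃)/2 A_i²

by overdamped dynamics `η ẋ_v = −∂E/∂x_v` (explicit Euler), with K = 2.5,
anisotropic line tension Λ = 0.2 on *transverse* junctions (within 45° of
the antero-posterior axis) and 0.075 on *vertical* ones, Λ = 6 at the
margins, and an area-based contractility Γ. Contractility programs cover
the full set of model variants: a constant cutoff band (Γ = 10, five central
rows), a Gaussian latero-ventral gradient (peak Γ_mid = 15, width σ = 2
rows), linear ramps (rate 0.15, capped at 25), per-cell Wiener noise
(σ_W = 0.3), a centroid-distance ("alternative") gradient, and the
*twi*-mutant attenuation (per-cell uniform factor in [0, 0.5]). Junctions
shorter than eps = 0.1 undergo T1 neighbour exchange. Every run archives
its configuration, noise paths and traces, so `replay()` reproduces it
bit-exactly — optionally with declarative modifications such as switching
off the contractility of a cell's neighbours.

## Worked example

```r
library(furrowvm)

arch <- run_preset("gradient_stochastic", master_seed = 1)
arch
#> <vf_archive> 360 cells, 280 steps run (furrow completed)
#>   final furrow width 0.9082, T1 swaps 23, seed 1

rl <- rate_lag_analysis(arch)
rl$best_offset_s           # forward shift of the contractility rate, seconds
#> [1] 4
rl$significant_positive    # ventral cells with p < 0.05 positive correlation
#> [1] 1
mean(rl$stagnation_counts) # stagnation periods per ventral cell
#> [1] 2.175

v <- ventral_cells(arch$final_sheet)
mean(arch$traces$eccentricity[v, ncol(arch$traces$eccentricity)])
#> [1] 2.03
```

The run reaches furrow completion (mean area of the five central rows below
0.35 A0) in 280 integrator sub-steps, which the normalization layer maps to
600 s of real time. Ventral cells end strongly anisotropic (AP/LV moment
ratio ≈ 2), nearly all of them show a significant positive correlation
between contractility rate and constriction rate, the correlation peaks
with the contractility rate shifted ~4 s forward (contraction precedes
constriction), and cells pause repeatedly on their way down — stagnation
periods that arise from force balance alone, with no ratchet in the model.
The force balance itself is exact: an isolated tension-free cell relaxes to
`A* = K·A0/(K+Γ)`,

```r
equilibrium_area_sweep(c(0, 2.5, 10, 25))
#>   gamma      area predicted
#> 1   0.0 2.5980762 2.5980762
#> 2   2.5 1.2990381 1.2990381
#> 3  10.0 0.5196152 0.5196152
#> 4  25.0 0.2361887 0.2361887
```

Variant experiments are one call each: `run_preset("cutoff")` (sharp
band-edge morphology), `tension_variant_run("symmetric")` (more neighbour
exchanges, rounder cells), `geometry_variant_run("square_constant")`
(isotropic constriction without a gradient), `twi_run()` (random patchwork
of constricted and unconstricted cells), and `reduced_seven_cell()` (the
one-contractile-cell rosette used to dissect stagnations). See the
methods vignette (`vignettes/vertex-model-methods.Rmd`) for the model
conventions, parameter meanings and known limitations.

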