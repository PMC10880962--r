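# jawgrowth

Mechanical forces from embryonic movement shape developing joints: when
larval zebrafish are immobilised, the Meckel's cartilage (MC) of the jaw
joint loses its normal growth anisotropy — depth (ventrodorsal) growth is
lost almost entirely, length (anteroposterior) growth is reduced, width
(mediolateral) barely changes. **jawgrowth** is an R package for asking
*which* biophysical stimulus from jaw movement drives that anisotropy. It
implements, end to end:

* **Growth quantification from tracked cells.** For link vectors *l*
  connecting neighbouring cell centroids (3D Delaunay neighbours with a
  length cutoff), the texture `M = <l (x) l>` and link change
  `C = <l (x) (l' - l)/dt>` give the *statistical symmetrised velocity
  gradient* `G = sym(M^-1 C)` per 15 µm cubic region of interest — a
  strain-rate-equivalent growth tensor whose eigenvectors are labelled by
  their nearest anatomical axis (VD/AP/ML). This yields the free-to-move and
  immobilised growth maps `G_free` and `G_imm`.
* **A finite-element jaw-motion model.** Linear-elastic 4-node tetrahedra in
  µm/nN/s units (stress = kPa); cartilage E = 142.01 kPa, Poisson 0.3,
  interzone at 0.025 % of cartilage stiffness; the four jaw muscles applied
  as fixed-direction loads with published force ratios, calibrated so peak
  jaw opening is the physiological 37.2 µm; closure and opening ramped in
  5 increments each, per-node hydrostatic stress σ_h stored per increment.
* **Three mechanobiological growth laws** on the immobilised baseline:
  `G_ave = G_imm - a·S·I₃` (cycle-averaged stress, compression promotes
  growth), `G_grad = G_imm + b·|∇σ_h(open) - ∇σ_h(close)|` (axis-wise
  reversal of stress gradients), and `G_comp_grad` (the same on the
  compressive part `min(σ_h, 0)` only). The modulating variables a and b
  are chosen by the sensitivity-sweep procedure (log-spaced sweeps with
  4× / 15× span, picking the value that best reproduces physiological MC
  depth growth).
* **Simulated morphogenesis.** Growth maps applied over 12 h windows as
  anisotropic eigenstrains in an elastic solve (or kinematically, as a
  growth flow), with morphometrics (length, depth, width-at-joint) and
  symmetric surface distances comparing every mechanobiological outcome
  against the `G_free` outcome.

The imaging inputs behind the original analysis (centroid tables, segmented
half-jaws, meshes) are not publicly deposited, so the package ships a
**synthetic rudiment generator**: a parametric MC + palatoquadrate +
interzone + ceratohyal assembly with ground-truth deformation fields
calibrated (against an independent mesh-deformation oracle) to the measured
organ-level changes — MC length +37 %, depth +43 %, width +11 % over
4→5 dpf free-to-move; +15 %, −6 %, +4 % immobilised. Every stage is tested
against this generator, including the full estimation → simulation →
measurement round trip.

## Worked example

```r
library(jawgrowth)

run <- run_pipeline(default_config(seed = 1))
print(run)
#> <jawgrowth_run> seed 1 - 183 s
#> organ-level percent changes (4 to 5 dpf):
#>     condition length depth width
#> 1        free   38.8 42.75  12.7
#> 2 immobilised   16.9 -7.77   3.3
#> calibrated jaw opening: 37.2 um
#> modulating variables: a = 0.00289  b = 0.00313
#> shape distance to G_free outcome (um, mean over windows):
#>           map mean_dist
#> 1       G_ave      2.34
#> 2 G_comp_grad      1.21
#> 3      G_grad      1.42
```

Reading the output: the first table is the round trip — growth tensors were
estimated from noisy synthetic tracks (30 cells per specimen, 7–8 specimens
per condition) and used to grow the 4 dpf shape for 24 h; the recovered
percent changes sit within ~2 points of the generator's calibrated targets
(37/43/11 free, 15/−6/4 immobilised), which is the noise floor of tracking
~30 cells. The jaw opening is met exactly because the model is linear. The
last table is the headline comparison: growth driven by **compressive stress
gradients** lands closest to the free-to-move outcome (1.21 µm mean surface
distance), full stress gradients next (1.42 µm), and cycle-averaged stress
— an isotropic stimulus that overgrows length and width — worst (2.34 µm),
reproducing the qualitative ranking found on the imaged jaws.

Useful entry points: `build_rudiment_mesh()`, `sample_cell_centroids()`,
`advect_tracked_pair()`, `assemble_growth_map()` (+ `tidy()`, `glance()`,
`autoplot()`), `simulate_jaw_cycle()`, `calibrate_muscle_forces()`,
`growth_ave()` / `growth_grad()` / `growth_comp_grad()`,
`calibrate_modulating_variable()`, `apply_growth()`, `extract_outline()`,
`compare_shapes()`. The methods vignette (`vignettes/methods.Rmd`) documents
the models, defaults and limitations.

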