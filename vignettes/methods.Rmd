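---
title: "Models and methods: mechanoregulated growth of the larval jaw joint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mechanoregulated growth of the larval jaw joint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jawgrowth)
```

jawgrowth asks a mechanobiology question: which biophysical stimulus arising
from jaw movement — the average hydrostatic stress over a motion cycle, the
spatial gradients of hydrostatic stress, or the gradients of its compressive
part only — best explains the anisotropic growth of the larval zebrafish jaw
joint between 4 and 5 days post fertilisation (dpf)? The package implements
the full chain needed to pose that question quantitatively: growth-tensor
estimation from tracked chondrocyte centroids, a linear-elastic finite-element
(FE) model of jaw motion, three candidate growth laws built on an
"immobilised" biological baseline, and simulated morphogenesis whose outcomes
are compared against the "free-to-move" outcome.

Because the underlying confocal data (centroid tables, segmented half-jaw
surfaces, meshes) are not publicly deposited, the package ships a synthetic
rudiment generator that emulates them. Every downstream stage is exercised and
tested against that generator; organ-level ground truth is imposed by
construction, so the whole estimation-simulation-measurement chain can be
validated as a round trip.

## The synthetic rudiment and its ground-truth deformation

The rudiment is a parametric solid, not a reconstruction of a real jaw: a
Meckel's cartilage (MC) built from a hemispherical joint head (radius 10 um)
whose equatorial disc forms the joint face, continued by a rod tapering from
7 to 5 um over a total MC length of 40 um; a palatoquadrate (PQ) block
mirrored across a 6 um interzone slab; and a ceratohyal (CH) anchor bar fused
beneath the PQ. The mechanics only requires the right topology — two stiff
elements bridged by a very soft interzone, loaded like a lever — so a
parametric solid is preferable to an unverifiable surface reconstruction.
The hemisphere-with-equatorial-face head is a deliberate choice: the widest
transversal section of the head sits at the joint face itself, so the "width
at the level of the joint" measurement samples a well-resolved, slowly varying
part of the geometry even after substantial anteroposterior growth.

Meshing voxelises the solid on a lattice of spacing `target_edge_length`
(default 2 um, the element scale used on the imaged jaws), splits each voxel
into six conforming tetrahedra, and then projects the surface nodes onto the
analytic surface (Newton iterations on the solid's level-set function,
clamped to 0.75 voxel and backed off per node if an element would drop below
5% of the regular subdivision volume). Four-node linear tetrahedra are used
rather than the ten-node quadratic elements of the original motion models;
the finer default edge length compensates, and the patch and convergence
tests in the suite quantify what linear elements can and cannot resolve
(notably their stiffness in bending). The discrete volume of the default mesh
is within 1% of the closed-form volume of the generating primitives.

The ground-truth deformation field is a separable velocity field in the
anatomical frame,

$$ v_i(x) = A_i \,\phi(s)\, (x_i - o_i), \qquad
   \phi(s) = \max\!\big(0.2,\; 1 - \beta (s/L)^2\big), $$

with $s$ the anteroposterior (AP) coordinate relative to the joint-line
origin $o$ and $\beta = 0.2$, a gentle axial profile peaking at the joint
line. The free-to-move mode is ventrodorsally dominant; the immobilised mode
has a slightly negative ventrodorsal amplitude. The amplitudes $A_i$ are
never set by hand: they are calibrated by secant iteration against the
mesh-deformation oracle so that integrating the flow for 24 h reproduces the
measured organ-level percent changes — MC length +37%, depth +43%, width
+11% for free-to-move larvae, and +15%, -6%, +4% for immobilised larvae.
Because $v_{AP}$ depends only on the AP coordinate, and the VD/ML components
depend on the AP trajectory but not on each other, the calibration problem
is triangular and three one-dimensional root finds suffice (to 0.02
percentage points).

Tracked cells are sampled by Poisson-disk dart throwing inside the MC
(default 30 cells, 4 um minimum spacing — about the cell count of the
modelled joint portion), advected through the flow with RK2 sub-stepping
(100 sub-steps per 12 h window; the integrator error is far below any other
error source), and the second timepoint perturbed with isotropic Gaussian
localisation noise. The noise level (0.3 um) is a configuration choice —
no measured value exists for it — representing confocal centroid
localisation error. Replicate counts default to the study's specimen
numbers: 7 free-to-move specimens per window and 8 (first window) / 6
(second window) immobilised specimens.

What the generator does *not* emulate: proliferation and intercalation
events (identities are conserved; the biological statistic treats these only
through centroid geometry anyway), image formation and segmentation error
structure (noise is isotropic Gaussian, real localisation error is
anisotropic in z), and any irregularity of real rudiment outlines. Passing
round-trip tests therefore demonstrates the correctness and noise behaviour
of the estimation and simulation machinery under controlled conditions, not
the biological fidelity of real-jaw measurements.

## Growth quantification

Local growth is the *statistical symmetrised velocity gradient* of the
centroid pattern. For link vectors $l$ connecting neighbouring centroids,
with $l'$ the vector of the same cell pair one window later,

$$ M = \langle l \otimes l \rangle, \qquad
   C = \big\langle l \otimes (l'-l)/\Delta t \big\rangle, \qquad
   V = M^{-1} C, \qquad G = \tfrac{1}{2}(V + V^\top), $$

a strain-rate-equivalent tensor (units 1/s). Neighbours are the 3D Delaunay
edges of the centroid cloud with a cutoff of 2.5x the median
nearest-neighbour distance (the neighbour rule is recorded with each link
set and isolated so it can be swapped). The tessellation is found by direct
empty-circumsphere enumeration — exact in general position and entirely
adequate at n = 30; the suite cross-checks the edge set against an
independent qhull tessellation. Links are built at the first timepoint and
matched by cell identity at the second; appearing/disappearing cells are
dropped (proliferation over these windows is negligible).

Tensors are computed per cubic region of interest (ROI; 15 um side, grid
anchored at the joint-line landmark) from all conserved links with at least
one endpoint in the ROI — links to neighbours outside the ROI included. ROIs
with fewer than 4 links or a texture-matrix condition number above 1e6 are
flagged invalid and excluded from interpolation support rather than zeroed.
Eigenvectors are labelled VD/AP/ML by the bijective assignment minimising
total angular mismatch with the anatomical axes; ties break with priority
VD > AP > ML so labelling is deterministic. Replicate specimens' maps are
averaged component-wise per ROI before any simulation, as a pooled map per
condition.

Interpolation between ROI centres is component-wise trilinear on the ROI
lattice (invalid lattice cells filled with the nearest valid tensor);
queries outside the lattice take the nearest valid ROI's tensor. The
original pipeline delegated this step to a proprietary solver's "analytical
mapped fields", whose dialect is unspecified; trilinear-plus-nearest is the
simplest rule that is exact at ROI centres and linear between them.

A deliberate consistency choice ties the estimator to the simulator: the
estimator's finite difference $(l'-l)/\Delta t$ reports $(\lambda-1)/\Delta
t$ for a window stretch $\lambda$, so growth application compounds strains
multiplicatively such that applying an estimated rate $g$ over a window
reproduces the stretch $1 + g\Delta t$ exactly. Mixing conventions (e.g.
exponential integration of a finite-difference estimate) would inflate a 43%
depth change to roughly 48% over two windows — a larger error than every
other term in the budget.

## Jaw mechanics

Small-strain linear elasticity on the labelled tet mesh, assembled in the
um / nN / s unit system so that stresses are in kPa and the published
numbers are usable verbatim: cartilage Young's modulus 142.01 kPa
(free-to-move nanoindentation value), Poisson's ratio 0.3 everywhere, and an
interzone at 0.025% of the cartilage modulus. Boundary conditions follow the
physiological set: the anterior end of the ceratohyal fixed, only AP
translation allowed at the posterior PQ face, and ML translation suppressed
at the anterior MC face (midsagittal symmetry).

Muscle loading uses the four jaw muscles with the published force ratios
(am 2.84, ima 1.25, imp 1.50, ih 1.50 nN at 4 dpf; 4.35/2.90/3.47/3.47 at
4.5 dpf), applied as fixed-direction loads distributed over small attachment
patches (2.5 um radius) — a point load on a single node would leave a stress
singularity in exactly the fields the growth laws consume. Attachment
geometry mirrors the anatomy of jaw opening: the opening muscles act through
the retroarticular lever just ventral-posterior of the joint head, pulling
predominantly posteriorly, and the adductor closes the jaw from the dorsal
head region, also with a posterior component. Both phases therefore press
the MC head into the interzone, so the cycle-averaged hydrostatic stress at
the joint is predominantly compressive while the ventrodorsal bending
gradient reverses between peak opening (dorsal tension / ventral
compression) and peak closure — the stress regime reported for the imaged
jaws.

The force scale is calibrated so the ventrodorsal displacement of the MC
anterior tip at peak opening equals the physiological 37.2 um; the model is
linear, so the scale is a closed-form ratio and the achieved opening is
exact. The same scale is applied to both phases to preserve the published
force ratios. A cycle is closure ramped over 5 increments, released, then
opening ramped over 5 increments (sequential steps; whether the original
steps overlapped is not stated, and full release is assumed); linearity
makes each increment an exact fraction of the peak solution. Per-node
hydrostatic stress $\sigma_h = \mathrm{tr}\,\sigma / 3$ (tension positive)
is stored per increment; the cycle average $S$ is the arithmetic mean over
all 10 stored increments (the description of the averaging window alternates
between the two step orders; averaging over the whole cycle is adopted and
kept behind one code path). Nodal stress gradients come from a per-node
least-squares linear fit over the edge-connected neighbourhood — exact for
linear fields including at boundaries — with a volume-weighted
element-gradient fallback for rank-deficient neighbourhoods.

## Growth laws and calibration

With the immobilised map interpolated to the mesh nodes as the biological
baseline $G_{imm}$:

* **Average stress:** $G_{ave} = G_{imm} - a\,S\,I_3$ — isotropic, with
  compression ($S<0$) promoting growth;
* **Stress gradients:** $G_{grad} = G_{imm} + b\,\lvert \nabla\sigma_h^{open}
  - \nabla\sigma_h^{close} \rvert$ — axis-wise (the gradients are kept as
  diagonal triples in the anatomical frame, and the absolute value applies
  per entry), so the reversal of the stress gradient over the cycle promotes
  growth along the axis it reverses in;
* **Compressive stress gradients:** identical to $G_{grad}$ but with each
  peak field clamped to $\min(\sigma_h, 0)$ before the gradients are taken.

The published magnitudes of the modulating variables (a = 3e9 m^2/(N s),
b = 5e10 m^3/(N s)) were tuned in the original model's unit system and do
not transfer to another geometry — in SI units applied to these stress
scales they are dimensionally absurd. The package therefore treats them as
provenance only and reruns the published *selection procedure*: a sensitivity
sweep, log-spaced with the published span ratios (4x for a, 15x for b),
centred on a scale estimate derived from the stimulus actually present
(the ventrodorsal rate deficit between the free and immobilised maps divided
by the median stimulus magnitude over the MC). For each sweep value the
4-4.5 dpf growth simulation is run and the value whose MC depth change best
matches the physiological target — the depth change of the G_free-grown
shape — is chosen; b is calibrated on the G_grad pipeline and reused
unchanged for G_comp_grad, and both values are reused for the 4.5-5 dpf
window, exactly as in the original procedure. If every sweep value
undergrows the target the maximum is returned with a warning.

## Morphogenesis

Growth is applied over a 12 h window either **kinematically** — nodes
advected through the growth-velocity field reconstructed as the line
integral of the (log-stretch) tensor field along the ray from the joint-line
origin, $v(x) = \big[\int_0^1 L(o + t(x-o))\,dt\big](x-o)$, which is the
exact inverse of taking a velocity gradient when the joint is anchored — or
by **eigenstrain** (the default), in which each element's growth strain
enters an elastic equilibrium solve as a stress-free strain per sub-step (10
sub-steps, incremental strains compounding multiplicatively), on the current
geometry. The eigenstrain route reproduces the expansion-subroutine
mechanics of the original simulations, including residual stress from
incompatible growth. Its solves use a minimal statically determinate 3-2-1
pinning, and the computed displacement then has the rigid motion of the
joint neighbourhood (Gaussian weight, 10 um scale) subtracted — grown
specimens stay aligned at the joint line, just as measured specimens are
aligned before analysis. The physiological motion constraints are *not*
imposed during growth: over a 20-40% expansion they generate large spurious
reaction stresses and a net rotation of the rudiment, which is a property of
those constraints, not of growth. A saturation guard caps shrinkage at -90%
per window; it is only ever reached by deliberately extreme
sensitivity-sweep values.

Morphometrics on an aligned shape: length is the AP extent, depth the VD
extent, and width the maximal ML extent among transversal slices within 5 um
of the joint line ("width at the level of the joint" is not quantified in
the source; 5 um is the package default). Slice extents are computed from
edge-plane intersections so the measure is continuous in the node positions.
Average shapes are built per slice by polar resampling about the slice
centroid (adequate for these convex, tubular sections; a documented failure
mode for strongly non-star-shaped outlines) and pointwise averaging.

Grown shapes are compared by the symmetric mean/max surface distance between
region surface nodes. This metric is a package addition: the original
comparison of outlines was visual, so all "most physiological" statements
are encoded as *ranking* assertions on this distance, never as absolute
distances.

## The pipeline and what the defaults mean

`run_pipeline(default_config(seed))` executes, per 12 h window: synthesis,
tracking, map estimation (G_free, G_imm pooled over replicates), growth of
the 4 dpf shape under both maps, the jaw cycle on the window's free-to-move
start shape with age-appropriate force ratios, stimulus construction,
calibration of a and b (first window only), construction of the three
mechanobiological maps, growth under each, and measurement of morphometrics
and shape distances against the G_free outcome. Problem sizes at the
defaults: ~2400 mesh nodes / ~10600 tets (2 um edges), 30 cells per
specimen, 7-8 specimens per condition and window, 9-point sweeps — sizes
chosen to keep a complete run in minutes on one core while leaving every
estimate comfortably inside its tolerance; the acceptance criteria quote the
tolerances.

Numerical-edge behaviour worth knowing: degenerate ROI point sets raise
errors rather than returning silently-zeroed tensors; element inversion
during growth aborts with the offending element ids; the secant calibrations
stop at 0.02 percentage points; labelling ties break VD > AP > ML; the
voxel mesh under-resolves the width of flat faces by up to one lattice step,
which cancels in percent changes because the ground-truth calibration and
the pipeline measure the same discrete geometry.

## Known limitations

* Linear elasticity and geometric linearity throughout (the original work
  found viscoelastic and elastic motion simulations near-identical; contact,
  poroelasticity and fluid flow are out of scope).
* Linear tetrahedra are stiff in bending; the cantilever test documents the
  convergence behaviour. Stress *patterns* (signs, gradients) are what the
  growth laws consume, and those are mesh-converged at the default edge
  length.
* The synthetic geometry is parametric; absolute stress magnitudes and the
  calibrated a, b values are meaningful only within this geometry. The
  procedure, not the numbers, is the transferable object.
* Alignment from two landmarks alone cannot recover a general 3D rotation;
  the joint-line direction (which meshes carry) is required for exact
  recovery.
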