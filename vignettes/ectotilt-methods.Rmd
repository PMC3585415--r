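---
title: "Positioning a receptor domain over the membrane: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positioning a receptor domain over the membrane: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectotilt)
```

## The problem

Integrins are bent, two-legged cell-surface receptors.  Where the
ligand-binding domain of an integrin sits relative to the plasma membrane
decides whether soluble ligands can reach it in the resting (bent) state.
`ectotilt` implements the quantitative chain of reasoning used to answer
that question for an αA-containing integrin probed with a fluorescent Fab
fragment bound at its ligand-binding (MIDAS) face:

1. **FLIM → FRET → distance.**  Per-cell donor fluorescence lifetimes are
   summarized by Gaussian fits; the quenching of the donor by a
   membrane-embedded acceptor gives a FRET efficiency and hence a
   donor–acceptor distance.
2. **Membrane orientation search.**  An atomic model of the ectodomain/Fab
   complex is placed in a canonical frame and rotated systematically over a
   planar membrane; orientations that clash with the plane are discarded,
   and the fluorophore-centroid distance from step 1 selects the consistent
   tilt angles.
3. **EM projection matching.**  The atomic model used in step 2 is itself
   validated against negative-stain class averages by sequential two-body
   projection matching, with Fourier shell correlation (FSC) for map
   resolution.

## FLIM/FRET model

Whole-cell mean lifetimes are binned (50 ps bins by default) and the bin
counts are least-squares fitted with a single Gaussian
$A\exp(-(x-\mu)^2/2\sigma^2)$ (`fit_lifetime_gaussian()`).  Fitting the
histogram rather than maximizing the likelihood of the raw values mirrors
the conventional FLIM workflow and yields a meaningful fit correlation
(Pearson r between observed and fitted counts).  The 95% CI on $\mu$ comes
from the fit covariance; resampling would be an equally defensible choice,
but the covariance route is deterministic and matches how such CIs are
usually quoted.

With donor-only lifetime $\tau_D$ and quenched lifetime $\tau_{DA}$,

$$E = 1 - \tau_{DA}/\tau_D, \qquad
  r = R_0\,(\tau_D/\tau_{DA} - 1)^{-1/6}, \qquad
  E(r) = \frac{R_0^6}{R_0^6 + r^6}.$$

The default Förster radius is $R_0 = 62$ Å (the $\kappa^2 = 2/3$ estimate
for the Alexa488/acceptor pair used in the motivating experiment); the
orientation-factor assumption is inherited, not modelled.  Uncertainty is
propagated by evaluating $r$ at the four $(\mu \pm \sigma)$ corner
combinations of the two fitted distributions (`distance_range()`); the
Förster relation is monotone in each lifetime, so the extremes provably
occur at the corners (a gridded search over the ±1σ box is part of the test
suite).  Note that $r$ is *increasing* in $\tau_{DA}$: less quenching means
a larger separation.

## Canonical frame and orientation scan

The leg axis of the α subunit is defined by a vector from the centre of the
disulfide bond that closes the large loop at the end of Calf-1 (midpoint of
the two Sγ atoms; Cα midpoint with a warning when Sγ is absent) to the Cα
of the last modelled α-chain residue.  `canonicalize()` translates the
terminal Cα to the origin and rotates this vector onto +z with the
minimal-angle rotation.  Aligning a single vector leaves the azimuth about
z free, so the frame is completed deterministically: the atom farthest from
the leg axis is rotated into the +x half of the x–z plane.  This makes
canonicalization a function of internal geometry only — idempotent and
invariant to any rigid pre-transform — which the test suite checks to
1e-6 Å.

The membrane is an infinite mathematical plane at $z = -\ell$, where $\ell$
is the **linker offset**: the length of the unresolved stretch between the
last modelled ectodomain residue and the start of the transmembrane helix.
Its true value is structure-specific and is the single most influential
guess in the scan; the default of 5 Å is a documented placeholder, and any
serious use should set it explicitly.

`orientation_scan()` evaluates the grid
$\Phi \in \{0, 5, \dots, 355\}$ (the tilt direction, periodic, endpoint
excluded) × $\rho \in \{0, 5, \dots, 180\}$ (both endpoints: legs vertical
→ flush → buried), i.e. 72 × 37 = 2,664 samples at the default 5° step.
Each sample applies the active extrinsic rotation $R_y(\rho) R_z(\Phi)$.
Only atom z-coordinates are needed, so the scan uses the closed-form z row
of the rotation; a naive triple-loop re-implementation serves as the test
oracle and must agree exactly.  A sample *clashes* when any atom centre
falls strictly below the plane — no van der Waals radii, no membrane
thickness, exactly the plane-comparison rule the procedure is built
around.  The fluorophore position is the centroid of the Fab lysine Cα
atoms (the dye labels lysine amines randomly, so with many labelled Fabs
the measured distance reports on the centroid).

The FLIM constraint keeps allowed samples with
$|d - r| \le$ tolerance.  No tolerance is stated in the source analysis;
the default 2.5 Å is half the typical per-grid-step change in centroid
distance, and the consistent set is monotone non-decreasing in the
tolerance (tested).  Tilt is reported as $90° - \rho$ (90° = legs
perpendicular to the membrane, negative = buried) and summarized with
arithmetic mean/SD; the tilt direction $\Phi$ is periodic and is summarized
with circular mean and circular SD ($\sqrt{-2\ln \bar R}$), since reported
directions cluster near the 0°/360° wrap.

The published counts for the real receptor (114 allowed orientations, 8
FLIM-consistent, tilt 52.5° ± 3.8°, Φ 323.6° ± 14.6°) depend on an
EM-fitted hybrid atomic model that is not publicly deposited and on the
authors' linker offset, which is not printed.  The package therefore
reproduces the *procedure* and validates it property-wise on synthetic
receptors with analytically known geometry; it does not claim to reproduce
those counts.

## Density simulation, projection matching, FSC

`model_to_density()` deposits every non-hydrogen atom as a unit-weight 3D
Gaussian whose Fourier amplitude falls to 0.5 at $1/\text{resolution}$
(real-space $\sigma = 0.187 \times$ resolution).  At the 18–26 Å
resolutions involved, elemental scattering differences are negligible, and
unit weights keep the test oracles simple.  Deposition uses per-axis
integrated Gaussians (normal-CDF differences across each voxel), so the map
integral equals the atom count regardless of sampling.  A consequence of
the width convention: two point atoms merge into a single maximum only when
closer than about $2\sigma \approx 0.37 \times$ resolution.

Projections use the ZYZ convention ($\Phi$ about z, then $\Theta$ about y,
in-plane $\omega$ handled in 2D).  Two routes exist and are tested against
each other: rotating the voxel grid with trilinear interpolation and
summing along z (`project()`), and the analytic route that projects the
Gaussian atoms straight to 2D (`project_model()`), which is exact and fast
and is what library generation uses.  Projection libraries cover the view
sphere at a configurable angular step (8° by default) with φ sampling
thinned by sin θ so arc spacing is approximately uniform.

`match_projection()` normalizes images to zero mean and unit variance
inside a circular mask of radius 0.45 × box (the reference software's
masking and normalization are not documented; a fixed fraction is a
reproducible replacement), searches the in-plane rotation on a grid
(default 2°) and the translation via the FFT cross-correlation peak.
Candidates are scored by the parabola-interpolated peak height — scoring
raw integer-pixel peaks systematically penalizes alignments whose true
shift is fractional.  Exact ties go to the lowest library index.  The
reported CCC is the Pearson correlation over the mask after alignment.
Intensity scale between projection and image is a least-squares scalar
after mean subtraction (negative-stain contrast is arbitrary).

`sequential_fit()` reproduces the two-stage fit: match body 1 (the
ectodomain without the αA domain), subtract its aligned, intensity-scaled
projection, then match body 2 (the αA/Fab moiety) into the difference
image.  The composite CCC correlates the image with the joint least-squares
combination of both aligned projections over the same mask, so it is
directly comparable to the single-body CCC; on two-body data the composite
value exceeds the single-body value, the same qualitative improvement
(0.79 → 0.88) that motivated the two-body model in the source analysis.
A body-2 CCC below 0.3 against the difference image flags body 2 as absent
(negative control).

FSC is the per-shell normalized correlation of Fourier coefficients,
$\mathrm{FSC}(k) = \mathrm{Re}\sum F_1 \bar F_2 / \sqrt{\sum |F_1|^2 \sum
|F_2|^2}$; `resolution_at()` interpolates the 0.5 crossing linearly in
frequency.  Shells where either map has no power are defined as
correlation 0.  `lowpass_map()` uses a *sharp* Fourier cutoff by design: a
per-shell-constant (e.g. Gaussian) filter cancels exactly in the FSC ratio
and would leave FSC ≡ 1 in every shell, whereas a sharp cutoff makes the
0.5 crossing land at the cutoff frequency — the property the band-limit
check relies on.

## Euler-angle recovery metric

Recovered views are compared by the angle between view axes rather than by
differencing (Φ, Θ): Φ is degenerate at the poles, and near-axial views of
blobby bodies genuinely cannot pin the in-plane/azimuthal split.  Recovery
within the library's angular step is only a well-posed claim for bodies
with no rotational symmetry; the synthetic test bodies (an asymmetric
tripod and a bent L with an out-of-plane knob) are chiral for exactly this
reason.

## Synthetic data: what it does and does not emulate

`make_toy_integrin()` builds a geometric stand-in, not a protein: an
α-chain Cα rod (5 Å spacing) ending at the terminal residue at the origin,
a disulfide pair whose Sγ midpoint sits exactly on the rod axis, a short
β-chain stub, and a pseudo-Fab of lysines whose Cα centroid lands at an
analytically known offset (jitter is centred, so the centroid is exact by
construction).  Defaults — 100 Å leg, centroid 71 Å above the terminus and
25 Å off-axis — put the toy at the physical scale of a bent integrin
ectodomain with its Fab at the experimentally reported height.

`simulate_lifetimes()` draws per-cell lifetimes from the fitted study
distributions (donor 2,234 ± 88 ps; donor+acceptor 1,529 ± 115 ps).  The
cell count per condition is not printed in the source; the default n = 176
is back-solved so that a 95% CI of ±13 ps on the fitted mean corresponds
to σ = 88 ps, giving the synthetic data the study's statistical texture.
An optional uniform outlier fraction (default 0) mimics the minor
off-distribution cell populations seen in real data.

`make_synthetic_class_average()` composites one or two body projections at
known views and adds Gaussian noise with SD `noise_sd · peak / sqrt(n_averaged)`
— averaging n particles suppresses noise by √n.  Ground truth is attached
to the image and written to a JSON side-car next to MRC output.

What passing tests on these fixtures *do not* show: real negative-stain
data has structured background, stain artefacts, CTF effects, conformational
heterogeneity and non-Gaussian noise; real lifetime data has instrument
response and multi-exponential decays (handled upstream of this package);
and real atomic models have flexible linkers the rigid-body scan ignores.

## Problem sizes and numerical choices

The test-suite and acceptance problem sizes are chosen so the full suite
runs in well under a minute of compute per module: 48-pixel boxes at 3
Å/px, 8–20° libraries, 2,664-sample scans, 100 fit replicates at n = 176.
All generators are pure functions of their seeds (the RNG state of the
caller is saved and restored), reports are byte-reproducible, and every
tolerance asserted in the tests (1e-6 Å rigid-geometry identities, one
grid step for angular recovery, 3 ps fit bias) is stated with its
rationale in the relevant help page or above.

Known limitations: the scan treats the ectodomain as rigid; the membrane
is a half-space with no thickness or curvature; MRC I/O is limited to mode
2; `match_projection` searches a single global in-plane grid rather than
refining locally; and the linker offset default is a guess, clearly
flagged as such.
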