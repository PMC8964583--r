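---
title: "Traction reconstruction under a force monopole: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traction reconstruction under a force monopole: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearTFM)
```

## The mechanical model

The substrate is treated as a linear-elastic, isotropic, semi-infinite
half-space. This is the standard TFM idealization: the gel is much
thicker than both the adhesion size and the depth of the marker beads,
so finite-thickness corrections are omitted (a documented limitation —
on thin gels the half-space kernel overestimates compliance). Only
in-plane tractions and displacements are modelled; out-of-plane
components are out of scope.

A tangential point force $F$ on the surface displaces the surface by
$u_i = G_{ij}(r)\,F_j$ with the Boussinesq/Cerruti tensor

$$G_{ij}(r) = \frac{1+\nu}{\pi E\, |r|}\Big[(1-\nu)\,\delta_{ij} +
\nu\,\hat r_i \hat r_j\Big].$$

The $1/|r|$ singularity makes point-force fits ill-posed and makes the
$k=0$ Fourier mode non-invertible. Both problems disappear when each
adhesion is represented as a **disc of uniform traction**: integrating
$G$ over the contact area gives a displacement field that is finite
everywhere, equals $u = q\,a\,(1+\nu)(2-\nu)/E$ at the center of a disc
of radius $a$ under traction $q$, and converges to the point-force
solution with $F = \pi a^2 q$ far away.

### Numerical evaluation of the disc integral

In polar coordinates centred on the *evaluation* point the $1/\rho$
singularity cancels the Jacobian exactly, and the radial integral
reduces to the chord length $L(\varphi)$ of the disc along each
direction:

$$u_i(x) = \frac{1+\nu}{\pi E}\int_0^{2\pi} L(\varphi)
\big[(1-\nu)\delta_{ij} + \nu\, e_i(\varphi) e_j(\varphi)\big]\,
q_j\, d\varphi .$$

For interior points the integrand is smooth and periodic, so a midpoint
rule converges spectrally. For exterior points only the cone of
directions subtending the disc contributes; the substitution
$\sin\psi = (a/d)\sin u$ removes the square-root endpoint kinks, so the
same node count retains full accuracy at any distance. The default is
720 angular nodes; beyond 5 radii the point-force form is used instead
(configurable), where its relative error is already far below the
quadrature target of $10^{-3}$. Both the center closed form and an
independent brute-force polar Riemann sum validate the scheme in the
test suite.

## The circular-patch force fit

Given per-frame patch geometry, the displacement predicted at the PIV
grid is linear in the stacked per-patch force vector, and the forces
minimize $\|u_\text{meas} - A F\|^2$ over the *valid* PIV vectors
(invalid vectors are excluded, never interpolated into the fit).
Deliberately, **no regularization** is applied: regularized inversions
bias absolute magnitudes downward, and the absolute net force is
exactly what is compared against the calibrated needle force. A
rank-deficient design matrix (e.g. duplicated patches) falls back to
the minimum-norm solution and is flagged in the diagnostics.

Patch geometry per frame:

- **Centers** are the local maxima of the displacement-magnitude map
  inside user-drawn search windows (one adhesion per window), with a
  deterministic tie-break (lowest row, then column). Windows should be
  drawn tightly around adhesions (in practice from the zyxin image):
  with a strong monopole the long-ranged background deformation can
  otherwise pull the maximum of a weakly loaded window toward a loaded
  neighbor.
- **Radii** are estimated per frame as the minimum of half the distance
  to the nearest other center and the radius at which the azimuthally
  averaged magnitude falls to half its center value, clamped to
  1–10 µm; the **common radius** used for all frames is the median of
  the per-frame estimates. The half-max rule is a documented stand-in
  for the original procedure, whose details are not public; radius
  misestimation affects individual patch forces more than the net
  force, which is dominated by the far-field (monopole) content of the
  fit.

## PIV

Displacements come from FFT cross-correlation of mean-subtracted
64-pixel windows at 50% overlap (the acquisition settings this pipeline
targets), with:

- three-point Gaussian subpixel interpolation per axis (parabolic
  fallback for non-positive samples). On window-periodic test images the
  estimator is exact for integer shifts; on real (aperiodic) images the
  window-edge through-flow limits subpixel accuracy to roughly 0.1 px,
  which is the tolerance asserted in the tests;
- peak-ratio SNR validation (primary/secondary peak, secondary searched
  outside a 3 px exclusion zone) at threshold 1.5;
- the normalized median test (8-neighbor residual, $\epsilon$ = 0.1 px)
  at threshold 2.0, applied per component.

Filters only flag vectors invalid; values are never altered. For FTTC,
which needs a complete grid, invalid vectors are filled by iterated
averaging of valid 8-neighbors.

## FTTC baseline and GCV

The per-wavevector Boussinesq operator is diagonal in the
$(\hat k, \hat k_\perp)$ basis with singular values
$2(1+\nu)(1-\nu)/(E|k|)$ and $2(1+\nu)/(E|k|)$. The operator is
normalized by its largest singular value so the 0th-order Tikhonov
parameter $\lambda$ is dimensionless and transferable across grids and
moduli. The $k=0$ mode is excluded — it is exactly the monopole mode,
which is why FTTC is only used at $t=0$ and for cross-validation. The
displacement grid is mean-padded to a power-of-two square before the
FFT to limit wrap-around of the long-ranged kernel, the apron is
discarded afterwards, and the returned map is re-centred so the
traction sums to zero exactly (a convention: the operator carries no
net-force information).

GCV evaluates
$V(\lambda) = \frac{(1/m)\|(I-A(\lambda))u\|^2}{[(1/m)\,\mathrm{tr}(I-A(\lambda))]^2}$
exactly from the per-mode filter factors ($m = 2(N_\text{pix}-1)$,
$k=0$ excluded), minimized over a log-spaced grid with golden-section
refinement — fully deterministic. A dense-matrix SVD brute force on a
tiny grid verifies the closed form in the tests.

## Needle calibration and shear force

A PDMS micropillar (length 6 µm, radius 2 µm, E = 801.5 kPa in the
reference configuration) acts as a cantilever of stiffness
$k = 3EI/L^3$, $I = \pi r^4/4$. Because the pillar is short and thick,
a Timoshenko shear correction
$k \to k / [1 + 3EI/(\kappa G A L^2)]$ with Cowper's
$\kappa = 6(1+\nu)/(7+6\nu)$ is applied by default; an optional
base-tilt factor is exposed but off by default, since which correction
terms the original procedure used is not documented. Calibration
regresses pillar force (pillar stiffness times on-axis deflection) on
needle bending (manipulator distance minus tip distance); the OLS slope
is the needle spring constant, and the same movement axis must be used
for calibration and shearing. The shear force is then
$F(t) = k_\text{needle}\,\times$ bending$(t)$.

## Force moments

With an external force, the first moment of the traction distribution
depends on the reference point: shifting the origin by $d$ changes the
moment tensor by $-d \otimes M$ (monopole $M$). All moments are
therefore taken about the **magnitude-weighted contractile center**,
and this convention is stamped into every output. Reported are the
monopole, the signed eigenvalues of the symmetrized first-moment tensor
ordered by magnitude (major/minor dipole; negative = contractile), the
torque (antisymmetric part), and the center itself.

## The synthetic-data generator

The generator emulates the reference experimental conditions: a
16.5 kPa, $\nu = 0.5$ polyacrylamide substrate; 0.1625 µm pixels
(6.5 µm camera pixel, 40× objective); 0.85 fps; needle speeds 2 µm/s
(calibration) and 5 µm/s (shearing); 9 adhesion patches of 1.5–2.5 µm
radius on a cell-sized ellipse; baseline contractility 10 nN per
peripheral patch (a typical focal-adhesion-cluster force for
fibroblasts on gels of this stiffness); an external force ramping from
zero to 100 nN. Three scenarios encode the characteristic behaviors:

- **perpendicular** — elongated cell loaded through its lateral
  adhesion clusters; the monopole grows perpendicular to the major
  dipole, which stays essentially constant;
- **colinear** — the patch under the needle carries half the load, the
  trailing-edge patches the rest; the force balance crosses over from
  dipole- to monopole-dominated mid-ramp;
- **rupture** — colinear geometry in which three tension-side patches
  rupture mid-ramp and their load is redistributed to the surviving
  load-bearing patches, with exact per-frame force accounting
  ($\sum_k F_k = F_\text{ext}$ always).

Beads are rendered as continuous Gaussians at seeded random positions
and displaced analytically (no raster warping), so sub-pixel PIV
validation carries no interpolation bias. What the generator does *not*
emulate: PSF aberrations, photobleaching, bead polydispersity, focal
drift, substrate nonlinearity or finite thickness, and biological force
fluctuations. Passing tests therefore demonstrate correctness of the
reconstruction mathematics under the stated model, not robustness to
every imaging artifact of real data.

Displacement noise in simulations is Gaussian with standard deviation
expressed as a fraction of the RMS displacement magnitude of the frame
(an SNR convention). Identifiability of the *weakest* patches degrades
if the same fraction is referred to the maximum displacement instead,
because a monopole-dominated frame has a large maximum; the net force
remains accurate in either case.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use field-level analysis
grids of 2.6 µm pitch (half the 64 px/50% PIV pitch at 0.1625 µm/px)
over an 83 µm field, 384² px bead images with 2200 beads for the
image-level end-to-end runs, and 10–18 frame ramps; these sizes resolve
all scenario phenomenology while keeping a full run in the minutes
range. The rupture analysis uses a 1.3 µm grid: the post-rupture force
floor of a dead adhesion is set by center/radius estimation error,
which finer sampling keeps below 10% of the pre-rupture force.
Degenerate inputs are handled explicitly: all-zero search windows fall
back to the window centroid with a warning; an all-zero field is an
error for GCV and the contractile center; flat correlation maps are
invalid with SNR 1; negative needle bending (slip) is flagged but kept.

## Known limitations

- Half-space, in-plane mechanics only; no finite-thickness or
  out-of-plane corrections.
- Circular patches only; elliptical adhesions are approximated by
  discs (reported elsewhere to have little effect on reconstructed
  forces).
- The radius rule and the center-detection field are documented
  conventions, not reproductions of the original (unpublished)
  procedure.
- Windows are user input; there is no automatic adhesion proposal from
  fluorescence images.
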