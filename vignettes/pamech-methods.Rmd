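---
title: "Methods: pulmonary-artery wall mechanics and microstructure with pamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulmonary-artery wall mechanics and microstructure with pamech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamech)
```

`pamech` quantifies how chronic hypoxia-type remodeling changes the
passive mechanics, vasoactive function and wall microstructure of small
pulmonary arteries studied ex vivo. This vignette documents the models,
the numerical choices, and what the synthetic-data generators do and do
not emulate.

## Thin-wall kinematics and mean stresses

A cannulated vessel under transmural pressure $P$ and axial force $f_T$
is treated as a thin-walled incompressible cylinder. The traction-free
excised state (length $L$, outer diameter $OD$, thickness $H$) is the
reference configuration; the wall volume
$\bar V = \pi L (OD^2 - ID^2)/4$ with $ID = OD - 2H$ is conserved, so the
loaded inner radius follows from the measured outer radius and length,
$r_i = \sqrt{r_o^2 - \bar V/(\pi l)}$, and the loaded thickness
$h = r_o - r_i$ is always derived, never measured. Mean stretches are
$\lambda_\theta = (r_i + r_o)/(2\rho_{mid})$ and $\lambda_z = l/L$, and
the mean Cauchy stresses are
$$\sigma_\theta = \frac{P r_i}{r_o - r_i}, \qquad
  \sigma_z = \frac{f_T + P \pi r_i^2}{\pi (r_o^2 - r_i^2)}.$$
A 2-D mean-stress formulation is appropriate here because residual
stresses tend to homogenize the transmural stress field; opening-angle
(thick-wall) analysis is deliberately out of scope. Raw data stay in lab
units (mmHg, µm, mN) and all mechanics is computed in SI with
1 mmHg = 133.322 Pa. Camera diameters are interpreted as outer-edge
diameters, the standard for these devices.

## Four-fiber-family constitutive model

The passive response is modeled by the stored-energy function
$$W = \frac{c}{2}(I_c - 3) + \sum_{i=1}^{4}
  \frac{c_1^i}{4 c_2^i}\Big\{\exp\big[c_2^i (IV_c^i - 1)^2\big] - 1\Big\},$$
with $I_c = \lambda_\theta^2 + \lambda_z^2 +
(\lambda_\theta\lambda_z)^{-2}$ and
$IV_c^i = \lambda_\theta^2\sin^2\alpha_0^i +
\lambda_z^2\cos^2\alpha_0^i$. The isotropic term represents the
elastin-dominated matrix; the four exponential families represent
collagen-dominated fibers along the axial ($\alpha_0 = 0$),
circumferential ($90^\circ$) and two symmetric diagonal
($\pm\alpha_0$) directions, the diagonal pair sharing $(c_1, c_2)$,
leaving 8 free scalars. The energy is implemented exactly as written —
even in $(IV_c - 1)$, with no tension-only switch — because that is the
stated form; a tension-compression switch can be emulated by setting the
relevant $c_1$ to zero. The removable $c_2 \to 0$ singularity is
evaluated through `expm1`, so the quadratic limit
$(c_1/4)(IV_c - 1)^2$ is exact to machine precision.

Stresses and stiffness come from analytic first and second derivatives
of the reduced (incompressible, zero-radial-stress) energy:
$\sigma_i = \lambda_i \, \partial\hat W/\partial\lambda_i$, and the
small-on-large linearized stiffness about a deformed state,
$$\mathcal{C}_{iiii} = 2\sigma_i +
  \lambda_i^4 \frac{\partial^2 \hat W}{\partial E_{ii}^2}
  = \lambda_i \frac{\partial \sigma_i}{\partial \lambda_i},$$
with $E_{ii} = (\lambda_i^2 - 1)/2$ the Green strains. Because stiffness
conventions differ between laboratories, both derivative identities are
enforced by finite-difference oracles in the test suite (relative
tolerances $10^{-6}$ for stresses, $10^{-4}$ for stiffness), so the
convention is testable independent of any reported number. Stiffness and
stored energy are reported at 5, 15 and 25 mmHg (diastolic, mean,
systolic) at the vessel-specific in vivo axial stretch.

## Parameter estimation

The 8 constants are estimated from all seven passive protocols at once.
For each record the stretches come from the measurements (outer radius
plus incompressibility, never refit); the model predicts $(P, f_T)$
through the equilibrium inversion
$P = \sigma_\theta (r_o - r_i)/r_i$,
$f_T = \sigma_z \pi(r_o^2 - r_i^2) - P \pi r_i^2$; and the objective is
$$J = \sum_k \Big[\tfrac{P^{mod}_k - P^{exp}_k}{\bar P}\Big]^2 +
  \Big[\tfrac{f^{mod}_k - f^{exp}_k}{\bar f}\Big]^2,$$
normalized by the per-vessel means so both channels carry comparable
weight and the fit is unit-invariant. Optimization is bound-constrained
Levenberg-Marquardt (`minpack.lm`) from Latin-hypercube starts (default
20; moduli sampled on a log scale because the plausible mass of the box
lies near its lower corner), with bounds $c, c_1 \in [0, 10^4]$ kPa,
$c_2 \in [0, 50]$, $\alpha_0 \in (5^\circ, 85^\circ)$ to keep the
diagonal family distinct from the axial/circumferential members. Ties
are broken by the smaller parameter norm, and the diagonal symmetry
holds exactly by construction.

On noise-free synthetic data all 8 parameters are recovered to well
under 1% and $\alpha_0$ to well under $0.5^\circ$. With 2%
multiplicative measurement noise the *parameters* are not reliably
recoverable: the fitted objective falls below the ground truth's
objective on every replicate, i.e. the data genuinely prefer displaced
parameter combinations along near-flat directions of the exponential
model — the well-known sloppiness of four-fiber parameterizations. The
*mechanical predictions* remain accurate (the
$\sigma_\theta(\lambda_\theta)$ curve is recovered to a few percent
pointwise), so downstream stiffness, energy and PWV metrics are robust
even when individual constants are not. Users should compare predicted
quantities, not raw constants, across vessels.

## Distensibility and pulse wave velocity

Distensibility is the normalized diameter change between the diastolic
and systolic evaluation pressures (default 5 and 25 mmHg),
$D = [(d_{sys}-d_{dias})/d_{dias}]/\Delta P$ in Pa$^{-1}$, and the
Bramwell-Hill velocity is $PWV = \sqrt{1/(\rho D)}$ with blood density
$\rho = 1050$ kg m$^{-3}$. Both the measured-diameter path and the
model-predicted-diameter path are supported. Note a convention caveat:
the Bramwell-Hill derivation concerns *area* distensibility, which is
twice the diameter-based value for small pulses, so diameter-based PWV
is exactly $\sqrt 2$ above the Moens-Korteweg speed
$\sqrt{E h/(2\rho r)}$ of the matching thin linear tube; the package
exposes `basis = "area"` for the convention under which the two
formulas coincide (verified to within 5% on a thin nearly linear tube,
using the linearized circumferential stiffness as the incremental
modulus). The diameter basis is the default because that is how the
quantity is defined for reporting.

## Vasoactive responses

Contraction (KCl, phenylephrine) and endothelium-related (ACh, L-NAME)
assays are diameter time series at 15 mmHg and the vessel-specific axial
stretch. Traces are normalized by the agent-specific baseline at
$t = 0$ (pre-stimulus diameter for constrictors; the post-PE/ACh
diameter for L-NAME), and the endpoint metric is
$100\,[1 - d(15\,\mathrm{min})/d(0)]$, linearly interpolated if no
sample falls exactly at 15 min; contraction is positive. Group
summaries average per-vessel endpoints (mean ± SEM) rather than taking
the endpoint of the mean trace; for linear operations the two orders
agree, and per-vessel endpoints are what the group statistics need.

## Orientation statistics from multiphoton stacks

Stacks are three channels (collagen SHG, elastin autofluorescence,
nuclei) with 0.48 µm in-plane pixels and 1 µm depth steps. The pipeline:

1. **Circle fit.** Per circumferential-radial slice, ray-cast
   intensity-weighted mid-thickness points from a coarse centroid, then
   an algebraic least-squares (Kåsa) circle fit in physical
   coordinates (anisotropic voxels handled). The cylinder is assumed
   straight: the median center/radius over a slice subsample is used.
2. **Polar unwrap.** Bilinear resampling onto a regular (angle, radius)
   grid, with the angular step chosen so the mid-wall arc length per
   sample is about one pixel.
3. **Layer segmentation.** The media lies between the internal and
   external elastic laminae, found as the innermost and outermost peaks
   of the radial elastin profile; wall edges are taken at 10% of the
   peak total signal. Layers are radial bands — adequate for
   near-cylindrical vessels, not for locally delaminated walls.
4. **Structure tensor.** The acquisition does not fix an orientation
   method, so the package uses the field standard for SHG fiber images:
   a 2-D structure tensor (gradient scale 1 px, integration scale 2 px)
   on each axial-circumferential plane of the layer's radial band
   separately, pooling angles across planes. Analyzing planes
   separately matters: projecting the band first and tensor-averaging
   crossing fibers from different depths inflated the concentration
   parameter about two-fold on phantoms. Per-pixel angles are corrected
   for the arc length per angular sample at the plane's radius, and
   pixels are weighted by coherence$^2 \times$ energy with a strict
   coherence cutoff (0.8).
5. **Axial von Mises fit.** Fibers are axial data (period 180°), so
   angles are doubled, the weighted circular mean and resultant
   $\bar R$ computed, and the ML concentration solved from
   $I_1(\kappa)/I_0(\kappa) = \bar R$ by Newton iteration from the
   standard series initialization, capped at $10^3$. Whether the
   original acquisitions summarized width by a von Mises $\kappa$ or
   another parameterization is unknown; the von Mises choice is the
   common one for axial fiber data and is what the generators sample
   from, so recovery is testable end to end.

## Nuclear densities

Nuclei are smoothed (1.5 µm), thresholded by Otsu's rule over the wall,
grouped into 6-connected 3-D components, filtered by a minimum volume
(7 µm³), and merged components are split at strict 26-neighborhood
intensity maxima separated by at least 4 µm (a nuclear diameter) — a
local-maxima splitting that behaves like seeded watershed on blob-like
nuclei while being simpler to verify. Detection runs over the whole
wall and each peak is assigned to a layer by its radial position;
detecting inside a layer mask instead double-counts boundary-straddling
nuclei as clipped fragments. Medial/adventitial densities are reported
per 0.001 mm³ of layer volume, the intimal density per 0.01 mm² of
luminal surface. The adventitia's outer edge is the least certain
boundary (signal-dropoff based), so its densities carry more systematic
uncertainty than the lamina-bounded media.

## Histology area fractions

Stained sections (VVG → elastin, trichrome → cytoplasm, Movat → ground
substance and fibrin) are quantified as stain-positive pixels over
tissue pixels after illumination correction (division by a large-radius
morphological closing of the brightness channel) and HSV-window
thresholding; the tissue mask is eroded by 3 px because section-edge
pixels mix with the slide background and carry no reliable stain
identity. Because trichrome overstains collagen, the collagen fraction
is the complement $1 - (\phi_{ela} + \phi_{cyt} + \phi_{gnd} +
\phi_{fib})$; the four-term variant is the default since only with all
four measured constituents do typical group-mean compositions close to
100%, and a two-term variant ($1 - \phi_{ela} - \phi_{cyt}$) is
available behind a flag. The default HSV windows are calibrated on the
synthetic stain panel, with cuts placed at the 50% color-mixture points
so boundary-pixel errors cancel to first order; real-slide use requires
recalibrating the windows to the scanner and staining batch.

## Statistics

Two-group comparisons use the classical pooled-variance two-tailed
unpaired t test (Welch by flag); metrics across pressure/stretch levels
use two-factor ANOVA (`aov`) with global F tests and Bonferroni-adjusted
pairwise comparisons, $p_{adj} = \min(1, m p)$; structure-function
relations use ordinary least squares with $R^2$ (squared Pearson
correlation) and t-based 95% confidence bands. Summaries are mean ±
SEM. Under a simulated null (10⁴ replicates, 2 × 3 design, n = 5 per
cell) the global test's type-I error sits at the nominal 5% within
Monte-Carlo error.

## Synthetic data: what it emulates, and what it does not

Every input modality has a generator with a machine-readable
ground-truth sidecar, and all generators are pure functions of
(specification, seed):

* **Biaxial protocols.** Three pressure sweeps (0–30 mmHg, 1 mmHg
  steps) at 0.95/1.00/1.05 × the in vivo axial stretch plus four axial
  sweeps (0.90–1.10 ×, 21 points) at 5/10/15/20 mmHg — 177 records.
  The seven-protocol composition is an assumption (the protocol set of
  such experiments is rarely enumerated); it spans the
  $(\lambda_\theta, \lambda_z)$ domain for identifiability and is
  labeled in the output so the fitter stays protocol-agnostic. Default
  ground truth: a 4 mm segment, 900 µm unloaded OD, 60 µm wall, in vivo
  axial stretch 1.4, $c = 18$ kPa with soft exponential families —
  order-of-magnitude plausible for murine pulmonary arteries (predicted
  PWV ≈ 2.2 m/s at 5–25 mmHg), not literature-fitted values.
  Measurement noise is 2% multiplicative Gaussian on diameter and
  force.
* **Vaso traces.** First-order responses
  $d(t) = d_0[1 - A(1 - e^{-t/\tau})]$ plus additive noise; $A = 0.35$,
  $\tau = 2$ min gives the canonical 34.98% endpoint at 15 min.
* **Image stacks.** A cylindrical shell with two Gaussian laminae
  (elastin), helical fiber segments at von Mises pitch angles in the
  adventitia (collagen; 600 segments by default, a dense SHG-like
  field), Poisson-placed ellipsoidal nuclei per layer, and optional
  Poisson shot noise. The phantom renders the full annulus, has no
  point-spread anisotropy beyond the voxel grid, no depth attenuation,
  and no undulated or bundled fibers — so passing recovery tests shows
  the geometry and estimators are correct, not that real-tissue
  contrast will be as kind.
* **Stain panels.** Compact Voronoi patches of the five constituents
  with exact realized pixel fractions, per-stain palettes, uneven
  illumination, blur and pixel noise. Real stains vary far more in hue.

Problem sizes in the test suite (e.g. phantom vessels of 40 µm outer
radius at 1 µm voxels, 10–50 phantom replicates, 10⁴ ANOVA replicates)
are chosen so the whole suite exercises every pipeline end to end at
desk scale while keeping Monte-Carlo error well below the asserted
tolerances.

## Known limitations

* Parameter sloppiness under realistic noise (see Estimation): report
  predicted mechanics, not constants.
* No viscoelasticity, active-stress terms, growth/remodeling, or
  thick-wall residual-stress analysis.
* Layer masks are radial bands; strongly eccentric or damaged vessels
  violate the cylindrical assumption.
* Histology thresholds are phantom-calibrated defaults, not universal
  stain classifiers; no stain deconvolution.
* No uncertainty quantification on fitted parameters (bootstrap CIs are
  future work).
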