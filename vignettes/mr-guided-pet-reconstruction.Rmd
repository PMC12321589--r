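---
title: "MR-guided penalized PET reconstruction: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-guided penalized PET reconstruction: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgpet)
```

## The reconstruction problem

PET measures coincidence counts $y_i$ along lines of response (LORs) $i$,
modelled as independent Poisson variables with expectation
$\bar y_i(u) = n_i \, [A \, b(u)]_i + r_i$, where $u$ is the activity image,
$A$ the geometric system matrix (here: exact ray–pixel intersection lengths
of a parallel-beam geometry with angles evenly spaced over $180^\circ$),
$b(\cdot)$ an isotropic image-space Gaussian point-spread function, $n_i$
per-LOR multiplicative normalization factors and $r_i$ an additive
background. Maximum-likelihood reconstruction minimizes

$$\sum_i \bar y_i(u) - y_i \log \bar y_i(u),$$

which MLEM solves with the multiplicative update
$u \leftarrow (u / s) \cdot A^T (y / \bar y)$, $s = A^T n$ being the
sensitivity image. OSEM accelerates this by cycling over interleaved angle
subsets. Unregularized (OS)EM images become progressively noisier with
iteration number, which in routine practice is hidden by stopping early and
post-smoothing with a Gaussian filter — at the price of resolution and
tissue contrast.

## The Parallel Level Sets prior

When a co-registered anatomical MR image $v$ is available (as on an
integrated PET/MR system), its edges can guide the reconstruction. The
package minimizes the penalized objective

$$\sum_i \bar y_i(u) - y_i \log \bar y_i(u) \; + \; \beta \, P(u, v),
\qquad
P(u, v) = \sum_x \sqrt{\alpha^2 + |\nabla u(x)|^2 - (\nabla u(x) \cdot \xi(x))^2},$$

where $\xi = \nabla v / (|\nabla v|^2 + \eta^2)^{1/2}$ is the normalized
gradient field of the prior. Where the PET gradient is parallel to a strong
MR gradient ($|\xi| \to 1$), the integrand collapses towards $\alpha$ and the
edge is essentially free; PET gradients with no anatomical counterpart are
penalized as in smoothed total variation. Because $|\xi| < 1$ strictly (for
$\eta > 0$), the penalty never *rewards* gradients: it can only reduce the
smoothing at shared edges, which is what protects PET-specific features —
a lesion bright on MR but cold on PET is not pushed towards the MR
appearance (see the no-hallucination test below).

Three parameters control the prior:

| parameter | meaning | default | units |
|---|---|---|---|
| $\beta$ | overall penalization strength | user-set (0.5–2 typical) | dimensionless |
| $\alpha$ | integrand smoothing (differentiability at flat regions) | $0.01 \cdot \max(u_0)$ | activity/mm |
| $\eta$ | MR edge threshold (gradients $\ll \eta$ treated as noise) | $0.05 \cdot q_{99}(|\nabla v|)$ | prior-intensity/mm |

$\alpha$ and $\eta$ are resolved from the data at reconstruction time when
not set explicitly, and the resolved values are attached to the returned
trajectory (`attr(rec, "alpha")`, `attr(rec, "eta")`), so every
reconstruction is auditable. They scale with the image: $\alpha$ follows the
initial-estimate magnitude (which itself follows the count level), $\eta$
follows the prior's gradient distribution, so the *relative* behaviour of a
given $\beta$ is stable across dose levels.

## The optimizer

The penalized objective is minimized with a one-step-late (OSL) MAP-EM
update inside the ordered-subsets loop:

$$u \leftarrow u \cdot
\frac{A_s^T (n\, y / \bar y)}{s_s + (\beta / N_{\text{sub}}) \, \partial P / \partial u},$$

with the penalty gradient evaluated at the current estimate and
$\partial P/\partial u = G^T w$, $w = (\nabla u - \xi (\nabla u \cdot \xi)) /
\sqrt{\alpha^2 + |\nabla u|^2 - (\nabla u \cdot \xi)^2}$. The discrete
gradient $G$ uses forward differences divided by the voxel spacing with
replicate boundary, and $G^T$ is its *exact* matrix transpose, so the
analytic gradient agrees with central finite differences of the discretized
penalty to first order in the step (verified to relative error $<10^{-4}$ in
the test suite, and typically $\sim10^{-10}$).

Design choices worth recording:

* **OSL rather than a provably convergent variant.** OSL is the simplest
  penalized-EM scheme that slots into the standard subsets/iterations
  protocol. It is not guaranteed monotone; the suite therefore *tests*
  monotonicity of the objective empirically for the single-subset case
  rather than assuming it. A De Pierro-style surrogate would be the natural
  extension if guarantees were needed.
* **Denominator clamping.** The OSL denominator $s_s + (\beta/N)\partial P$
  can approach zero when $\beta$ is far too large for the count level; it is
  clamped below at $10^{-3} \, s_s$ (configurable) and a warning is emitted
  when the clamp is active on more than half of the field of view.
* **$\beta$ split across subsets.** Each sub-iteration sees $\beta/N_{\text{sub}}$,
  so the accumulated penalty pressure per full iteration is independent of
  the subset count.
* **$\beta = 0$ short-circuit.** The penalty branch is skipped entirely, so
  the guided algorithm with $\beta = 0$ reproduces OSEM *bitwise* — a tested
  contract, not an approximation.
* **Post-filtering policy.** The Gaussian post-filter (3 mm FWHM by default,
  $\sigma = \text{FWHM} / 2\sqrt{2\ln 2}$) is applied only to OSEM output;
  guided reconstructions are returned unfiltered. This mirrors how the two
  algorithms are deployed clinically and how they are compared here.
* **Subset order.** Angle $j$ goes to subset $j \bmod N$; subsets are visited
  in bit-reversed order for balanced angular coverage.
* **Blur self-adjointness.** The PSF and the post-filter use a separable
  Gaussian with half-sample-symmetric (mirror) boundary. This operator is
  self-adjoint, maps flat images to flat images and preserves the total
  image sum, which keeps the forward/backward projector pair exactly adjoint
  with resolution modelling enabled — the property the EM count-conservation
  identity relies on.

## The synthetic phantom and what it does (not) emulate

`generate_brain_phantom()` builds a 2-D single-slice digital phantom in the
spirit of the Hoffman brain insert: an elliptical brain with an outer CSF
rim, a convoluted cortical gray-matter ribbon (sinusoidal "gyral"
perturbation of the gray/white interface; harmonic phases drawn from the
seed), a white-matter core and two ventricles. Activity is piecewise
constant at GM:WM:CSF $= 4{:}1{:}0$ — the ratio that defines the contrast
recovery coefficient — and the T1-like prior (WM $= 1.0$ > GM $= 0.6$ > CSF
$= 0.1$) shares every tissue boundary with the activity image. A 2-D slice
was chosen deliberately: every algorithmic property being validated
(adjointness, EM contracts, penalty geometry, dose trends) is
dimension-agnostic, and the slice keeps full sweeps in seconds. The true
Hoffman insert geometry is proprietary; any convoluted 4:1:0 geometry
serves the same validation purpose.

Acquisition is emulated by forward-projecting the phantom, scaling the
expectation to a target count level (default $2 \times 10^6$ expected events
for a 128×128 slice — a realistic single-slice count budget for a ~10-minute
brain acquisition), drawing Poisson counts, and thinning with element-wise
binomial sampling to emulate dose levels of 50/25/12.5% — statistically
exact for listmode subsampling (thinned Poisson counts are Poisson with the
thinned mean, a tested property). What is *not* modelled: scanner ring
geometry, time-of-flight, attenuation/scatter/randoms estimation (their
effects enter only through the optional $n_i$, $r_i$ terms, defaults 1 and
0), detector normalization, patient motion, and MR segmentation or
registration error (prior and activity are perfectly co-registered by
construction, except where a mismatch lesion is inserted on purpose).
Passing phantom trends therefore validate the algorithm and its
implementation — not the full clinical correction chain.

Focal lesions are inserted with independent PET and MR multipliers, which
covers the two clinically interesting mismatch cases: hypermetabolic
lymphoma-like lesions (PET ×3, MR ×1) and PET-cold but MR-bright
angioma-like lesions (PET ×0.25, MR ×2).

## Measurement ROIs

Quantitative metrics need tissue ROIs placed well inside each compartment.
The published ROI schemes for the physical phantom are not reproducible from
their citation alone, so the package places its own: by default, every voxel
of a tissue at least 2 voxels from the tissue boundary ("eroded" mode; large
stable samples for noise statistics), or a single disk at the deepest
interior point of each tissue (distance-transform maximum, "disk" mode,
emulating manually drawn circular ROIs). The standard deviation in COV and
CNR is the sample SD (denominator $n-1$); the convention is stated here
because published formulas leave it open.

## Validation problem sizes

The shipped tests and the acceptance script use: 16×16 grids with 12 angles
for operator (adjoint) checks; 8×8 image/prior pairs for the
finite-difference gradient oracle; a 64×64 phantom with 120 angles for the
EM contracts (50-iteration likelihood monotonicity and count conservation)
and for noise-free recovery (200 MLEM iterations, radial bins at 0.8 mm —
finer than the 1.2 mm voxels, as scanner radial sampling usually is — reach
a normalized RMSE below 5%); and the full 128×128 phantom at $2\times10^6$
counts for the dose-trend study (20 subsets, metrics read at iteration 6,
doses down to 12.5%, $\beta \in \{0.5, 1, 2\}$, 10 noise seeds). The
PET-cold/MR-bright robustness fixture uses a 10 mm radius (~2 cm diameter,
a typical conspicuous lesion size) and a $2\times10^7$-count acquisition,
reflecting that lesion protocols reconstruct the full acquisition for best
image quality; the guided and unguided lesion means are required to agree
within 10%.

Two caveats the trend tests make explicit rather than hide: with a *cold*
mismatch lesion the guided lesion mean sits a few percent *below* OSEM —
the prior suppresses spill-in of surrounding white-matter noise across the
MR-visible boundary; the direction of the deviation is away from
hallucinated uptake. And at very low doses a large $\beta$ is needed before
the guided reconstruction's noise drops below that of 3-mm-filtered OSEM;
with $\beta = 2$ it comfortably beats *unfiltered* OSEM noise while
exceeding filtered OSEM's contrast, which is the clinically relevant
comparison pair.

## Known limitations

* 2-D single-slice geometry; the API treats 3-D as a size change, but the
  shipped projector is 2-D parallel-beam.
* OSL updates: empirical, not guaranteed, monotonicity for multi-subset
  runs.
* No SUV calibration (no dose/weight bookkeeping): all SUV-based ratios are
  computed on activity values, which is exact for every ratio used but
  means absolute SUVs are out of scope.
* The $\alpha$, $\eta$ defaults are declared package choices; scanner
  implementations keep their own (unpublished) fixed values, so absolute
  $\beta$ values are not transferable between implementations — only
  within-package comparisons are meaningful.
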