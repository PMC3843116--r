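---
title: "Methods: site-matched micromechanical prediction of lamellar bone indentation moduli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-matched micromechanical prediction of lamellar bone indentation moduli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellar)
```

## Scope and model overview

Lamellar bone at the sub-lamellar scale (a few micrometers, the size of a
nanoindentation interaction zone) is organized as an array of parallel
mineralized collagen fibrils embedded in an extra-fibrillar mineral foam.
This package predicts the indentation modulus at an indent site from two
locally measured covariates — the mineral volume fraction of the fibril
array, $\varphi_{mi,fa}$, and the out-of-plane fibril angle $\theta$ — and
provides the surrounding machinery: image calibration, modality
registration, covariate extraction, cohort statistics and a synthetic-data
generator with known ground truth.

The prediction chain is deterministic given the covariates:

$$\varphi_{mi,fa} \xrightarrow{\text{3-level Mori–Tanaka}} S_i
  \xrightarrow{\; r(\theta_i) = [0,\sin\theta_i,\cos\theta_i] \;}
  \tilde E_{ind,i}$$

## qBEI calibration

Calcium weight fraction maps are converted to hydroxyapatite mass fraction
by the stoichiometric calcium share of Ca$_{10}$(PO$_4$)$_6$(OH)$_2$. The
constant (0.39894) is computed at run time from standard atomic masses
(Ca 40.078, P 30.974, O 15.999, H 1.008) rather than hard-coded at fewer
digits, so the canonical chain $0.25 \rightarrow 0.627 \rightarrow 0.38$
reproduces at documented precision. The mass-to-volume step uses the
empirical density relation
$\varphi = B\psi/(\psi - A\rho_{HA})$ with $A = 0.59$ ml/g, $B = -0.75$,
$\rho_{HA} = 3.16$ g/cm$^3$. The relation has a pole at
$\psi = A\rho_{HA} \approx 1.864$, far outside the physical domain of mass
fractions, but the implementation guards it defensively and rejects any
pixel whose output volume fraction leaves $[0, 1]$, reporting the offending
pixel coordinates. Thresholded porosity is represented by the raster mask,
never by $\varphi = 0$, so that disk averages stay unbiased.

## Three-level fibril-array homogenization

All tensors are stored as $6\times6$ matrices in the orthonormal Mandel
basis ($\sqrt2$ weights on shear components), in which matrix inversion
equals tensor inversion and matrix congruence equals tensor rotation. This
removes the factor-of-2 bookkeeping that plagues Voigt-notation
implementations of Eshelby algebra; Voigt matrices are accepted and emitted
only at I/O boundaries. The fibril axis is $e_3$; moduli are in GPa, angles
in degrees at interfaces and radians internally.

Given the total mineral volume fraction $\varphi$, the mineral quota
$q$ (default 0.25, interpreted as a *volume* quota — all fractions in the
calibration chain are volumetric) and the fibril volume fraction $f_{fib}$
(default 0.53), the phase partition is

$$f_{min/fib} = \frac{q\varphi}{f_{fib}}, \qquad
  f_{void/ef} = 1 - \frac{(1-q)\varphi}{1-f_{fib}},$$

both required to lie in $[0,1]$; parameter sets violating this are rejected
as infeasible (this matters for the Monte Carlo study below, where the
sampled corners $q \gg f_{fib}$ and $f_{fib} \to 1$ are arithmetically
infeasible and are redrawn, with the rejection count reported).

Each level is a two-phase Mori–Tanaka estimate with aligned spheroids,

$$C_{eff} = C_m + f\,(C_i - C_m)\,A\,[(1-f)I + fA]^{-1}, \qquad
  A = [I + P\,(C_i - C_m)]^{-1},$$

where $P$ is the Hill polarization tensor of the inclusion shape in the
matrix. For an isotropic matrix $P$ comes from the closed-form Eshelby
tensor of a spheroid (validated against the textbook sphere values to
1e-10 and the infinite-cylinder limit to 1e-4); a numerical route
(Gauss–Legendre × periodic-trapezoid integration of the inverse acoustic
tensor over the unit sphere) supports anisotropic matrices and serves as
the independent cross-check of the closed form.

Design choices where the design was genuinely open:

* **Scheme at the foam level.** The extra-fibrillar matrix is modeled as
  mineral with spherical voids by the *Mori–Tanaka* scheme (which for
  spherical voids coincides with the Hashin–Shtrikman upper bound, an
  identity used as a test oracle). A self-consistent alternative was
  evaluated and rejected: its percolation behavior at the default porosity
  (~0.39) softens the array so much that the cohort-mean axial prediction
  drops by ~10 GPa, inconsistent with the rest of the model chain.
* **Level-(c) matrix anisotropy.** With spherical voids the foam is exactly
  isotropic, so the closed-form Eshelby tensor applies at every level. If a
  non-spherical void phase ever makes the foam anisotropic, the package
  switches (flag-selectable) to either the Frobenius-closest isotropic
  projection of the matrix for the polarization tensor, or the fully
  numerical polarization integral; the two routes agree within a few
  percent on mildly anisotropic matrices and are tested against each other.
* **Void stiffness.** Voids are zero-stiffness inclusions, not a compliant
  placeholder. As $\varphi \to 0$ the foam degenerates; the model reports a
  degenerate-material error rather than returning a near-singular tensor.
* **Aspect-ratio semantics.** $a$ = axial length / equatorial diameter;
  the fibril aspect ratio 100 is evaluated by its exact prolate closed
  form, not the cylinder limit.

## Virtual indentation

The indentation modulus of the anisotropic half-space is computed by the
equivalent-modulus construction for axisymmetric indenters: rotate the
stiffness so the indentation axis is the surface normal $e_3$, form the
Barnett–Lothe tensor

$$B(\tau) = \frac1\pi \int_0^\pi
  \big[(mm) - (mn)(nn)^{-1}(nm)\big]\, d\phi,
  \qquad (ab)_{jk} = a_i C_{ijks} b_s,$$

for in-surface directions $\tau$, and average the normal–normal surface
compliance: $M = 2 / \langle (B^{-1})_{33} \rangle_\tau$. For isotropic
material this reduces analytically to $E/(1-\nu^2)$ (asserted to 1e-6 in
the tests); for transversely isotropic material indented along the symmetry
axis it matches the explicit contact-mechanics formula
$M_3 = 2\sqrt{(C_{11}C_{33}-C_{13}^2)\,/\,
\big(C_{11}(1/C_{44} + 2/(\sqrt{C_{11}C_{33}}+C_{13}))\big)}$ to 1e-4.
The equivalent-modulus definition is indenter-geometry independent for
axisymmetric tips; a Berkovich tip is treated through this equivalence.

Both angular integrands are smooth and periodic, so the periodic trapezoid
rule converges spectrally: 90 points per loop reproduce a 720-point
reference to ~1e-15 relative for every tensor arising in this model family,
including the extreme Monte Carlo corners. The default is therefore 90
points (a `check_convergence` flag re-evaluates at half resolution and
errors above 1e-6 relative change); the kernel is compiled (RcppArmadillo)
so one evaluation costs ~10 ms and the 10,000-draw Monte Carlo study runs
in minutes. For bulk per-site prediction a bilinear $(\varphi, \theta)$
interpolation grid (steps 0.01 and 3°) is provided and validated against
direct evaluation to better than 0.01 GPa over the physiological range.

## Site matching

Indent positions live in the light-microscope frame; each modality raster
is mapped by an in-plane rigid transform (translation + rotation). The
registration objective is the normalized SSD over the masked overlap after
z-scoring each modality (the images carry different physical quantities);
the optimizer is a deterministic exhaustive coarse grid over the search
window followed by Nelder–Mead refinement restricted to the free
coordinates. Registration of a known displacement recovers it to half a
pixel (0.25 µm), also under 5% additive noise, and is inverse-consistent.

Covariates are averaged over the indenter interaction zone, a disk of
radius $r_{in} = 1.75$ µm (diameter = 7 × 500 nm indentation depth).
Pixel centers at $(i - \tfrac12)\,\Delta$ are included when they fall
inside the disk (center-in-disk rule, no partial-pixel weighting): with
$r_{in}$ spanning only ~3.5 pixels this is the simplest defensible
discretization. Its boundary term fluctuates at any fixed center, so the
convergence test averages over many disk centers; the mean error decreases
systematically as the pixel size is refined 0.5 → 0.25 → 0.125 µm. Sites
whose zone holds no valid pixel are flagged `near_pore` and excluded
downstream, never silently dropped.

Load–displacement curve irregularity is *not* detected by the package (no
such data are in scope); it enters as a quality flag on the indent table,
and filtering retains only `ok` sites while logging counts per reason.

## Synthetic cohort

The generator emulates the study conditions: 29 patterns × 33 indents
(957 sites) on 60×60 µm tiles at 0.5 µm/px; osteonal mineralization
0.38 ± 0.02 and interstitial 0.39 ± 0.03 (region labels per tile, mixed
tiles split in half); fibril angles truncated-normal 32.3° ± 14.7° on
[0°, 73.2°] — the simplest parametric family consistent with all the
summary statistics; 74 of 957 sites flagged invalid; a known rigid
misregistration (default 3 µm, −2 µm, 0.5°) applied to the modality
rasters, with the calcium map emitted by inverting the calibration so a
pipeline run exercises the full chain.

Choices not fixed by any measured quantity:

* **Spatial correlation length 5 µm**, matching the width of an osteonal
  lamella; it affects only visual realism and the effective number of
  independent pixels, not the marginal statistics, and is configurable.
* **Pore placement.** Masked elliptical pores are placed in the margin
  band between patterns so that no interaction zone can be fully masked;
  partially overlapping zones still exercise the mask logic, and fully
  masked zones are tested separately. This keeps the filtered count of a
  default cohort deterministic (883 of 957).
* **Measurement noise SD 4.4 GPa** (coupled mode): chosen so model spread
  plus noise reproduces the measured cohort SD of ~5.1 GPa. Note that with
  this noise the coupled cohort still shows $r^2 \approx 0.2$–0.3 between
  measured and predicted moduli — additive noise alone cannot reproduce a
  near-zero correlation. The **decoupled mode** (measured moduli drawn
  N(23.99, 5.12) GPa independent of the covariates) exists precisely to
  reproduce that null regime; the discrepancy between the two regimes is a
  property of the data-generating assumptions, and both are exposed rather
  than hidden.

What passing tests on synthetic data do *not* show: the generator contains
no imaging texture, no spatially structured measurement error, no
registration-residual bias, and its fields are Gaussian; agreement on
synthetic cohorts demonstrates correctness of the pipeline, not validity of
the micromechanical model for real tissue.

## Statistics

Group comparisons use one-way ANOVA with Tukey's HSD (α = 0.05); measured
vs predicted moduli are compared by a two-sided Wilcoxon test and Welch
t-test. The Wilcoxon default is the two-sample rank-sum form — the
comparison is between the two *distributions*' locations; since the samples
are site-paired, a paired (signed-rank) variant is available behind a flag.
Correlations are squared Pearson coefficients of a linear dependence.

## Monte Carlo sensitivity study

At fixed $\varphi = 0.34$, the mineral quota and fibril volume fraction are
drawn uniformly on [0.25, 0.75] and the fibril angle uniformly on
[0°, 90°]; infeasible phase partitions are rejected and redrawn (the
feasible region excludes slivers at two corners; rejections are counted).
Each of the 10,000 feasible draws is pushed through the full
homogenization + virtual indentation chain. Under these ranges the
predicted modulus spans roughly 11–30 GPa; extremes are stable to
±0.5 GPa across seeds, the minimum arising at large angles with a highly
porous foam ($q$ large, $f_{fib}$ small) and the maximum near the
dense-foam corner where the extra-fibrillar porosity approaches zero.
Reported extremes are rounded to integer GPa.

## Problem sizes and reproducibility

Cohort-scale checks run at the study size (883 retained sites of 957); the
sensitivity study at 10,000 draws; registration tests on 96×96-pixel
rasters; quadrature validation against 720-point references. Every
stochastic component is seeded through a single integer (cohort
configuration, sensitivity configuration, script `--seed`), and identical
configurations produce bit-identical rasters, tables and summaries.

## Known limitations

* The mean-field chain assumes aligned, dilute-interaction microstructure
  at every level; extreme partitions (fibrils that are almost pure mineral,
  foams near zero or full porosity) push Mori–Tanaka far outside its
  comfort zone, and predictions there should be read as model
  extrapolations.
* The closed-form Eshelby route requires an isotropic matrix; the
  isotropized-projection fallback is an approximation (validated against
  the numerical route, but still an approximation).
* Registration is rigid only; no deformable distortion between modalities
  is modeled, matching the acquisition geometry but not, e.g., section
  warping.
* Water is not a distinct phase; mineral crystals are isotropic; the
  indentation model is purely elastic (no hardness, creep or size effect).
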