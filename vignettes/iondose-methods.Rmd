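---
title: "iondose: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{iondose: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iondose)
```

`iondose` is a desk-scale condensed-history Monte Carlo engine for
therapeutic ion beams (protons, helium, carbon, oxygen) in voxelized
phantoms. This vignette is the package's own account of the physics it
implements, the surrogates it uses where full nuclear or multiple-
scattering theory is out of scope, the tunable parameters with their
defaults, and the limitations a user should keep in mind.

## Electronic stopping power

The core of the engine is the mean electronic energy loss of a heavy
charged particle, assembled in `electronic_stopping_power()` as

$$
-\frac{1}{\rho}\frac{dE}{dx} =
 \frac{2\pi n_e r_e^2 m_e c^2\, z_{\mathrm{eff}}^2}{\rho\,\beta^2}
 \left[\ln\frac{2 m_e c^2 \beta^2 T_{\max}}{I^2(1-\beta^2)}
 - 2\beta^2 + 2 z L_1 + 2 z^2 L_2 + K_M - 2\frac{C}{Z} - \delta\right]
$$

with $n_e$ the electron density, $I$ the mean excitation energy and
$T_{\max}$ the kinematic maximum energy transfer to a free electron,
computed with **all** mass-ratio terms kept (`tmax()`), not the common
heavy-projectile approximation. Each correction is individually
toggleable through `stopping_options()`:

* **Density effect** $\delta$ — Sternheimer parameterization. Water and
  air ship with their standard coefficient sets; any other material gets
  a generic parameterization derived at construction from $I$ and the
  plasma energy via the Sternheimer–Peierls selection rules.
* **Shell correction** $C/Z$ — the classic Barkas–Bichsel polynomial in
  $1/\eta^2$ ($\eta = \beta\gamma$) with $I^2$ and $I^3$ terms, a form
  originally fitted to proton stopping tables. Its fit domain ends at
  $\eta = 0.13$; below that the argument is clamped with a warning.
* **Effective charge** $z_{\mathrm{eff}}$ — bare charge for $z \le 2$ at
  all energies; for heavier ions the Barkas-type form
  $z\,(1 - e^{-k\beta z^{-2/3}})$ with $k = 125$ by default. $k$ is
  config-exposed because published re-fits of this constant differ.
* **Barkas ($z^3$) term** $L_1$ — an Ashley–Ritchie–Brandt-shaped
  surrogate $F_0 / (\sqrt{\bar Z}\,V^3)$ in the scaled velocity
  $V = \beta\gamma/(\alpha\sqrt{\bar Z})$ with $F_0 = 0.35$. The exact
  tabulated ARB function is not reproduced; the surrogate has the right
  sign (odd in $z$), magnitude and high-velocity decay.
* **Bloch ($z^4$) term** — the exact closed form
  $\psi(1)-\mathrm{Re}\,\psi(1+iy)$, $y = z_{\mathrm{eff}}\alpha/\beta$,
  evaluated as the convergent sum $-y^2\sum_n [n(n^2+y^2)]^{-1}$.
  Because it enters the bracket as $2z^2L_2$, `barkas_bloch_terms()`
  returns $L_2$ = (full correction)$/z_{\mathrm{eff}}^2$.
* **Mott correction** $K_M$ — higher-order electron-ion scattering
  beyond the first Born approximation, relevant once $z\alpha/\beta$ is
  not small. The published fit family is not openly available, so a
  documented surrogate $c_M\, y/(1+y)$ with $c_M = 0.6$ is used; it
  vanishes in the Born limit and grows with projectile charge. Default
  off for $z \le 2$, on for $z \ge 3$.

**Low-energy branch.** The Bethe bracket loses validity below roughly
0.5 MeV/u. Inside the operating domain (0.01–1000 MeV/u) but below that
switch, a Ziegler-style velocity-proportional branch
$S(E) = S(0.5)\sqrt{E/0.5}$ is substituted. This guarantees a strictly
positive stopping power with a single maximum (the Bragg-curve
precondition) and costs almost nothing in range terms: the residual
range below 0.5 MeV/u is micrometers of water. A non-positive bracket
above the switch raises an error rather than being clamped.

The unrestricted proton values in water agree with standard reference
tabulations at the 2% level over 1–250 MeV (a packaged eight-point grid
is asserted in the test suite as a regression guard; the comparison is
at the $I = 78$ eV equivalence level, which is also the package default
for water and user-overridable). CSDA ranges integrate $A\,dE/S$ by
adaptive quadrature at relative tolerance $10^{-6}$
(`csda_range()`); transport uses a 200-points-per-decade log-grid table
with linear log-log interpolation (`stopping_table()`).

## Condensed-history transport

`run_simulation()` drives an Rcpp kernel that steps each primary through
the voxel grid. The step length is the smaller of the remaining chord in
the voxel (half-open boxes, beam axis $+z$, positions in mm) and the
distance over which the expected fractional energy loss stays below
`max_fractional_energy_loss` (default 2%, hard-capped at 5%). A
mid-step re-evaluation of the stopping power removes most of the
first-order step-size bias.

* **Straggling.** The cumulant-based fluctuation algorithm used by
  full-scale codes is not reproducible from open sources; `iondose` uses
  a Gaussian surrogate with the Bohr variance
  $\sigma^2 = 0.1569\, z_{\mathrm{eff}}^2 (Z/A)\, \rho\,\Delta x\,
  (1-\beta^2/2)/(1-\beta^2)$ MeV², truncated to $[0, E]$. The model enum
  (`straggling_model`) reserves room for a future Vavilov option.
* **Multiple Coulomb scattering.** Highland's closed form
  $\theta_0 = (13.6\,\mathrm{MeV}/\beta c p)\, z \sqrt{t/X_0}
  (1 + 0.038 \ln t/X_0)$ replaces Molière theory; radiation lengths come
  from the standard per-element formula combined over the composition.
  Projected angles are sampled independently in two transverse planes.
* **Delta rays.** Explicit delta-ray transport is out of scope, so the
  kernel uses the *unrestricted* stopping power for the continuous loss:
  secondary-electron energy is deposited at the production point. The
  `delta_threshold` (>= 1 keV) governs `restricted_stopping_power()`,
  which is exported for users who need the restricted quantity itself.
* **Nuclear attenuation and the fragment tail.** Primaries are removed
  with probability $1-e^{-\Delta x/\lambda(E)}$,
  $\lambda = 1/\sum_i n_i \sigma_i(E)$, from packaged Bradt–Peters-style
  geometric cross sections with a threshold rise (user-replaceable;
  `default_inelastic_sigma()`). On removal the residual energy is split:
  a locally deposited fraction (default 0.6), a forward tail deposited
  exponentially downstream with decay length 2 cm (default fraction
  0.3), and an escaping remainder. These defaults reproduce the
  *qualitative* forward fragment build-up and dose beyond the Bragg peak
  only; they are in no way equivalent to an intranuclear-cascade event
  generator, and the run header says so on every run. Because the local
  fragment deposit scales with the residual primary energy, the
  simulated entrance plateau acquires a mild negative slope that a pure
  attenuation model does not have.
* **Bookkeeping.** Every MeV is accounted to exactly one of deposited /
  escaped geometry / nuclear escaped / tail escaped; the ledger closes to
  0.1% by construction and the test suite asserts it. The same seed,
  config and inputs give bit-identical grids (the kernel draws from R's
  RNG stream seeded by `rng_seed`). Batch statistics use 10 sequential
  batches by default.

Scoring: per-voxel dose (MeV/g per primary), per-depth-slice,
per-log-energy-bin fluence spectra (track length), primary crossings per
slice (for attenuation checks), and — when an LQ table is attached — the
per-voxel mixed-field sums described next.

## Mixed-field biological dose

For a mixed radiation field the per-voxel dose-weighted averages

$$
\bar\alpha_j = \frac{\sum_i \Delta d_{i,j}\,\alpha_{i,j}}
 {\sum_i \Delta d_{i,j}},\qquad
\bar\beta_j = \frac{\sum_i \Delta d_{i,j}\,\beta_{i,j}}
 {\sum_i \Delta d_{i,j}}
$$

are accumulated over all deposits (`accumulate()`, or inside the kernel
during transport). The coefficients $\alpha(E), \beta(E)$ per species
come from user-supplied CSV tables; interpolation is log-linear in
energy with edge clamping. The total deposited dose of the primary
species is used as the weight $\Delta d$; nuclear local/tail deposits
are assigned the coefficients at the primary's residual energy — a
pragmatic choice, since the surrogate tail has no fragment spectrum to
look up.

The RBE-weighted dose inverts the photon linear-quadratic curve at equal
effect $\epsilon = \bar\alpha D + \bar\beta D^2$:

$$
D_{\mathrm{RBE}} = \sqrt{\left(\frac{\alpha_{ph}}{2\beta_{ph}}\right)^2 +
 \frac{\epsilon}{\beta_{ph}}} - \frac{\alpha_{ph}}{2\beta_{ph}},
$$

the standard quadratic-root form (the inversion itself is a documented
package decision). The default photon reference is the representative
cell line with $\alpha/\beta = 2$ Gy ($\alpha_{ph} = 0.1$ Gy⁻¹,
$\beta_{ph} = 0.05$ Gy⁻²); at the reference coefficients
$D_{\mathrm{RBE}} = D$ identically. Proton plans typically use the
constant clinical factor instead: `proton_clinical_rbe()` multiplies
every voxel by exactly 1.1.

**SOBP optimization.** `optimize_sobp()` finds non-negative
per-component weights for a flat RBE-weighted plateau. It alternates
(1) converting the prescribed photon-equivalent effect into the physical
dose $D^*(z)$ that the *current* $\bar\alpha(z),\bar\beta(z)$ would
need, and (2) multiplicative image-space (ISRA-type) non-negative
least-squares updates of the weights toward $D^*$. Both steps are
deterministic; with energy-independent coefficients equal to the photon
reference the procedure reduces to plain non-negative least squares
(cross-checked against an independent NNLS solver in the tests). The
fixture tables (`lq_table_carbon_like()`) have $\alpha$ rising from 0.1
to 1.0 Gy⁻¹ as the energy falls below ~20 MeV/u and $\beta$ fixed at
0.05 Gy⁻², which makes $\bar\alpha$ rise toward the distal edge and
keeps $D_{\mathrm{RBE}} \ge D$ everywhere — the qualitative behavior of
LEM-derived carbon tables, without claiming their values. Real tables
are user-supplied CSVs.

## Hounsfield-unit calibration

`hounsfield_from_mu()` implements the CT number definition
$HU = 1000(\mu_x-\mu_{H_2O})/(\mu_{H_2O}-\mu_{air})$ (air $-1000$,
water 0). `build_default_calibration()` loads the packaged
stoichiometric segmentation: 24 materials over 41 half-open HU intervals
tiling $[-1000, 3500]$, each interval with a nominal density at its
center and a linear continuous density scaling in HU. The same
per-voxel density scale multiplies electronic and nuclear interaction
densities during transport (separate multipliers would be a one-line
extension).

The packaged table is a *synthetic reconstruction* in the Schneider
stoichiometric style — tissue compositions from standard reference
tables, the skeletal series as marrow-to-cortical blends, densities from
a continuous piecewise-linear $\rho(HU)$ anchored at air and water —
because the original 24 compositions and 41 interval edges are not
printed in open sources available here. Facility-specific calibrations
load from two CSVs (`read_hu_calibration()`). HU outside the calibrated
range clamp to the nearest bound with a warning; interval membership is
half-open with the last interval closed, so every HU maps to exactly one
segment. Phantoms can also be read/written as raw little-endian arrays
with a JSON sidecar; DICOM import is not included because no DICOM
reader is available to the package's dependency set.

## In-vivo monitoring surrogates

The PET chain folds the scored fluence spectra with reaction cross
sections: production per depth bin is
$\sum_E \Phi(E)\,\sigma(E)\,n_{\mathrm{target}}$, linear in each factor
(`emitter_production()`). The per-depth production is spread across the
voxels of its slice proportionally to deposited dose — an approximation
consistent with the pencil-beam geometries the engine targets. Decay
counting in an acquisition window is the exact double exponential with
an optional uniform washout rate added to $\lambda$
(`activity_in_window()`). Fixture cross sections are analytic
threshold-plateau shapes for the two dominant proton channels on tissue
(¹⁵O and ¹¹C production); evaluated nuclear data are user-supplied CSVs.

`detect_coincidences()` emits two back-to-back 511 keV photons per decay
(optional Gaussian acollinearity jitter; positron range off by default,
optionally a Gaussian blur), intersects them with a geometric cylinder
of perfect-absorber crystals, and applies the scoring options: energy
window on Gaussian-smeared energies (fractional FWHM at a reference
energy, $\sqrt{E}$ scaling by convention, switchable to
energy-independent), coincidence timing from path-length difference plus
detector jitter, minimum scoring time, and per-module dead time. A
partial ring of opening angle $\theta \in [0^\circ, 180^\circ]$ is
modeled as two opposing arcs (dual heads); $180^\circ$ is the complete
ring. Crystal block sub-structure collapses to azimuthal module
segmentation. `bin_sinogram()` maps each line of response to its
(signed radial offset, azimuth) pair with count conservation and an
overflow tally.

## Comparison metrics

`bragg_peak_position()` uses parabolic interpolation through the maximum
bin (ties break toward shallower depth; monotone curves are an error).
The dose-difference and chi-square estimators are named but not defined
in the sources this package follows, so the definitions are fixed here
and isolated in one function each so alternates can be swapped:

* `dose_weighted_dose_difference()`:
  $\sum w_i |D_{sim}-D_{ref}| / \sum w_i D_{ref}$ with $w = D_{ref}$,
  i.e. 0.02 for a uniform +2% offset.
* `weighted_chisq()`: curves are first normalized to unit integral over
  the dimensionless depth coordinate $u = (z-z_{\min})/(z_{\max}-z_{\min})$
  (making the statistic independent of dose and length units), then
  $\sum D_{ref}(D_{sim}-D_{ref})^2 / \sum D_{ref}$. Near-identical
  curves land at the 1e-5–1e-4 scale. Whether the original estimator
  uses statistical or dose weights is not recoverable; dose weights are
  used and noted here.

Curves are resampled to the finer of the two grids with monotone
interpolation before comparison. `dvh()` provides the cumulative
dose-volume histogram with `d_at_volume()` (D50) and `v_at_dose()` (V10)
accessors.

## Problem sizes and study conditions

The packaged study conditions are those the engine is tested under:
mono-energetic pencil beams of $10^4$ primaries in 1 mm water slabs for
single-curve work, and the SOBP benchmark with 12 carbon-like components
(163–246 MeV/u, 0.4% energy spread, $10^4$ primaries each) optimized to
3 Gy (RBE) over the 6-cm target centered at 9 cm depth in water. The
energy ladder was chosen so the component peaks span the target; 0.4%
energy spread is a realistic synchrotron momentum spread and softens the
ripple between the ~5 mm-spaced carbon peaks. With those settings the
optimizer lands within 1% of the prescription in the target mean; the
residual ripple at the plateau edges (~15% point-wise) is the expected
consequence of superposing sharp carbon peaks without a ripple filter.

## What the tests do and do not show

The synthetic generators emulate: Bragg-curve shapes with range
straggling and lateral spread, exponential primary attenuation with a
forward tail, carbon-like LQ depth dependence, threshold-shaped
excitation functions, and ring-detector coincidence geometry. They do
not emulate: real fragment spectra and their angular distributions,
prompt-gamma line structure, detector scatter and randoms, patient
anatomy, or LEM-derived radiobiology. A passing suite therefore
demonstrates internal consistency with the stated models and agreement
with closed-form oracles — not clinical accuracy against measured beam
data, which requires facility-specific calibration of $I$, the
cross-section tables and the biological database.

## Known limitations

* The fragment-tail surrogate has no spectral or angular content; its
  three parameters are placeholders until user cross sections are
  supplied, and dose beyond the peak is only qualitatively right.
* Shell, Barkas and Mott corrections are surrogate parameterizations;
  output metadata (the run header) flags them on every run.
* Energy straggling is Gaussian: the Landau tail of thin absorbers is
  not reproduced, so very thin-slab energy spectra are too symmetric.
* Secondary charged particles, neutrons and prompt gammas are not
  transported; monitoring observables are production-level surrogates.
* The PET detector is a perfect absorber: no crystal efficiency,
  scatter, randoms, or reconstruction.
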