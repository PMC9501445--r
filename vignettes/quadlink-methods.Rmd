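---
title: "Linked-equilibrium analysis of quadruplex folding and ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked-equilibrium analysis of quadruplex folding and ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadlink)
```

## The model

The human telomeric fragment 22GT (5'-GGGTTAGGGTTAGGGTTAGGGT-3') folds
through a populated intermediate: the unfolded strand U binds one K⁺ to
form the two-quartet antiparallel intermediate I, which binds a second K⁺
to form the folded hybrid-3 quadruplex Q.  A bisquinolinium end-stacking
ligand L (360A) binds at two ends: site 1, the "upper" end that is
exposed only on the intermediate (after the second specific K⁺ has been
lost), giving the LI complex; and site 2, the "bottom" end shared by Q
and I, giving QL and IL, and LIL when both ends of I are occupied.  The
three site-2 events (Q + L → QL, I + L → IL, LI + L → LIL) share one
parameter set because the bottom ends of Q and I are structurally
equivalent; no LQ complex exists because site 1 requires the loss of a
specifically bound K⁺ that Q retains.  All species are treated as being
at equilibrium — folding is modelled as fully reversible, with no
kinetics.

Each folding step carries five numbers at the reference state (25 °C,
100 mM K⁺): ΔG°, ΔH°, ΔCp, and the signed count *n* of K⁺ ions exchanged;
the entropic part is always derived as TΔS = ΔH − ΔG and never stored,
which removes an exact collinearity from every fit.  Parameters
propagate to other conditions by Gibbs–Helmholtz with constant ΔCp,

$$\Delta G(T) = \Delta H_0 - T\,\frac{\Delta H_0 - \Delta G_0}{T_0}
  + \Delta C_p\left[(T - T_0) - T\ln\frac{T}{T_0}\right],$$

plus, for folding steps only, the ion-linkage term
$n R T \ln(c_{K^+}/c_{\mathrm{ref}})$.  Binding sites exchange no ions
and carry no salt term.  Activities are identified with molar
concentrations throughout; the analysis the model supports makes the
same implicit assumption.  The sign convention for *n* (used as printed
for the folding direction, linkage added as above) is validated by a
downstream consistency check: it reproduces the 60 %/40 % Q/I split at
20 °C and 1 mM K⁺ that the ligand-free CD spectra imply.

Internal units are K, mol/L and kcal; files and figure axes use °C, mM
and µM, converted at the boundary.

## Speciation

Given free-ligand concentration *L*, the seven species concentrations
follow from mass action (I = K_UI·U, Q = K_IQ·I, QL = K₂·Q·L,
IL = K₂·I·L, LI = K₁·I·L, LIL = K₁K₂·I·L²).  Species weights are
evaluated in log space with max-subtraction, so strongly folded or
strongly bound conditions cannot overflow.  The ligand conservation
function g(L) = L + bound(L) − c_L is strictly increasing, so the free
ligand is the unique root on [0, c_L]; it is bracketed by bisection and
polished with Newton steps to a relative tolerance of 10⁻¹⁰.  The grid
variant used by phase diagrams and the ITC forward model runs the same
bisection in lock-step over all conditions at once.  The test suite
checks the solver against an independent oracle that minimizes the total
mixture Gibbs energy (ideal-dilute chemical potentials, including the
mixing entropy) along the feasible composition curve by dense grid
search plus golden-section refinement; agreement is required to 10⁻⁶ in
every fraction.

## Forward models

**CD melting.**  The normalized signal is f = α_I·f_I + α_U with f_I a
single temperature-independent normalization coefficient per curve, and
the raw ellipticity is recovered through linear pre- (folded) and
post-transitional (unfolded) baselines, θ = θ_Q(T) + f·(θ_U(T) − θ_Q(T)).
Normalization and denormalization are exact inverses; equal baselines on
any grid point are rejected as degenerate.

**DSC.**  The mean excess enthalpy ⟨ΔH⟩(T) = Σ_s α_s(T)·H_s(T) uses
species enthalpies relative to the unfolded strand (the baseline
convention of the DSC analysis), propagated by Kirchhoff's relation.
The model excess heat capacity is the centred-difference derivative of
⟨ΔH⟩ on an internal 0.1 K grid, interpolated to the data grid — this
avoids a lengthy analytic derivative while conserving the transition
area: the integral of the curve over the scan equals
⟨ΔH⟩(T_high) − ⟨ΔH⟩(T_low) to better than 1 %.  In the two-state limit
(intermediate suppressed) the peak height matches the analytic van't
Hoff result ΔH²/(4RT_m²) to 0.5 %.  For measured thermograms the
intrinsic heat capacity is a quadratic fitted to user-configurable
folded and unfolded windows (defaults 0.5–15 °C and 85–95 °C).

**ITC.**  Titrations run in reverse — DNA into ligand — so heats are
normalized per mole of DNA injected, and the dilution heat is one fitted
constant per isotherm.  Injection bookkeeping uses the
instantaneous-displacement convention standard for perfusion cells (the
injected volume displaces an equal volume of pre-injection
composition); the analysis does not depend on an alternative convention
being distinguishable at these injection volumes.  The heat of
injection k is the enthalpy inventory change of the cell corrected for
displaced and injected material; the syringe content is taken as
pre-equilibrated ligand-free DNA at the cell temperature, so its folding
state (mostly Q at 25 °C) contributes to the measured heat exactly as a
conformational-conversion term.  The default protocol — 25 × 10 µL into
a 1.4 mL cell, 70 µM syringe DNA, 10 µM cell ligand — is a plausible
instrument protocol; injection counts and volumes are configurable
because the underlying experiments do not pin them.

## SVD rank analysis

The spectra matrix is decomposed raw (no mean-centering; a flag is
provided).  Because "dominant" is a visual judgement in the source
analyses, two explicit criteria are reported: singular values above a
fraction f = 0.05 of the largest (the headline criterion), and
components whose temperature-amplitude vectors have lag-1
autocorrelation above 0.8 — a smoothness criterion that scores pure
noise as rank 0.  Both return 3 on the default synthetic series.

## Global fitting

The objective is a weighted sum of squares over datasets,
SSR = Σ_d w_d Σ_i (y_di − ŷ_di)²; the default weight
w_d = 1/(n_d·σ̂_d²), with σ̂_d² estimated from first differences of the
data (var(diff(y))/2), makes heat capacities, raw ellipticities and
injection heats — which differ by orders of magnitude in raw units —
contribute comparably.  Optimization is bounded Levenberg–Marquardt
least squares (trust-region, minpack.lm) from the nominal start
(data-driven nuisance values: end-window baseline fits, tail-median
dilution offsets) plus Latin-hypercube draws of the free shared
parameters over their physical bounds (default 20 starts, mandatory
seed).  The site heat-capacity changes are bounded above by zero:
end-stacking ligand binding buries surface and sheds water, so a
positive binding ΔCp is excluded a priori.  This constraint also matters
numerically — without it, three-temperature isotherm sets admit a
near-degenerate solution that repartitions the two sites' enthalpies
with a compensating positive ΔCp, a ridge the physical bound removes.
The ion count *n* is treated as a continuous bounded parameter;
nothing in the model requires integrality, and the fit's job is to
recover it.  By default folding parameters are fixed during binding
(ITC) fits and estimated from DSC+CD; a joint mode is available by
freeing both blocks, but the staged default mirrors how the experiments
constrain the parameters (melting data carry almost no binding
information at r = 0, and isotherm information on folding is indirect).
Uncertainties come from a residual bootstrap (resample fitted residuals
per dataset, refit from the solution); bootstrap spread is reported as
the standard error, with a warning if fewer than half the replicates
converge.

Mechanism comparison refits the same isotherms under the full linked
mechanism, a two-non-equivalent-independent-site model on the folded
form, and a sequential two-ligand model, ranking by small-sample
corrected AIC — the qualitative statement that simpler mechanisms fail
is made quantitative this way.  The site-2 equivalence constraint is
hard-wired in the full mechanism; the alternatives serve as the relaxed
comparators.

## Energy decomposition and phase diagrams

The binding free energy at 25 °C is split as ΔG = ΔG_hyd + ΔG_int +
ΔG_other with ΔG_hyd = 80 K × ΔCp (the 80 (±10) K dehydration factor is
fixed at 80 for point estimates; its ±10 K spread belongs to the
uncertainty, not the point value), ΔG_int ≈ ΔH, and ΔG_other the exact
remainder.

Pseudophase diagrams label each cell of a temperature × log₁₀[K⁺] or
temperature × r grid (defaults 200 × 200, T ∈ [0, 95] °C,
log₁₀[K⁺] ∈ [−4, −1], r ∈ [0, 3], 10 µM DNA) with the most populated
species; ties within 10⁻¹² resolve by species-list order for
deterministic output.  Boundaries are refined by bisection between
adjacent cells of different label until the two fractions agree within
10⁻⁶; triple points are located from 2 × 2 blocks carrying three labels
and refined by two-dimensional minimization of the pairwise tie
residuals, keeping only junctions that stay inside the window.  In the
ligand-free diagram the three phase bands run Q → I → U with rising
temperature at every salt level and never meet inside the window, so the
junctions live on the ligand-loading diagram (e.g. the LI/LIL/QL tie
near r ≈ 1 at low temperature).

## Synthetic data

The generator's defaults are the study conditions: the published
parameter set as truth; DSC scans 0.5–95 °C at 100 µM DNA and 1, 10,
100 mM K⁺; CD melting at 290 nm, 5–95 °C, 10 µM DNA at the same salt
levels; a 210–330 nm spectra series at 10 mM K⁺; reverse ITC at 15, 25
and 40 °C, 100 mM K⁺.  Noise is white Gaussian at plausible instrument
magnitudes — 0.05 kcal mol⁻¹ K⁻¹ (DSC), 2 % of the signal range (CD and
spectra), 0.2 kcal per mol injectant (ITC) — chosen once since the
source reports none.  Basis spectra are synthetic band shapes
qualitatively emulating the hybrid-3 form (maxima at 290/245 nm, 270 nm
shoulder, minima at 265/235 nm), the two-quartet antiparallel
intermediate (minimum shifted to ~262 nm, no shoulder) and a weak
unfolded-strand spectrum; they are labelled synthetic throughout and
carry no claim to quantitative band positions.  Every dataset stores its
truth (parameters and noiseless curve), and identical seeds reproduce
bit-identical data without perturbing the caller's RNG stream.

What passing recovery tests shows — and what it does not: white noise
plus smooth baselines is the statistical structure the fitting assumes,
so recovery within the stated envelopes demonstrates identifiability and
correctness of the estimation machinery under that structure.  Real
thermograms and isotherms carry correlated baseline drift, scan-rate
effects and subtraction artifacts that are not modelled, so the
envelopes should be read as best-case precision, not instrument-grade
error bars.  Raw measurement data are not redistributable with this
package, which is why parameter recovery on synthetic data is the
package's acceptance surface.

## Problem sizes and numerical choices

The shipped analysis uses DSC curves at 0.5 °C spacing (190 points), CD
curves at 1 °C (91 points), 37-temperature spectra, 25-injection
isotherms, 20 fit starts, 20 bootstrap replicates, and 120 × 120 phase
grids with 50 × 50 grids in the fast consistency checks — sizes chosen
so the full workflow runs on a laptop in minutes while leaving the
recovery envelopes comfortably met.  Degenerate inputs fail loudly:
non-bracketable ligand balances, empty baseline windows, all-zero
spectra matrices, a never-populated intermediate (whose spectrum is then
unidentifiable) and non-monotone temperature grids all raise errors
naming the offending quantity.

## Known limitations

One intermediate only; no Na⁺ or TMAA solution models; no activity
corrections; no kinetics or hysteresis; no UV-absorbance melting model;
no multi-wavelength global CD fitting (the spectra matrix is used for
rank analysis and intermediate-spectrum estimation, not fitted
directly); possible DMSO perturbation of folding parameters in titration
buffers is not modelled — folding values are applied unchanged, matching
the staged fitting convention.
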