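---
title: "Models and methods behind crocinrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crocinrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocinrad)
```

crocinrad analyses the oxidation of crocin — the carotenoid diester that
colours saffron — by hydroxyl radicals generated radiolytically in water.
This vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## Radiolytic yields and dosimetry

Water radiolysis delivers a fixed cocktail of primary species whose yields
(G values, mol of species per J of absorbed dose) are well established for
dilute solutions at ~100 ns scavenging times: G(e⁻_aq) = G(H⁺) = G(OH•) =
2.8, G(H•) = 0.62, G(H₂) = 0.47, G(H₂O₂) = 0.73, all ×10⁻⁷ mol/J. These are
the defaults of `primary_yields()`; values are stored in SI mol/J and only
printed in the conventional 10⁻⁷ units, which avoids silent ×10⁷ unit bugs.

In N₂O-saturated solution the hydrated electrons are converted to OH•, so
the operative oxidant yield is `oh_yield()` = G(e⁻_aq) + G(OH•) =
5.6×10⁻⁷ mol/J; the slow H• conversion is excluded from this sum.
Throughout, the dilute-water convention 1 Gy ≙ 1 J/L (density 1 kg/L) turns
dose × yield directly into a concentration, e.g. a 97 Gy pulse delivers
~5.4×10⁻⁵ M of OH•. Pulse dosimetry inverts Beer–Lambert on the hydrated
electron band (ε₆₆₀ = 18,000 M⁻¹cm⁻¹, G = 3.3×10⁻⁷ mol/J at 5 ns).

`scheme_yield()` encodes the bookkeeping of the three oxidation regimes:

* pulse, N₂O: every OH• (plus the H• channel) abstracts one H atom from one
  crocin, G(−croc) = G(e⁻_aq) + G(OH•) + G(H•) = 6.2×10⁻⁷ mol/J; the
  radicals then dimerize, so the dimer yield is half of that.
* gamma, N₂O: at low dose rate the radical is complexed by excess crocin and
  disproportionates (two radicals → one twice-oxidized molecule + one
  regenerated crocin), and H₂O₂ also oxidizes crocin:
  G = ½(G(e⁻_aq) + G(OH•) + G(H•) + 2G(H₂O₂)) = 3.84×10⁻⁷ mol/J.
* gamma with Ag⁺: silver ions scavenge H•, and the resulting silver atoms
  regenerate crocin from its oxidized radical:
  G = ½(G(e⁻_aq) + G(OH•) − G(H•)) ≈ 2.5×10⁻⁷ mol/J. The ½ prefactor (the
  disproportionation stoichiometry) is required for the printed primary
  yields to reproduce the accepted 2.5×10⁻⁷ value, and is therefore part of
  the implemented formula.

## Transient kinetics

Radical formation at 678 nm follows pseudo-first-order kinetics when crocin
is in excess: A(t) approaches a plateau as 1 − exp(−k_obs t) with
k_obs = k₂[croc]. `fit_pseudo_first_order()` implements the classical
linearization, a regression of log(A_∞ − A) on t. Numerical choices:

* the fit window starts at 50 ns by default, excluding the instrument
  "bump" caused by hydrated electrons formed within the pulse;
* the plateau A_∞ is the mean of the final 5% of samples unless supplied;
* the regression stops where the *smoothed* plateau distance falls below a
  fraction (default 0.2) of its value at the window start. Ending on a
  pointwise rule instead would retain only positive noise excursions deep in
  the plateau and bias the slope severely; ending too early leaves the fit
  dominated by residual bump contamination. The 0.2 default balances the
  two and leaves exact exponentials untouched. With the instrumental ±5%
  multiplicative noise the recovered k₂ has ≲0.5% bias and ~5% spread
  across seeds.

Radical decay at 678 nm is a self-reaction (dimerization): 1/A(t) is a
straight line whose slope k_obs converts to the bimolecular constant as
2k = k_obs · ε₆₇₈ · l. The conversion path defaults to 1 cm because the
published rate (3.7×10⁹ M⁻¹s⁻¹) follows from 0.6×10⁶ × 6.23×10³ only under
that convention, although the pulse cell itself was 0.5 cm; the path is an
explicit argument so either convention can be used. `order_discrimination()`
fits both linearizations and reports the more linear one, supporting the
assignment of the decay to a second-order recombination.

Both fits use ordinary unweighted least squares on the linearized forms —
the classical "tests" — with a nonlinear least-squares refinement available
(`nonlinear = TRUE`) but never used for headline numbers.

## Calibration algebra

The isosbestic points at 375 and 510 nm establish a 1:1 crocin → radical
stoichiometry, which anchors all molar absorptivities:

* `calibrate_by_ratio()`: with equal optical paths, ε of the radical at
  678 nm follows from ε₄₄₁(croc)·A₆₇₈/A₄₄₁ = 6230 M⁻¹cm⁻¹.
* `differential_to_absolute()`: the absolute radical spectrum is the
  algebraic sum of the crocin spectrum and the differential spectrum
  (negative results are clipped to zero with a warning, since noise can push
  small absorptivities negative).
* `dimer_epsilon()`: two radicals give one dimer, so the dimer concentration
  is half the radical's; the late/early bleaching ratio then gives
  ε_d = 2[ε_c − ratio·(ε_c − ε_r)]. The worked case (ratio ≈ 2.39) yields
  ~1.84×10⁵ M⁻¹cm⁻¹ at 441 nm.

Optical paths differ between experiments (0.5 cm pulse cell, 1–2 mm
steady-state cells) and are always explicit arguments, never globals.

## Dose-series deconvolution

Gamma irradiation converts crocin into one product molecule per consumed
parent (mass balance c_croc + c_product = c₀), so each spectrum is a
two-component Beer–Lambert mixture. Subtracting the zero-dose spectrum
leaves a rank-1 bilinear term, which identifies the product spectrum and the
consumed concentrations only up to one shared scale — the classical
rotational ambiguity of curve resolution. `deconvolve_dose_series()` fixes
the scale physically: the product is transparent in the far red
(≥ 580 nm by default) where crocin still absorbs, so in that window each
spectrum reads the parent concentration directly by regression on the
parent absorptivity. Those concentrations seed the product spectrum, and
both factors are refined by alternating least squares with concentrations
clamped to [0, c₀].

Two numerical points deserve note. First, the ±5% uncertainty of the
measured absorbances is multiplicative, so both refinement steps are
weighted by 1/A² — with A the *model-predicted* absorbance, because
weighting by the noisy observations correlates the weights with the errors
and biases the scale. Second, nonnegativity of the product spectrum is
imposed only on the reported result, not inside the iteration: clipping
during the iteration rectifies tail noise and again biases the scale. With
these choices the noiseless round trip recovers concentrations to ~10⁻⁷
relative and the consumption yield G_exp to <0.1%; at ±5% noise the
per-seed worst-case concentration error averages ~2% (the smallest dose,
with only ~10% of the crocin consumed, is the hardest and can reach ~5% in
unfavourable seeds), and G_exp stays within ~2%.

The yield G_exp is the slope, through the origin, of consumed concentration
against dose, restricted to doses ≤ 97 Gy — the range over which the
isosbestic point, and hence the two-component description, holds. A
rank-deficiency diagnostic flags series whose dose-differential spectra are
(anti)parallel to the parent spectrum, where no product component is
separable.

## Spectrum synthesis from transition line lists

Electronic-structure calculations deliver lists of excitation lines
(energy, oscillator strength, spin expectation ⟨S²⟩) on configurations
sampled along a trajectory. `convolve_lines()` turns them into spectra by
summing Gaussians in the *energy* domain — widths are quoted in eV — with
area (not height) proportional to the oscillator strength, since f is an
integrated intensity; the profile is then evaluated on a wavelength grid
with no Jacobian reweighting beyond the variable change. Per-configuration
sums are averaged over configurations (equivalent to pooling when all
configurations carry equally many lines — an assumption we document rather
than resolve). Three conventional widths are registered: 0.70 eV for
optimized-structure lines, 0.50 eV for intense and weak high-energy bands,
0.20 eV for weak low-energy bands.

Spin contamination of open-shell TDDFT states is screened by discarding
lines whose ⟨S²⟩ exceeds the ground-state value by more than the screening
parameter. The default reads the conventional "20%" as a *relative* excess
(cutoff 0.90 for a doublet); an absolute mode is provided as well.
Screening is idempotent and monotone in the parameter.

Species spectra are combined with `mix_spectra()` and probability
arithmetic: random pairing maps monomer probabilities (p_a, p_b) to dimer
weights (p_a², 2p_a p_b, p_b²); the *sugar-driven* site model assigns the
OH• radical to the chain with probability f (split evenly between the two
methyl sites) and to a sugar otherwise, whence it migrates to the
neighbouring site a — giving p_a = (1 − f) + f/2. A chain-encounter
fraction of ⅓ yields the (⅚, ⅙) weights; f = 1 recovers the
no-sugar-influence (½, ½) limit.

## Monte Carlo conformer sampling

`run_mc()` is a Metropolis sampler with the move mixture used for polyene
conformer searches: collective Gaussian "multi-stretch" displacements of
all sites (probability 0.8) and torsional moves about a uniformly chosen
rotatable bond (probability 0.2), the latter proposing with equal chance a
uniform angle perturbation or a cis↔trans flip. Proposals are accepted with
min(1, exp(−ΔE/k_BT)). The default temperature is 295 K; conformer searches
use 1000 K. Burn-in, stride (every 100th step by default, mirroring the
subsampling used for line lists), and all amplitudes are settings. The
proposal amplitudes are artifact choices — the underlying publications do
not specify them — with the stretch amplitude defaulted to give on the
order of 50% acceptance on the surrogate surface.

The quantum energy at each step is out of scope by design; for testing, the
surrogate `make_torsion_energy()` combines per-torsion two-state wells
(cis offset by a configurable gap) with harmonic stretch terms, giving an
analytic stationary distribution for Boltzmann-recovery tests
(a 0.05 eV gap at 1000 K is verified to 3σ with 40,000 recorded steps).
One master seed drives a single R random stream, so trajectories are
bit-reproducible; freezing no torsions reproduces the unconstrained
trajectory exactly, and `constrain_conformer()` freezes all torsions to
sample vibrations of a fixed conformer. `enumerate_single_cis()` generates
the all-trans plus single-cis conformer sets (8 states for the
di-methyl-ester model's 7 isomerizable double bonds; 14 for the
H-abstracted radical, whose delocalized unpaired electron makes all 13
chain bonds isomerizable).

## Thermochemistry

`wertz_correct()` applies the empirical entropy correction for
solution-phase association free energies,
G_corr = G_pcm − ½(G_gp − H_gp) + k_BT, with the +k_BT term cancelling the
PV contribution to the gas-phase enthalpy. The per-particle k_BT (CODATA
k_B = 8.617×10⁻⁵ eV/K) is numerically identical to the molar RT in these
units; the default temperature is the experimental 295 K.
`redox_potential()` uses the one-equivalent convention E = E_ref + Δ_rG
(eV numerically equal to V): the ≈ −2 eV H-abstraction free energy of the
crocin model against the 2.0 V_NHE OH•/H₂O couple places the oxidized
radical couple at ≈ 0 V_NHE, the basis of crocin's indirect antioxidant
(repair) capability. The computed reaction free energies of the oxidation
network — H-abstraction, dimerizations, disproportionation channels,
complexations — ship as a machine-readable table
(`reaction_free_energies()`).

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the analysis relies
on: the exponential approach to a plateau with an additive 50 ns electron
bump; exact second-order decay; ±5% multiplicative noise (the instrumental
uncertainty is relative, hence multiplicative rather than additive); a
crocin-like absorptivity spectrum (441 nm main band at 1.35×10⁵ M⁻¹cm⁻¹,
460 nm shoulder, weak 333/250 nm bands, negligible absorption beyond
550 nm); a product-like spectrum anchored at ε₃₃₀ = 0.25×10⁵,
ε₄₄₁ = 0.11×10⁵ and crossing the parent exactly at 375 nm; dose series with
exact mass balance; and line lists with a controlled fraction of
spin-contaminated lines.

They do *not* emulate: the mechanistic chemistry of the electron bump (it
is a phenomenological exponential, adequate because the fitters only
exclude it); instrument response functions beyond the bump; the secondary
oxidation regime above ~100 Gy (where the first product is itself attacked
and the isosbestic point is lost — detection and exclusion, not modelling,
is the package's job); baseline drifts or wavelength-correlated noise; and
any real conformational energetics (the MC surrogate is a toy surface).
Passing round-trip tests therefore demonstrates the correctness and
calibration of the estimators under the stated noise model, not their
robustness to instrumental artefacts absent from that model.

## Problem sizes and tolerances used in the tests

Kinetic traces use 601 points; noisy-recovery statistics use 100 seeds.
Dose series use 7 doses (0–97 Gy) on a 1 nm grid from 230 to 700 nm.
The Boltzmann-recovery run records 40,000 steps; move-frequency checks use
10⁵ steps. The alternating deconvolution refinement stops at a 10⁻⁸
relative change or 100 iterations. Published values rounded to two
significant figures are compared at that precision; recovery tests use the
tolerances stated alongside each property (10⁻³ relative for noiseless
fits, a few percent under noise).
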