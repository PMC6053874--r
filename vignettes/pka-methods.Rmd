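---
title: "Spectrophotometric and thermodynamic-cycle pKa determination for catechols"
author: "dhbpka"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrophotometric and thermodynamic-cycle pKa determination for catechols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhbpka)
```

## Why per-site pKa values for catechols

1,2-dihydroxybenzenes (DHBs) — catechol, catecholamines such as dopamine
and epinephrine, and phenolic acids such as caffeic acid — chelate metals,
scavenge or generate radicals, and participate in Fenton-type oxidation
chemistry. All of that is governed by which hydroxyl is deprotonated at a
given pH, so the quantity of interest is not just "the" pKa but the
dissociation constant of each site: the hydroxyl *meta* to the
4-substituent (`OH_m`), the one *para* to it (`OH_p`), and, for compounds
with carboxylic or ammonium side chains, the substituent proton (`RH`).
Literature values disagree by up to a pH unit, which motivates a workflow
that pairs systematic spectrophotometric measurement with a calibrated
quantum-chemical calculation. This package implements the data-analysis
side of that workflow: everything downstream of the spectrometer and of
the electronic-structure code.

## Speciation model

For an n-protic acid the package uses the stepwise Henderson–Hasselbalch
relation. The mole fraction of the species that has lost $j$ protons is

$$ f_j(\mathrm{pH}) \propto 10^{\,j\,\mathrm{pH} - \sum_{i \le j} \mathrm{p}K_{a,i}} , $$

normalised so the fractions sum to one. The implementation subtracts the
largest base-10 exponent before exponentiating, so a pKa of 2 evaluated at
pH 14 (a 10^12 dynamic range) stays exact to machine precision. Up to four
dissociations are supported (Dopa needs four: two side-chain protons plus
both hydroxyls). Activity corrections and buffer equilibria are out of
scope: pH is taken as given, as when each titration point is a separately
adjusted Britton–Robinson buffer.

## What the synthetic generator emulates — and what it does not

The raw titration spectra behind the packaged reference tables were never
deposited, so the package ships a generator that reproduces the
*statistical structure* the estimators rely on:

* species spectra as sums of Gaussian bands in wavelength — broad UV
  bands that red-shift and gain intensity on deprotonation, the typical
  catecholate pattern;
* Beer–Lambert mixing: at each pH the spectrum is the speciation-weighted
  sum of the pure species spectra (exactly convex, residual < 1e-12 in the
  noiseless case);
* additive i.i.d. Gaussian noise per (wavelength, pH) cell, default
  0.002 AU — typical diode-array photometric noise; no noise
  characterisation was reported for the original instrument, so this is a
  package choice;
* default grids: pH 2.0–14.0 in steps of 0.25 (the span used for the
  reference titrations; the published work does not state the pH step, so
  the step is a package choice), wavelengths 190–500 nm at 1 nm (covering
  the 194–450 nm analysis wavelengths of the reference study).

It deliberately does **not** model vibronic band asymmetry, baseline
drift, pH-measurement error, ionic-strength effects, or compound
decomposition at extreme pH. Passing the recovery tests therefore shows
the estimators are correct *given* two-state Beer–Lambert transitions and
white noise; it does not certify them against instrument systematics.

Reproducibility: `simulate_titration()` seeds R's RNG locally (restoring
the caller's RNG state), so a fixed seed gives bit-identical matrices.

## The five estimators and the cascade

`pka_fit()` reproduces the practitioner's decision sequence: an isosbestic
point in the raw spectra is used when one exists; failing that, in the
first- or second-derivative spectra; failing that, the zero-crossing
method; then the baseline-to-peak fit; and last the three-point Seok
closed form. The fitted object records the winning method per dissociation
and the reason each earlier method was skipped, because the method label is
part of how such results are reported.

**Transition windows.** Multi-step titrations are analysed window by
window. The aggregate spectral change between adjacent pH columns (summed
|ΔA| per pH unit) peaks at each pKa; the `n` strongest peaks at least one
pH unit apart become the transition centres and windows split midway
between centres. The reference work selected windows by eye; the
`min_separation` default of 1 pH unit is the package's own choice.

**Isosbestic detection.** At an isosbestic wavelength the across-pH
standard deviation of absorbance drops to the noise floor. Candidates are
local minima of that spread below max(5 x estimated noise, 2% of the
maximum spread); the noise is estimated from the long-wavelength tail
(median absolute first difference along pH), since catechol chromophores
no longer absorb there. Two refinements matter in practice: (i) a crossing
that falls between grid points leaves a dip whose minimum sits above the
cut, so a sign change of the base-minus-acid difference spectrum in the
immediate neighbourhood also qualifies; (ii) the dip must be flanked
within 20 nm by wavelengths carrying at least 20% of the maximum spread,
which excludes flat baseline regions where the spread is trivially small.
A series whose maximum spread is itself below the noise threshold is
degenerate (single species) and reported as such.

**Wavelength-pair choice and the crossing correction.** The two monitoring
wavelengths are chosen on opposite sides of the isosbestic point among
those with at least half the side's maximum pH response, subject to the
crossing condition (one wavelength reads higher in acid and lower in base
than the other), minimising the mismatch of their acid+base absorbance
sums — the algebraic condition for the traces to cross exactly at the pKa.
Because the pH grid ends at 14, a high transition (catechol's second pKa,
13.07) is truncated: the "base limit" column is only ~90% converted and
the naive crossing is biased by ~0.1. The package therefore refines the
estimate by a short fixed-point iteration: unmix the pure species spectra
from the window-edge columns using the provisional pKa, re-choose the
pair on the pure spectra, and correct the crossing by the residual
amplitude ratio ($\mathrm{p}K_a = \mathrm{pH}^* - \log_{10}\rho$ with
$\rho$ the ratio of pure-spectrum trace amplitudes). Four iterations
reduce the truncation bias to under 0.01 pH units.

**Derivatives.** Column-wise Savitzky–Golay differentiation with respect
to wavelength, window 7 and cubic polynomial by default — suited to bands
of width ≥ ~9 nm sampled at 1 nm. The reference work used vendor software
without stating parameters.

**Zero-crossing.** A derivative value counts as zero when its magnitude is
below 2% of that column's maximum amplitude. Because derivative signs are
arbitrary, the crossing of the two selective traces is located on their
magnitudes.

**Baseline-to-peak.** The published description of the M and N differences
is garbled in its prose; the package implements the standard reading: M =
A − A(acid limit), N = A(base limit) − A, fit log10(M/N) against pH by
ordinary least squares over points with both M and N above 2% of the
amplitude, pKa = −intercept/slope. The slope is left free and reported as
a diagnostic (unit slope indicates a clean single transition) rather than
constrained.

**Seok closed form.** The printed equation in the source literature has
ambiguous numerator/denominator boundaries, so the form used here was
re-derived from scratch: writing the two-state trace
$A(\mathrm{pH}) = (A_{HA} + A_{L}r)/(1+r)$, $r = 10^{\mathrm{pH}-pK_a}$,
at three pH values and eliminating the two limiting absorbances gives
$\mathrm{p}K_a = \mathrm{pH}_1 - \log_{10}(N/D)$ with the N and D stated
in `?seok_pka`. The derivation is verified in the test suite against an
independent numeric three-equation solver on 1000 random inputs (agreement
to 1e-8). In the cascade, the three points default to the window's
25th/50th/75th percentile pH columns.

All estimators are invariant to uniform absorbance scaling, so molar
absorptivity and path length never matter. Reported values are rounded to
two decimals for display; full precision is kept internally.

### Accuracy envelope

With noiseless synthetic data generated from the experimental constants of
all 24 reference compounds, the cascade recovers every dissociation to
within 0.05 pH units provided the transition is at least 2 pH units from
its neighbours and at least 1 unit inside the measured pH range. Overlapping
transitions (catechin's 8.67/9.37) or transitions cut at the boundary
(4-*tert*-butylcatechol's 13.93 against a pH 14 ceiling) violate the
two-state-per-window assumption and are not claimed; they are where the
multivariate global-fitting methods the package deliberately omits would
be needed.

## Thermodynamic cycle

For the proton-exchange reaction HA + H₂O → A⁻ + H₃O⁺,

$$ \Delta G_{sol} = \Delta G_g + \Delta G_{solv}(A^-) + \Delta G_{solv}(H_3O^+) - \Delta G_{solv}(HA) - G_{solv}(H_2O), $$
$$ \mathrm{p}K_a = \Delta G_{sol}/1.364 - \log_{10}[H_2O], \qquad
   \mathrm{p}K_a^{corr} = \mathrm{p}K_a - 4.54 . $$

Choices worth stating:

* **1.364 kcal/mol** is stored as the conventional printed constant rather
  than recomputed, for bit-reproducibility; `rt_ln10_kcal()` exists to
  validate it (RT ln 10 = 1.3642 at 298.15 K with
  R = 1.98720425e-3 kcal mol⁻¹ K⁻¹).
* **[H₂O] = 55.34 mol/L** (pure water at 25 °C). The source expression
  uses log[H₂O] without printing a value; the molarity is exposed in
  `thermo_config()` so other standard-state conventions can be applied.
* **4.54** is the empirical proton-exchange correction; corrected and
  uncorrected values differ by exactly this constant for any input.
* The package consumes free-energy tables (TSV; kcal/mol per species and
  solvation model) and never runs quantum chemistry. Effects such as the
  intramolecular hydrogen bond between the neighbouring hydroxyls are
  representable only as alternative free-energy rows.

## Validation analyses

`compare_solvation_models()` ranks PCM/IPCM/CPCM by their maximum percent
relative error 100·|exp − calc|/exp over matched compounds. On the
packaged three-compound table, CPCM's maximum error is 2.87% (below 3%),
PCM's 5.9%, IPCM's 13.5% — IPCM worst, matching the choice of CPCM for
production calculations.

`pair_sorted()` matches computed site values to experimental dissociations
by acidity rank (both sorted ascending, truncated to the shorter side —
Dopa has four computed protons against three measured dissociations).
`correlation_r2()` then gives the OLS coefficient of determination per
dissociation index; across the 24 reference compounds this yields 0.990,
0.990 and 0.871, all above the 0.87 claim. Which compounds entered the
original correlation figure is not stated, so all 24 are used.

`first_deprotonation_site()` applies the Hammett rule: electron-donating
4-substituents (σp < 0) leave `OH_m` most acidic, electron-withdrawing
ones (σp > 0) shift the first deprotonation to `OH_p`, whose anion they
stabilise by resonance. A record is flagged as an exception either when
its site contradicts the rule (4-chlorocatechol: σp = 0.23 yet `OH_m`
first) or when the substituent is a halogen or hydroxyl: these are weak
deactivators — inductively withdrawing but resonance-donating — for which
the sign of σp misstates the effect on ring acidity. That chemistry-based
flag, rather than a name lookup, is what marks 1,2,4-benzenetriol (printed
σp = −0.37, site `OH_m`, superficially rule-consistent) as the second
exception. The printed σp values are stored as published, including that
−0.37, without reinterpretation; compounds with no published σp are
reported as not classifiable and excluded from rule-consistency counts.

One bookkeeping choice: 4-ethylcatechol's experimental first pKa appears
as 8.32 in the main experimental table and as 8.29 in the solvation-model
comparison; both are stored as printed in their respective tables rather
than reconciled. "3,4-Dihydroxydihydrocinnamic acid" and "hydrocaffeic
acid" are the same compound (entry 4).

## Problem sizes, determinism and limits

The test suite and the acceptance script run simulations at the default
grids (311 wavelengths × 49 pH points); the noise-robustness check uses
100 seeds at 0.002 AU, a scale at which the whole suite completes in well
under a minute of CPU. All stochastic steps take explicit integer seeds;
the cascade itself is deterministic, and identical inputs give identical
reports.

Known limitations: no global multivariate fitting (so overlapping
transitions are out of reach by design); no activity or ionic-strength
corrections; the zero-crossing wavelength choice maximises selectivity,
not amplitude matching, and is accordingly the least accurate cascade
member; Hammett ρ (reaction-constant) regression is intentionally not
estimated.
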