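---
title: "Methods: from fluorescence-polarization plates to synergy surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence-polarization plates to synergy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estroscreen)
```

## The problem this package addresses

Estrogen receptor alpha (ERα) drives the proliferation of most breast
cancers, and tumors carrying hotspot mutations such as Y537S signal
through the receptor even without hormone. A drug-repurposing strategy
against this axis screens a library of approved drugs for direct ERα
binders by fluorescence-polarization (FP) competition, triages the hits
by annotation, confirms activity across a battery of cell-based assays
in both wild-type (MCF-7-like) and Y537S-mutant models, quantifies
potency with dose-response fits, and finally asks whether candidates
synergize with CDK4/6 inhibitors and which transcriptional programs they
reshape.

`estroscreen` implements that analysis cascade as composable, tested R
functions, together with a synthetic-data generator that plants known
ground truth at every stage. Because raw plate data for such screens are
rarely deposited, the generator is the package's reference input: every
statistical claim in the test suite is a recovery of something planted.

## Primary screen statistics

**Polarization.** Each well's two emission channels are collapsed to
millipolarization, `mP = 1000 (I∥ − G·I⊥) / (I∥ + G·I⊥)`. Bound tracer
gives high mP (vehicle/DMSO wells); competitor-displaced tracer gives
low mP (estradiol wells). The instrument G factor defaults to 1 and is a
per-well column in the input, since kit-specific values vary.

**Plate QC.** The Z' factor, `1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|` with sample
standard deviations over the positive and negative control wells,
summarizes each plate's assay window. Plates with `Z' < 0` are failed
and contribute no compounds to scoring — their compounds are reported as
QC-excluded rather than silently dropped, so library accounting is
conserved. The boundary `Z' = 0` is kept because the discard rule is
strictly "below zero". A plate whose control means coincide has no
window at all; its QC row carries the error message as the failure
reason.

**Hit calling.** Compound wells are first normalized to percent
displacement against their own plate's control means (0 = vehicle-like,
100 = full competition; noise may push values outside that range and
they are retained). Robust Z scores, `(x − median) / (1.4826·MAD)`, are
computed per plate over that plate's compound wells, oriented so binders
score positive, and a compound is a primary hit when `Z* > 3` strictly.
Two declared choices deserve emphasis:

* *Per-plate scoring.* The median/MAD are taken within each plate, not
  across the library, which makes the score invariant to plate-to-plate
  shifts in absolute mP. With 384-well plates carrying ~85–352 compound
  wells the MAD is well estimated; the score is undefined (and reported
  as an error, never a division by zero) on degenerate plates.
* *Consistency factor 1.4826.* Scales the MAD to estimate the standard
  deviation under normality, so `Z* > 3` carries its familiar ~0.13%
  one-sided false-positive rate; the test suite checks a pure-null
  screen empirically against that rate.

## Annotation triage

The primary hit list is depurated in three ordered stages: anti-cancer
drugs, drugs already used for endocrine indications, then manually
flagged compounds (xenoestrogens, progestins, hormones). Stages are set
subtractions, so the final list does not depend on the order; only the
*attribution* of a multiply-flagged compound does, and it is fixed to
the first matching stage. Every input hit appears exactly once in the
survivors or the removal ledger — an invariant the tests enforce. The
package ships no curated drug ontology: annotations are a user-supplied
table, and `simulate_annotations()` builds synthetic ones that reproduce
the canonical 61 → 47 → 35 → 21 funnel for testing.

## In-cell consensus

Each cell line contributes six datasets: receptor levels and
proliferation at days 3 and 7, transcriptional-reporter activity at
days 1 and 3. The per-dataset hit rule is not something a heatmap
figure pins down, so it is a declared, configurable default: a
compound's mean readout is standardized against the vehicle wells'
median and scaled MAD, and it is a hit when that robust effect is at or
below −3 — one-sided, because all three assays read an active compound
as a reduction. A compound passes a cell line when at least `k = 4` of
the 6 datasets support it (monotone by construction), and the two cell
lines' consensus sets are intersected to separate shared from
line-specific candidates.

## Dose-response and Ki

The four-parameter logistic `y = bottom + (top − bottom)/(1 +
(x/IC50)^hill)` is fit by unweighted nonlinear least squares on log10
dose. The sign of `hill` encodes orientation: displacement and
growth-inhibition data *rise* from 0 toward `top` with dose, which in
this parameterization is a negative slope; fits are canonicalized to
`bottom ≤ top` (the model is invariant under swapping asymptotes and
negating the slope), so downstream code can rely on the orientation of
the asymptotes.

Numerical choices: Levenberg–Marquardt descent (`minpack.lm::nls.lm` on
a residual function, which is robust to exactly-zero residuals from
noiseless data) from a multi-start grid — five log-spaced IC50
candidates across the observed dose range crossed with Hill slopes
{±0.5, ±1, ±2} — keeping the lowest residual sum of squares among
converged starts. A fit that converges nowhere reports
`converged = FALSE` with the collected optimizer messages; parameters
are never fabricated. Noiseless data are recovered to better than 1e−6
relative error, and the fitted IC50 is exactly equivariant under dose
rescaling.

Uncertainty is a nonparametric case bootstrap: replicate rows are
resampled within each dose and refit from the original estimates; the
2.5/97.5 percentiles of the resampled IC50s form the 95% interval.
Below 100 resamples the result carries a warning field. The binding
IC50 is reported as the inhibition constant Ki directly, as is common
for FP competition when tracer parameters are unpublished; when the
tracer concentration and Kd are known, `cheng_prusoff_ki()` applies
`Ki = IC50/(1 + [L]/Kd)`.

Impedance-style growth curves are reduced to endpoint inhibition by
normalizing each dose's cell index to its value at treatment time
(normalized cell index) and taking `1 − NCI_dose/NCI_vehicle` at the
endpoint, clipped to [0, 1] with clipping reported. The validation
growth IC50s refer to a 5-day endpoint.

## Synergy surfaces

Combination grids live on the effect-fraction scale (0 = vehicle,
1 = complete inhibition) with dose 0 on both axes, so the first row and
column are single-agent margins. Margins are fit with the 4PL; three
reference surfaces are available:

* **Bliss** independence `E = E_A + E_B − E_A·E_B`, requiring effects in
  [0, 1];
* **HSA** `E = max(E_A, E_B)`, which never exceeds Bliss on the
  fraction scale;
* **Loewe** additivity, solving `d_A/D_A(E) + d_B/D_B(E) = 1` for each
  cell by root bracketing on the shared effect range of the two fitted
  curves (tolerance 1e−8). The left side is monotone in E, so the root
  is unique; cells whose additive demand exceeds what both drugs can
  reach below their fitted ceilings are flagged `out_of_range` and never
  extrapolated. The solver passes the sham-combination test (a drug
  "combined" with itself reproduces its own curve at the summed dose) to
  1e−6.

On the margins the expected surface is set to the observed margins, so
synergy deltas vanish there by construction. The pointwise score is
`observed − expected` (positive = synergy) and the summary score is the
mean delta over interior cells. Per-cell significance shading is not
computed: the grid container stores per-cell replicate means, and a
t-test overlay would need the full replicate spread, which endpoint
grids rarely retain.

## Gene-panel modulation

Relative expression uses the delta-delta-Ct rule, `fold =
2^−[(Ct_tgt,trt − Ct_ref,trt) − (Ct_tgt,ctl − Ct_ref,ctl)]`, which
cancels any global cycle offset. Genes with a missing Ct or any Ct above
40 cycles are invalid and leave both numerator and denominator of every
percentage. A gene is *modulated* when `|fold − 1| > 0.5` strictly — the
">50% variation" rule read symmetrically on the linear fold scale, so
fold 0.4 and fold 1.6 both qualify while the boundary values 0.5 and
1.5 do not. An asymmetric reading (e.g., up means fold > 2) is a
one-line change via the threshold argument. The panel summary reports
the percentage of valid genes modulated and, of those, the percentage
reduced; the latter is undefined (NA, not zero) when nothing is
modulated.

## What the generator emulates — and what it does not

The generator's defaults describe the study conditions end to end: a
1018-compound library on twelve 384-well plates (controls in the last
two columns, 16 wells each; compounds spread nearly evenly, ~85 per
plate), estradiol-like positive controls near 50 mP and vehicle wells
near 200 mP, Gaussian well noise of 5 mP, and 61 planted binders with
displacement fractions drawn uniformly from [0.8, 1.0] — strong hits,
as a validated-compound recovery experiment requires. With that noise
the expected plate Z' is 0.8; the config warns whenever requested noise
implies an expected Z' below zero. The layout arithmetic otherwise uses
the fewest plates that hold the library, so small test screens fit one
plate.

Noise models are the standard measurement models for each readout:
multiplicative Gaussian (coefficient of variation) for optical
intensities and plate readouts, additive Gaussian in Ct space for qPCR.
Dose-response validation curves use 8 log-spaced doses spanning 1/30 to
30 times the true potency, 5% CV and 3 replicates; combination grids
default to 3 replicate wells per cell, stored as cell means. All
generators take explicit integer seeds (scoped with `withr`, leaving
the session RNG untouched) and are bit-reproducible.

Deliberately not modeled: fluorophore photophysics, plate-edge and
drift effects, dispense errors, compound fluorescence interference,
cytostatic-versus-cytotoxic distinctions in growth curves, and
amplification-efficiency differences in qPCR. Passing tests therefore
demonstrate that the *statistics* recover planted truth under idealized
noise — not that any real screen is free of the artifacts above.

A note on statistical honesty: under the default curve protocol the
sampling spread of a fitted log-IC50 is roughly 8%, so any single
simulated curve can land more than 15% from its planted truth with a
few percent probability. The test suite checks distributional accuracy
(median absolute log-error below 0.07 over 100 curves) alongside
specific seeded recoveries.

## Problem sizes and runtime

The shipped tests and the acceptance script run the full-scale screen
(1018 compounds, 12 plates), a 3520-compound null screen for the
false-positive-rate check, 100-curve recovery sweeps, and bootstrap
intervals at 100–200 resamples — sizes chosen so the whole suite
completes in a few minutes on a laptop core while keeping every
statistical check well-powered. Bootstrap defaults are 1000 resamples
for production use.

## Known limitations

* The triage annotations are synthetic stand-ins with the canonical
  funnel cardinalities; real analyses must supply a curated table.
* The per-dataset in-cell hit rule (robust Z ≤ −3 versus vehicle) is a
  declared default, not a published one; sensitivity to it should be
  explored with the threshold argument.
* Loewe surfaces require strictly monotone fitted margins; flat or
  non-invertible fits are rejected with a pointer to Bliss/HSA.
* Ki equals IC50 unless tracer parameters are supplied; absolute
  affinities are therefore upper bounds.
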