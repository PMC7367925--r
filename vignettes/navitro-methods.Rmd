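---
title: "navitro: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{navitro: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navitro)
```

navitro implements the data side of a cross-laboratory in vitro toxicology
testing program: a validated plate-data format, baseline quality control,
concentration–response summarization to points of departure (PoD),
free-concentration biokinetics, and test-method readiness scoring. This
vignette explains the underlying models, the parameters that matter, and
the design decisions taken where more than one defensible choice existed.

## The unified concentration convention

All concentrations are carried internally as $-\log_{10}$ of the molar
concentration ("neglog"): 6.0 is 1 µM, 5.6 is about 2.5 µM, 7.0 is 100 nM.
Unit conversion happens only at the I/O boundary (`neglog_to_conc()`,
`conc_to_neglog()`), which removes the µM/nM mix-up class of errors
entirely and makes potencies directly comparable across assays. Display
formatting rounds to two significant figures (`format_conc()`); full double
precision is kept internally. The conversion pair round-trips to better
than $10^{-12}$ relative error over the whole working range (0–12), which
the test suite verifies.

The standard test design is a 13-point dilution series from 4 to 10 in
0.5-log steps (100 µM down to 0.1 nM), in triplicate. `dilution_series()`
treats the series as an inclusive arithmetic sequence in neglog space with
a $10^{-9}$ tolerance on the endpoint so binary representation of steps
like 0.5 cannot drop the final point.

## Plate-data format and validation

One plate file is a long-format CSV (one row per well × endpoint) preceded
by a `#`-prefixed `key: value` metadata header. The design responds to the
documented failure modes of spreadsheet-era data handling:

* **Strict numerics.** The decimal separator is "." only. A cell like
  `40,5` raises `LOCALE_COMMA`; a cell like `Jun-05` — the signature of a
  spreadsheet converting a number to a date — raises
  `SPREADSHEET_DATE_ARTIFACT`. Nothing is silently coerced; parse issues
  are structured findings with row/column coordinates.
* **Flags are annotations, not deletions.** `lab_error`, `outlier` and
  `below_detection` travel verbatim through every read/write; flagged rows
  are excluded only at computation time (control means, curve fits). The
  rationale is information preservation: dropping rows on write is exactly
  the loss the format exists to prevent.
* **Control linkage.** Every plate × endpoint that carries treatment wells
  must also carry at least one solvent-control well
  (`MISSING_CONTROL_LINK`), since all downstream statistics are expressed
  relative to the plate's own controls.
* **Metadata discipline.** `test_method_id`, `lab_id`, `solvent` and
  `exposure_h` are mandatory at parse time. Identical metadata blocks
  across datasets with *different* run ids are reported as the
  copy-paste-without-adaptation pattern (warning severity, because
  legitimate repeat runs can look similar).
* **Determinism.** Writes use a fixed key order, fixed column order and
  15-significant-digit numeric formatting, so two writes of one dataset
  are byte-identical and `write(read(f))` is byte-stable — a property the
  round-trip tests check on 100 randomized datasets.

Well coordinates are letter-row plus 1-based column (A1…P24); no 0-based
indexing is user-visible anywhere.

## Baseline variance

Technical replicates $x$ of the solvent controls on one plate are
normalized to their plate average $\mu$ ($x_{norm} = x/\mu$), and plate
noise is summarized as the relative standard deviation,
$\mathrm{RSD}\,[\%] = \mathrm{SD} \cdot 100 / \mu$. The SD uses the sample
($n-1$) denominator by default: replicates are a sample, and at the
typical $n$ of 3–6 the choice is material; a `sample_sd = FALSE` switch
provides the population version. The cross-plate summary is the unweighted
mean of per-plate RSDs — weighting by replicate count is an alternative,
but plates are the natural experimental unit here and equal weighting
keeps a high-replicate plate from dominating the noise estimate.

Negative-control spread (`negative_control_spread()`) pools the
solvent-control-normalized responses of designated non-cytotoxic compounds
at their two lowest tested concentrations, *and* only below a per-compound
concentration cap — the two conditions are applied conjunctively, which is
the conservative reading when both are stated. The summary reports the
pooled mean, SD and the fraction of values inside 80–120% of control.

## Concentration–response model

The curve family is the four-parameter log-logistic (4PL), the field
standard for viability and reporter endpoints, and the one family that
admits a closed-form benchmark-concentration inversion. With $c$ the
concentration in neglog units and $e$ the log EC50 on the same scale:

$$y(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{\,h \cdot s \cdot (e - c)}}, \qquad
s = \begin{cases} +1 & \text{decline} \\ -1 & \text{induce} \end{cases}$$

so declining endpoints run from `top` (low concentration) to `bottom`, and
inducing endpoints from a ~100% baseline up to their plateau. The model
family is a configuration point of the pipeline, not a claim that no other
family could serve.

**Fitting.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with multi-start initialization (EC50 at the
quartiles of the tested range × Hill slopes 0.5/1/2, best residual sum of
squares wins — a deterministic tie-break). Default bounds: bottom
$\in [-10, 50]$%, top $\in [50, 120]$%, hill $\in (0, 10]$ for decline;
for induction those asymptote bounds cannot hold (reporter induction
routinely exceeds 120% of control), so the defaults become baseline
$\in [50, 120]$% and plateau up to 10 000%. In both directions the log
EC50 is constrained to the tested range ±1 log unit, so a fitted EC50 can
never be a far extrapolation — this matches the censoring semantics: what
the series cannot see is reported as a bound, not invented.

**No-effect and failure handling.** If the per-concentration mean
responses span less than `min_effect` (default 10 percentage points), the
fit is refused with `fit_ok = FALSE` and note "no effect" — fitting four
parameters to a flat profile is meaningless, and the downstream PoD is
censored. Optimizer failure across all starts gives `fit_ok = FALSE`,
"no convergence". No automatic statistical outlier rejection is applied by
default; the workflow's quality gate is the expert visual check, encoded
as a mandatory per-curve flag (`pending`/`passed`/`failed`) that summary
exports can refuse while pending. An optional studentized-residual screen
(|r| > 3, one refit) exists for callers who want it.

**BMC and PoD.** The benchmark concentration at benchmark response BMR is
the closed-form inversion of the fitted curve at $100 - \mathrm{BMR}$
(decline) or $100 + \mathrm{BMR}$ (induce). The default BMR is 25% of
control — a conventional mid-sensitivity choice on these endpoints — and
because it is a convention, not a constant of nature, it is configurable
and recorded in every PoD result (provenance). When the fitted asymptote
never reaches the target, the result is censored with the bound set to the
**highest tested concentration** (the minimum neglog of the series):
"no effect observed up to …". The closed form is verified against numeric
root-finding to $10^{-9}$ on 1000 random curves. For non-monotone
composite responses (induce-then-decline reporters) only the fitted
monotone branch is inverted; the lowest-concentration crossing would be
the tie-break if a non-monotone family were configured.

**Cytotoxicity anchoring.** A functional hit is interpreted against the
viability PoD of the same system via the specificity ratio
$10^{\mathrm{PoD}_f - \mathrm{PoD}_v}$. Cut-offs: ≥10× specific, 3–10×
borderline, <3× cytotoxicity-confounded — derived from the qualitative
observation that genuinely pathway-specific activations sit roughly
10–100× below cytotoxic concentrations, and configurable. A censored
functional PoD is `undetermined`; a censored viability PoD makes the ratio
a lower bound (still `specific`). In antagonist mode the reference agonist
is co-applied at its fitted EC50 (`reference_ec50()`); antagonist-mode
responses are normalized to the agonist-only co-treatment control, the
natural 100% reference for inhibition.

## Free-concentration model

The biokinetics module predicts the fraction of the nominal concentration
that is free in medium from a three-compartment, linear-binding mass
balance:

$$f_u = \frac{1}{1 + K_{prot} C_{prot} + K_{lip} C_{lip}}$$

with sorption coefficients in L/kg and phase concentrations in kg/L.
Assumptions, inherited from the framework this implements: (i) albumin and
triacylglycerol are the only significant binding phases; (ii) binding is
linear over the tested range; (iii) compounds with air–water partition
coefficient $K_{AW} < 0.03$ are non-volatile (the band
$[0.015, 0.03)$ — half-threshold — is flagged borderline, which reproduces
the judgement call usually made at $K_{AW} = 0.02$; both edges are
configurable); (iv) plastic and cell binding are excluded — a permanent
warning notes that extreme hydrophobics (logK$_{ow}$ > 5) can lose of the
order of a third of the compound to plastic.

Albumin stands proxy for all serum protein, converted at 66.5 kDa; the
100% FCS reference is 23 mg/mL protein ≈ 346 µM albumin and ~6000 mg/L
lipid, scaled linearly to the medium's FCS percentage
(`medium_from_fcs()`). Charcoal-stripped serum is handled by overriding
the lipid term to zero while keeping the protein term.

**Binding constants** come in two modes, because projects typically have
measured plasma protein binding (PPB) for drugs but only logK$_{ow}$ for
industrial chemicals:

* `ppb_scaled` (default when PPB is available):
  $K_{prot} = \frac{\mathrm{PPB}/(1-\mathrm{PPB})}{C_{alb,plasma}}$ with a
  600 µM plasma-albumin reference (configurable); the lipid term falls
  back to $K_{lip} = K_{ow}$.
* `kow_regression`: $\log_{10} K_{prot} = 0.71 \log K_{ow} + 0.42$ (serum
  albumin sorption regression) and $K_{lip} = K_{ow}$.

The two modes can differ noticeably for strong binders — PPB-scaled
constants embed whatever non-albumin binding the plasma measurement
contains — which is why the mode used is always recorded in the result and
why the package does not promise exact reproduction of any particular
published free-fraction table. What the model does guarantee, and the
tests verify, is: the three fractions sum to one; $f_u$ is monotonically
decreasing in albumin, lipid and logK$_{ow}$; $f_u \to 1$ as the binding
phases vanish; and serum-free media give free ≡ nominal exactly, so
low-binding compounds show a 0% free-vs-nominal difference there, well
inside the ≤5% band expected of most media.

## Readiness scoring

A test method's fit-for-purpose readiness is scored over a rubric of 13
categories with 62 sub-items in total. The shipped default
(`default_rubric()`) is a structural skeleton — correct shape, placeholder
wording, uniform 2-point maxima — because the authoritative sub-item texts
belong to the readiness-criteria literature; real evaluations should load
their rubric via `load_rubric()` (YAML).

At least two experts score independently; sub-item scores are averaged.
The discrepancy metric is the spread of the raters' *overall* percentages
in percentage points: the 20%-rule is stated without a base in common
practice, and the overall percentage is the quantity the rule protects, so
that is where it is applied (per-item ranges are also reported for
transparency). At ≥20 points with two raters, a third rater is required
and report generation is blocked; with three sheets the arithmetic mean of
all three is used. Category and overall percentages are points-weighted
(sum of means over sum of maxima), not category-averaged — a deliberate
choice the tests pin down with a toy rubric where the two definitions
differ. Bands: high ≥85%, intermediate ≥50%, low otherwise; the published
band notation overlaps at 85 and 50, and navitro assigns boundaries to the
better band (config-overridable).

## The synthetic generator

`synthetic_spec()`/`generate_plate()` emulate the standard battery design:
13-point 0.5-log series, triplicates, solvent controls on every plate,
multiplicative lognormal noise (mean-one parameterization,
$\sigma_{\log}^2 = \log(1 + CV^2)$), optional additive noise, and
flag-annotated outlier injection (3× deviation). The default control CV of
10% reflects what a well-behaved viability endpoint shows — average
baseline RSDs in the low teens — and is configurable per spec. Negative
controls respond flat at 100%. Random streams are per-plate substreams
derived from the master seed, so extending a study with more plates never
reshuffles existing ones, and the generator restores the caller's RNG
state.

What it deliberately does **not** emulate: plate edge effects, signal
drift, pipetting gradients, heteroscedastic detector saturation, or
compound-specific artifacts (precipitation, autofluorescence). Passing
recovery tests on this generator therefore demonstrates correctness of
the pipeline's statistics under its stated noise model — not robustness to
every pathology of real screening data; the visual-check workflow exists
for exactly that gap.

Problem sizes used by the test suite were chosen to exercise the claims at
meaningful scale while keeping the suite quick: 200 seeded fits for
parameter recovery at 5% CV (13 points × 3 replicates), 1000 random curves
for the BMC closed-form/root-finding equivalence, 1000 random vectors for
the RSD oracle, 100 randomized datasets for format round-trips.

## Known limitations

* The 4PL is the only built-in curve family; model-averaging and
  biphasic families are out of scope.
* The free-fraction model stops at the medium: no cell partitioning, no
  PBPK, no in-vitro-to-in-vivo dose extrapolation.
* Exact numeric agreement with any specific published free-fraction table
  is not guaranteed (binding-constant provenance differs between sources);
  the model's structural guarantees are what the package asserts.
* Time-course endpoints are treated as separate endpoints per time point;
  there is no longitudinal model.
* The readiness module aggregates expert scores; it does not score method
  descriptions automatically.
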