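# navitro

**navitro** is an R toolkit for running a battery of animal-free in vitro
test methods (NAMs — new approach methods) across laboratories and getting
comparable, regulator-ready numbers out the other end. It covers the five
data-side jobs such a testing program needs:

1. **A validated plate-data format** — long-format CSV with a `#`-prefixed
   metadata header (test method, laboratory, solvent, exposure time, run id),
   strict numeric parsing, and a validator that catches the classic
   spreadsheet failure modes: locale commas, numbers silently turned into
   dates ("Jun-05"), lost laboratory-error/outlier flags, missing
   solvent-control linkage, copy-pasted metadata blocks.
2. **Baseline-variance QC** — per-plate noise of solvent controls as the
   relative standard deviation of technical replicates
   (RSD [%] = SD·100/μ, with x_norm = x/μ), and the pooled spread of
   non-cytotoxic negative-control compounds around 100% of solvent control.
3. **Concentration–response analysis** — normalization to solvent controls,
   bounded four-parameter log-logistic (4PL) fitting, closed-form benchmark
   concentration (BMC) inversion at a recorded benchmark response (BMR),
   and points of departure (PoD) in a unified −log10(M) convention
   (6.0 ≡ 1 µM, 5.6 ≈ 2.5 µM), with censoring ("no effect observed")
   bounded by the highest tested concentration, and cytotoxicity anchoring
   of functional hits via the specificity ratio
   10^(PoD_functional − PoD_viability).
4. **Biokinetics** — the free (unbound) fraction of a compound in any
   culture medium from a three-compartment mass balance,
   f_u = 1 / (1 + K_protein·C_protein + K_lipid·C_lipid), with albumin as
   serum-protein proxy (66.5 kDa; 100% FCS ≡ 23 mg/mL ≈ 346 µM albumin and
   ~6000 mg/L lipid) and binding constants either scaled from measured
   plasma protein binding or regressed from logK_ow.
5. **Readiness scoring** — fit-for-purpose test-method evaluation over a
   13-category / 62-sub-item rubric, two-expert aggregation with a
   third-rater rule at ≥20 percentage points discrepancy, and
   green/orange/red bands (high ≥85%, intermediate ≥50%, low <50%).

A deterministic synthetic-plate generator with known ground truth
(`synthetic_spec()` / `generate_plate()` / `generate_battery()`) makes the
whole pipeline testable end to end without any external data.

## Worked example

Simulate a small study — one cytotoxic compound (rotenone-like) and one
negative control (tolbutamide) on three plates of a 13-point, 0.5-log
dilution series — then run the full pipeline:

```r
library(navitro)

truth <- data.frame(
  compound_id = c("rotenone", "tolbutamide"),
  endpoint_id = "viability",
  top = 100, bottom = c(0, 100), log_ec50 = c(6.8, 5), hill = c(1.5, 1),
  direction = "decline")
spec <- synthetic_spec(seed = 17, true_curves = truth, n_plates = 3,
                       noise_cv = 0.10, negative_controls = "tolbutamide")
plates <- generate_plate(spec)

validate_dataset(plates)
#> validation report: clean (no findings)

plate_baseline_profile(plates, "viability")
#> baseline profile: 3 plate(s), average RSD 10.23%
#>  plate_id endpoint_id n_replicates  mean_raw    sd_raw rsd_percent
#>       P01   viability            6 1001.0010 124.66326    12.45386
#>       P02   viability            6  952.4719  58.16651     6.10690
#>       P03   viability            6 1012.9938 122.96724    12.13899

pod_rot  <- fit_and_pod(plates, "rotenone", "viability")
pod_tolb <- fit_and_pod(plates, "tolbutamide", "viability")
assemble_pod_matrix(list(pod_rot, pod_tolb))
#>             viability
#> rotenone    "7.11"
#> tolbutamide "no effect"
```

The per-plate RSDs estimate the 10% noise the generator injected; the
fitted PoD of 7.11 −log10(M) (≈ 0.077 µM at the default BMR of 25%)
recovers the true curve (log EC50 6.8, so the BMC25 sits above it on the
−log scale), and the flat negative control is correctly censored as
"no effect observed".

Free-concentration prediction for a strong plasma-protein binder in a
10%-serum medium:

```r
reg  <- read_registry(system.file("extdata", "demo_registry_synthetic.csv",
                                  package = "navitro"))
tolb <- registry_compound(reg, "tolbutamide")
free_fraction(tolb, medium_from_fcs(10), mode = "kow_regression")
#> <free_fraction tolbutamide in fcs_10> f_u = 0.710 (protein 0.197, lipid 0.093) [kow_regression]
#>   note: volatility unknown (no K_AW value)
#>   note: binding to plastics and cells is not modelled
```

So ~71% of the nominal concentration is predicted free in 10% FCS medium,
and in serum-free medium the free concentration equals the nominal exactly.
The shipped registry (`inst/extdata/demo_registry_synthetic.csv`) is an
illustrative demo — its physicochemical values are plausible but not
authoritative; supply your own measured registry for real work.

A thin command-line front end over the same functions is installed at
`system.file("cli", "navitro.R", package = "navitro")`, e.g.

```sh
Rscript navitro.R chem convert --neglog 5.6 --unit uM
Rscript navitro.R data validate plate.csv --registry registry.csv
```

## Documentation

The methods vignette (`vignettes/navitro-methods.Rmd`) describes the
models, their assumptions, the tunable parameters with defaults and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical choices and known limitations.
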