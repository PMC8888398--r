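# sctape

Dermatopharmacokinetic (DPK) analysis of stratum corneum (SC)
tape-stripping studies, with a companion skin-blanching
(vasoconstriction) pipeline, an exact noncentral-t power engine, and a
fully seeded synthetic-study generator.

## Who this is for

Groups running (or planning) topical-bioavailability studies in which
the SC is sampled with adhesive tapes after a timed drug application:
per-tape SC masses and pooled-group drug assays go in; depth profiles,
areal drug loads, kinetic metrics, outlier-screened summaries, and
power/sample-size tables come out. Because raw clinical datasets in
this field are rarely shareable, the package also *generates* complete
synthetic studies with the statistical structure the analysis assumes,
so every stage is testable end to end.

## The model

For each subject and dose, an uptake site is stripped immediately
after a 4-h application and a clearance site Δt = 6 h later. With
Q_Up and Q_Cl the drug masses per unit area (ng cm⁻²) recovered from
the two sites:

* input flux into viable tissue: **J = (Q_Up − Q_Cl)/Δt**
* first-order SC elimination: **k = −ln(Q_Cl/Q_Up)/Δt**
* relative depletion: **1 − Q_Cl/Q_Up**

SC thickness removed follows from mass/(area·density); group
concentrations are drug mass over pooled SC mass; extracts below the
assay LOQ (0.032 µg mL⁻¹) are censored, not zeroed, in the data files.
The blanching arm normalises chromameter a* readings against three
untreated control sites (Δa*_t) and integrates the signed area above
the effect curve (AAEC, hours, 0–22 h, trapezoidal; negative =
blanching). Power and sample size for detecting a fractional change
in any metric's mean use the exact noncentral-t one-sample test.

## Worked example

```r
library(sctape)

# a complete synthetic study: 12 subjects x {2, 5, 10} mg/cm2 x
# {uptake, clearance} SC sites + blanching sites, fully seeded
study <- simulate_study(sim_config(seed = 42))

siteq <- site_Q(study$strip_data$groups)        # per-site Q (BLQ -> 0)
siteq <- merge(siteq, study$sites[, c("subject_id", "site_id",
                                      "dose", "phase")])
metrics <- dpk_metrics(siteq[siteq$phase %in%
                               c("uptake", "clearance"), ])
tab1 <- table1_report(metrics)
tab1[tab1$metric %in% c("q_up", "q_cl"), ]
#>    dose metric  n mean   sd ci95_half ci_defined n_outliers
#> 1     2   q_up 11 39.2 35.0      23.5       TRUE          1
#> 2     2   q_cl 12 25.5 31.1      19.7       TRUE          0
#> 5     5   q_up 11 73.0 38.3      25.7       TRUE          1
#> 6     5   q_cl 12 51.2 52.0      33.0       TRUE          0
#> 9    10   q_up 11 91.0 46.9      31.5       TRUE          1
#> 10   10   q_cl 12 63.9 58.1      36.9       TRUE          0
```

Per-dose means with t-based 95% half-widths after a single-pass Grubbs
screen; the low-dose means sit well below the noise-free calibration
(≈55 ng cm⁻²) because the 64-ng-per-group LOQ censors many low-dose
clearance groups — the censored fraction is reported per site.

The kinetic identities on published-scale numbers:

```r
dpk_flux(55, 37, 6)            # 3      ng cm-2 h-1
elim_rate(55, 37, 6)           # 0.06607 h-1
100 * depletion(55, 37)        # 32.7 -> prints as 33%
thickness_from_mass(0.49, 1)   # 4.9 um
```

Power of a 12-subject design to detect a 20% or 50% change in mean
Q_Up, and the n required for 80% power:

```r
summ <- data.frame(metric = "q_up", dose = c(2, 5, 10),
                   mean = c(55, 94, 63), sd = c(27, 45, 20), n = 12)
power_table(summ)[, c("dose", "effect_fraction", "delta",
                      "power_pct", "n_required")]
#>   dose effect_fraction delta power_pct n_required
#> 1    2             0.2  11.0      25.2         50
#> 2    5             0.2  18.8      26.2         47
#> 3   10             0.2  12.6      51.2         22
#> 4    2             0.5  27.5      89.4         10
#> 5    5             0.5  47.0      90.8         10
#> 6   10             0.5  31.5      99.9          6
```

A 50% change is comfortably detectable with 6–10 subjects; a 20%
change needs 22–50.

## Command line

```sh
Rscript inst/cli/sctape.R simulate  --seed 42 --out-dir study/
Rscript inst/cli/sctape.R report    --in-dir study/ --out-dir out/ --seed 42
Rscript inst/cli/sctape.R analyze-sc --strips study/strips.csv \
    --sites study/sites.csv --out-dir out/ --blq-policy zero
Rscript inst/cli/sctape.R analyze-sb --chroma study/chromameter.csv \
    --sites study/sites.csv --out-dir out/ --aaec-anchor on
Rscript inst/cli/sctape.R power --input out/table1.csv --out-dir out/
```

Outputs are deterministic given `--seed`; every CSV carries the seed
in a `# seed=N` header line.

## Layout

* `R/` — data model & CSV I/O, Fickian generator, SC profiles, DPK
  metrics, blanching, power engine, CLI
* `tests/testthat/` — unit, property and acceptance suites (all
  fixtures generated in code)
* `vignettes/sctape-methods.Rmd` — model assumptions, numerical
  choices, generator calibration, limitations
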