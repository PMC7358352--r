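# secmal

Secondary-malignancy risk estimation from paired proton/photon
dose–volume histograms.

## What it does

Patients cured of mediastinal lymphoma by radiotherapy live long enough
for radiation-induced second cancers to matter, so the choice between
proton therapy and photon IMRT is partly a choice between the second-cancer
risks each modality leaves behind in the lungs, breasts and esophagus.
`secmal` quantifies that trade-off for a paired cohort: for every patient it
takes the differential dose–volume histogram (DVH) of each organ at risk
under both plans and computes

**Cancer-induction risk (linear–quadratic competition model).** For an
organ whose volume fractions *v&#7522;* receive total doses *D&#7522;* in *n*
fractions,

```
risk = Σᵢ vᵢ (α₁Dᵢ + β₁Dᵢ²/n) · exp(−(α₂Dᵢ + β₂Dᵢ²/n)) / Σᵢ vᵢ
```

where the first factor is LQ-shaped mutation induction and the exponential
is LQ cell kill — the competition makes risk rise, peak and fall with dose.
`α₁` is the ICRP-derived low-dose slope (separate values for *total* and
*fatal* cancer), `α₂` the sterilization slope, and `β = α/(α/β)` with
α/β = 3 Gy for all five organs.

**Organ equivalent dose (OED).** The uniform dose causing the same cancer
incidence as the inhomogeneous distribution,
`OED = Σᵢ vᵢ · RED(Dᵢ) / Σᵢ vᵢ`, under three dose–response scenarios:
linear (`RED = D`), linear–exponential (`RED = D·e^(−α′D)`) and plateau
(`RED = (1 − e^(−α′D))/α′`), with `α′ = α₂ + β₂D/n` re-evaluated per bin.
The proton/photon **relative risk** is the ratio of the two OEDs; RR < 1
favors protons.

Cohort comparisons use medians, ranges and an exact paired Wilcoxon
signed-rank test (exact null up to 25 informative pairs, ties handled by
midranks; normal approximation beyond). Because clinical DVH sets are
rarely shareable, the package includes a seeded generator of synthetic
paired cohorts with the structure of a 23-patient consolidation-RT
population (16 female; 20–39.6 Gy(RBE) in 10–22 fractions; photon plans
with a broad low-dose bath, proton plans with strong out-of-field sparing,
and occasional lateralized cases where the proton dose to the right breast
or esophagus exceeds the photon dose).

## Worked example

```r
library(secmal)
cohort <- generate_cohort(cohort_config())   # 23 patients, 16 female, seed 42
fit <- secmal(cohort$pairs)
fit
#> Paired proton/photon secondary-malignancy risk analysis
#>   23 patient(s) (16 female), 1469 result records
#>   8 relative-risk exceedance(s) (RR > 1)

s <- summary(fit)
q <- s$quantities
q[q$organ == "lung_right" & q$quantity == "total_risk",
  c("organ", "modality", "median", "min", "max")]
#>       organ modality     median         min        max
#>  lung_right   photon 0.02371188 0.019712523 0.02496581
#>  lung_right   proton 0.01001445 0.008204825 0.01254906
```

Risks are probability fractions: under the photon plans the median total
risk of a radiation-induced right-lung cancer is 2.37% (range 1.97–2.50%),
and the proton plans cut it to 1.00% — the direction and magnitude expected
when a low-dose bath is replaced by sharp distal fall-off. The OED-based
relative risks for the same organ:

```r
s$relative_risk[s$relative_risk$organ == "lung_right", ]
#>       organ             model    median       min       max
#>  lung_right  schneider_linear 0.4317498 0.3591814 0.5144648
#>  lung_right  schneider_linexp 0.4587282 0.3924317 0.5391820
#>  lung_right schneider_plateau 0.3880146 0.3591890 0.4064405
```

so proton therapy roughly halves the predicted lung-cancer induction under
every dose–response assumption. Individual organs can still go the other
way; the generator plants such lateralized cases deliberately and
`flag_rr_exceedances(fit)` recovers them:

```r
flag_rr_exceedances(fit)
#>  patient_id        organ            variant       rr
#>         P05 breast_right             linear 6.997494
#>         P05 breast_right linear_exponential 6.972035
#>         P05 breast_right            plateau 6.993267
#>         ...
#>         P17    esophagus            plateau 1.424157
```

`write_results(fit$results, "results.csv")` exports everything;
`read_dvh_table()` imports real cohorts from a plain-text DVH table
(cumulative or differential). A command-line wrapper with `simulate`,
`compute`, `summarize` and `compare` subcommands is installed at
`inst/cli/secmal.R`.

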