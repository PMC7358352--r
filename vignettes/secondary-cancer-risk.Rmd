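---
title: "Modelling secondary cancer risk from paired proton and photon DVHs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secondary cancer risk from paired proton and photon DVHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmal)
```

## The problem

Consolidation radiotherapy for mediastinal lymphoma irradiates young,
mostly curable patients, so the late risk of radiation-induced second
cancers in the lungs, breasts and esophagus is a first-order concern when
choosing between proton therapy and photon IMRT. `secmal` turns each
patient's paired plans into comparable risk numbers using two established
radiobiological frameworks, then aggregates a cohort with nonparametric
paired statistics.

All dose input is a *differential* DVH per organ: bin-center doses
$D_i$ in Gy(RBE) with volume fractions $v_i$ normalized to
$\sum_i v_i = 1$. Working with fractions rather than absolute volumes is
deliberate: both models below are volume-weighted averages, so absolute
organ volume cancels. Proton doses are assumed to arrive already in
Gy(RBE) (constant RBE 1.1 folded in upstream); the package does no RBE
arithmetic.

## The two risk models

**Competition model (induction vs sterilization).** The per-bin risk
contribution is

$$r(D_i) = \left(\alpha_1 D_i + \beta_1 \tfrac{D_i^2}{n}\right)
  \exp\!\left(-\left(\alpha_2 D_i + \beta_2 \tfrac{D_i^2}{n}\right)\right),$$

and the organ risk is $\sum_i v_i\, r(D_i)$. The first factor is
linear–quadratic mutation induction, the exponential linear–quadratic cell
survival; their competition makes risk rise, peak near $1/\alpha_2$ and
decay at therapeutic doses. $n$ is the plan's fraction number, applied to
every bin: each volume element receives its bin dose spread over all $n$
fractions, the standard DVH-based LQ convention. Two $\alpha_1$ values per
organ distinguish *total* (any induced cancer) from *fatal* risk;
$\alpha_1^{fatal} \le \alpha_1^{total}$ always, so fatal risk can never
exceed total risk. Defaults (per Gy):

| organ | $\alpha_1$ fatal | $\alpha_1$ total | $\alpha_2$ |
|---|---|---|---|
| lung (each side) | 0.0101 | 0.0144 | 0.129 |
| breast (each side) | 0.0028 | 0.0144 | 0.008 |
| esophagus | 0.0014 | 0.0015 | 0.274 |

Both quadratic coefficients derive from the same organ ratio,
$\beta = \alpha/(\alpha/\beta)$ with $\alpha/\beta = 3$ Gy — one ratio per
organ, not per term, which is the only reading consistent with a single
stated organ ratio. Risks are stored as fractions in $[0,1]$; report
formatting multiplies by 100. Coefficients are overridable from YAML
(`read_coefficients()`) for sensitivity analyses; no age- or
sex-modification is applied because the $\alpha_1$ values are
population-averaged.

**Organ equivalent dose.** Two dose distributions are deemed equivalent if
they cause the same induced-cancer incidence; the OED is the uniform dose
with that incidence, computed as $\sum_i v_i\,\mathrm{RED}(D_i)$ under
three scenarios spanning the plausible high-dose behavior:

* *linear*: $\mathrm{RED} = D$ — no sterilization;
* *linear–exponential*: $\mathrm{RED} = D e^{-\alpha' D}$ — no
  repopulation/repair;
* *plateau*: $\mathrm{RED} = (1 - e^{-\alpha' D})/\alpha'$ — complete
  repopulation/repair. The $1/\alpha'$ normalization makes the response
  approach $D$ at low dose and saturate at $1/\alpha'$, the standard
  plateau form.

$\alpha' = \alpha_2 + \beta_2 D_i/n$ is re-evaluated per bin, since the
fractionation correction depends on the bin dose. The proton/photon
relative risk is the OED ratio per organ and variant. When the photon OED
is zero there is no risk to compare; such records are excluded from
summaries (not set to 1, which would bias medians) and logged.

One non-obvious consequence of the per-bin $\alpha'$: although the plateau
*response function* is strictly increasing in dose at fixed $\alpha'$,
raising a bin dose also raises that bin's $\alpha'$, so the plateau OED of
a whole DVH is not globally monotone in a bin dose. The tests assert
monotonicity where it actually holds (the response at fixed $\alpha'$) and
the turnover of the linear–exponential variant at both the response and
the OED level. Similarly, the low-dose limit $r(D) \approx \alpha_1 D$
holds within 5% at $D \le 0.1$ Gy, but approaches 1 from *above* for the
breast: with $\alpha_2 = 0.008$ the quadratic induction term outweighs the
sterilization loss at small doses.

## Cohort statistics

Per organ and quantity the package reports median, minimum and maximum
over patients, and a two-tailed paired Wilcoxon signed-rank p-value for
proton vs photon. Implementation choices:

* zero differences are dropped before ranking (Wilcoxon's original rule,
  the default of the mainstream statistics packages this analysis style
  assumes), midranks break ties;
* the null distribution is exact for up to 25 informative pairs — computed
  by a generating-function convolution over doubled ranks, so ties are
  handled exactly rather than by falling back to an approximation — and a
  tie-corrected normal approximation with continuity correction beyond;
* the two-tailed p doubles the smaller tail, capped at 1; under the
  sign-symmetric null this equals the symmetric-deviation tail sum;
* fewer than 5 informative pairs raises an `insufficient data` condition,
  which cohort summaries record as a note instead of a p-value;
* no multiple-testing correction is applied: the per-organ p-values are
  reported raw, as is conventional for descriptive paired plan
  comparisons.

Combined bilateral figures (`lung_combined`, `breast_combined`) are
per-patient left+right sums of the sided risks, summarized as such — the
median of sums, never the sum of medians (the tests include a cohort where
the two differ). Breast statistics automatically cover only female
patients because only they carry breast DVHs; a male patient with breast
DVHs is rejected at validation.

## DVH input conventions

Cumulative input (volume receiving at least each tabulated dose) is
converted by successive differences, normalized by the total volume; each
difference sits at the interval midpoint — the usual planning-system
convention with bias bounded by the grid spacing — and residual volume at
the last tabulated dose becomes a terminal bin at that dose. Zero-volume
bins are dropped; zero-*dose* bins with mass are retained, because they
dilute the volume average exactly as the models intend. Converting
differential to cumulative and back reproduces the volume fractions to
better than $10^{-12}$; mass conservation is property-tested over random
monotone inputs. Export uses `%.17g`, so a write/read round trip leaves
every downstream risk bit-identical.

## What the synthetic generator emulates — and what it does not

Clinical DVH sets are rarely publishable, so `generate_cohort()` produces
paired cohorts with the *statistical structure* of a mediastinal-lymphoma
consolidation population: 23 patients, 16 female, prescriptions of
20–39.6 Gy(RBE) in 10–22 fractions of 1.8–2 Gy(RBE) with modes near
36 Gy(RBE) and 18 fractions (fraction numbers drawn with a discrete peak
at the mode; dose per fraction reconciled so the product stays in range).

Each organ DVH is a three-component mixture — a zero-dose mass, an
exponential low-dose tail truncated at the prescription, and a plateau
mass in the bin adjacent to the prescription for tissue bordering the
target — discretized on a 0.5 Gy grid, fine enough that midpoint bias is
negligible against model effects. This is the simplest family that spans
both regimes of interest: the photon "low-dose bath" (long, heavy tails)
and proton distal sparing (large zero-dose mass, short tails). Defaults
(see `default_organ_params()`) were chosen once to give photon lung risks
in the low single-digit percent range, heavier breast involvement, and a
nearly-in-field esophagus, with proton plans dominated by the photon plans
organ-wise; per-patient lognormal jitter is shared between the two
modalities of a patient-organ, so the dominance — and hence the linear-OED
ordering — holds for every non-adversarial organ by construction, not by
luck.

Lateralized exceptions are planted explicitly: a deterministic
`round(adversarial_fraction × n)` patients (default 2/23) have the proton
and photon distributions of one organ swapped — right breast for women,
otherwise esophagus — reproducing the clinical mechanism of laterally
weighted beam arrangements without modelling beams. A fixed count rather
than a Bernoulli draw keeps the default cohort faithful to a population
with a known small number of such cases at any seed. Ground truth records
every draw so tests can check that flagged organs surface in
`flag_rr_exceedances()`.

Per-patient parameters come from counter-derived substreams of the master
seed, so extending a cohort does not perturb existing patients, and the
whole cohort is byte-reproducible through `export_cohort()`.

What the generator does **not** emulate: real spatial dose correlation
between neighboring organs, plan-optimizer trade-offs, anatomy-driven
variation in organ volume, respiratory motion, or inter-planner style
differences. Passing the directional tests therefore shows that the
pipeline preserves orderings implied by DVH dominance and recovers planted
exceptions — it does not validate the absolute risk levels of any clinical
cohort, which depend on the real dose distributions.

## Numerical and design notes

* Organ vocabulary is closed (five labels); unknown labels are errors, not
  warnings, because coefficients exist only for these organs.
* The exact signed-rank convolution covers $m \le 25$ informative pairs —
  comfortably past typical cohort sizes — at negligible cost
  ($O(m^3)$ doubled-rank states).
* Uniform-dose sanity anchors: linear OED of a uniform DVH is exactly the
  dose; the competition-model risk at zero dose is exactly zero.
* Test problem sizes: oracle-equivalence sweeps use 1000 random DVHs of up
  to 200 bins at relative tolerance $10^{-12}$; exhaustive signed-rank
  enumeration runs to $n = 12$; population-fidelity checks use a
  200-patient cohort. The full suite runs in well under a minute.
* Limitations: constant RBE only; no age/sex-specific excess-risk scaling;
  no confidence intervals on medians (ranges are reported, matching how
  such cohorts are conventionally summarized); risks are per-organ
  probabilities, not life-years lost.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_patients = 8, n_female = 5,
                                        seed = 11))
fit <- secmal(cohort$pairs)
summary(fit)
flag_rr_exceedances(fit)
```
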