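---
title: "Estimating FMEA occurrence and detectability from layered QC logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FMEA occurrence and detectability from layered QC logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcrpn)
```

## The problem

Failure modes and effects analysis (FMEA) ranks the ways a clinical process
can fail by the risk priority number RPN = O x S x D, where O scores how
often a failure mode (FM) arises, D how likely it is to slip past every
check undetected, and S the severity of the consequence. In practice O and
D are usually set by expert consensus, and it is unclear how well consensus
values describe any particular clinic.

When the quality-control measure that guards an FM is performed **twice** —
the canonical case is a physics chart check done at plan release and
repeated at the first weekly check — and the clinic records *which* check
caught each instance, O and D become estimable from routine QC data. This
package implements that estimator, the scale lookups that turn its
probabilities into 1–10 scores, a consistency test of consensus values
against observed counts, and a simulator for studying the estimator's
statistical behaviour.

## The model

Let $N_0$ be the true number of times an FM occurred (caught or not) over a
logging period, $N_1$ the number caught by the first check and $N_2$ the
number caught by the second. Assume each check independently catches a
present FM with the same single-check efficacy CE. Then

$$N_1 = N_0\,\mathrm{CE}, \qquad N_2 = (N_0 - N_1)\,\mathrm{CE},$$

which solve to

$$\mathrm{CE} = 1 - \frac{N_2}{N_1}, \qquad
  N_0 = \frac{N_1^2}{N_1 - N_2}.$$

This is the two-sample capture–recapture idea applied to QC layers: the
second check "recaptures" what the first missed, which calibrates the
efficacy of both. Two derived probabilities feed the score lookups:

* the per-plan occurrence probability $N_0 / \#\text{plans}$ (the number of
  plans must be supplied externally — it is not inferable from a catch
  log), and
* the probability $(1-\mathrm{CE})^{n}$ that the FM escapes all $n$ QC
  layers in place — the layered-defence ("Swiss cheese") identity. Adding
  checks lowers D: a CE of 84% gives D = 8 with a single check but a
  continuous D below 3 with three.

`estimate_risk()` performs all of this per failure mode on a data frame of
counts and keeps both continuous scores (e.g. 5.84) and nearest-integer
scores (6), because published tables quote both styles.

```{r}
estimate_risk(
  data.frame(fm_id = "FM36_dose_calc", n1 = 8, n2 = 2),
  n_plans = 2358
) |> tidy() |> dplyr::glimpse()
```

## Scale tables

The 10-point occurrence and detectability scales are *data*, not code: a
`scale_table` holds ten anchors (score, probability) and `prob_to_score()`
/ `score_to_prob()` interpolate **linearly in probability** between them.
Linear interpolation is the convention that makes one-decimal consensus
scores (4.4, 4.7, 5.7) land on the probabilities practitioners quote for
them; log-linear interpolation does not.

Two boundary choices matter:

* The top category of each published scale is open-ended ("more than 5%"
  occurrence, "more than 20%" undetected). We give score 10 a nominal
  finite probability (0.10 occurrence, 0.30 detectability) so that both
  lookup directions are defined on the whole of [1, 10] and the round trip
  `prob_to_score(score_to_prob(s)) == s` holds at every anchor; any
  probability above the top anchor still clamps to 10, so e.g. a 38%
  single-review detection rate (62% undetected) scores D = 10.
* Probabilities at or below the score-1 anchor clamp to 1.

The bundled anchors are reconstructions of the widely used TG-100-style
tables; clinics holding the exact institutional values should load them
with `read_scale_json()` (`inst/extdata/*.json` shows the schema) — every
function accepts substituted tables.

## Validating consensus values

`validate_consensus()` asks whether externally supplied consensus (O, D)
scores are plausible for the clinic that produced the counts:

* **Expected counts.** Consensus D is read as the undetected probability
  across *all* existing layers, so the per-check efficacy is recovered as
  $1 - p_{\text{undet}}^{1/n}$; with the O-implied occurrence probability
  this yields expected $N_1$ and $N_2$. Feeding those expectations back
  into the count estimator recovers the consensus-implied CE and $N_0$
  exactly (an algebraic identity the tests assert).
* **Tail probability.** A seeded Monte-Carlo simulation of the clinic the
  consensus scores describe (per-plan Bernoulli occurrence, per-check
  Bernoulli detection, simulated via the exactly equivalent binomial
  draws) gives the probability that total catches $N_1+N_2$ fall at least
  as far from their expectation as observed — two-sided by distance from
  expectation, which matches the "x-fold fewer instances" way these
  judgements are argued. Likelihood-ordering variants were considered and
  rejected as harder to explain for no practical gain at these counts.
* **Verdict.** Below a configurable `alpha` (default 0.05, since published
  judgements are only qualitative) the consensus entry is flagged
  `inconsistent`; estimator or bootstrap breakdown yields `indeterminate`.
  The verdict is joint in (O, D); `occurrence_ratio()` — the fold
  difference between the estimated and consensus-implied occurrence
  counts — attributes the discrepancy.

```{r}
validate_consensus(
  data.frame(fm_id = "FM36_dose_calc", n1 = 8, n2 = 2),
  data.frame(fm_id = "FM36_dose_calc", o = 4.4, d = 4.7),
  n_plans = 2358, n_reps = 2e4, n_boot = 500, seed = 1
) |> dplyr::select(fm_id, expected_n1, expected_n2, tail_prob,
                   occurrence_ratio, verdict)
```

Uncertainty on the fitted quantities comes from a **parametric bootstrap**
(`bootstrap_intervals()`): occurrences are redrawn per plan at the fitted
occurrence probability, catches per check at the fitted CE, and percentile
intervals are taken over the re-estimates. Replicates where the estimator
breaks down (no first-check catches, or $N_2 \ge N_1$) are counted and
reported — never silently dropped — and more than 50% breakdown flags the
result indeterminate.

## The simulator

`simulate_clinic()` generates the data-generating process the estimator
assumes, plus the two violations worth studying:

* each plan carries each FM independently with probability `p_occ`
  (Bernoulli per plan, not Poisson: at most one instance of an FM per
  plan, which is the convention under which instances are counted against
  plan totals; at per-plan rates of order 1% the distinction is
  negligible, but it must be fixed for reproducibility);
* an occurred FM meets the check layers **in order**, each catching it
  independently with that layer's efficacy only if all earlier layers
  missed (initial-then-weekly workflow);
* a caught FM is logged with probability `p_record`; an unrecorded catch
  is lost entirely rather than deferred, modelling incident-learning-style
  under-reporting.

A single global seed spawns a deterministic per-FM substream (string-hash
derived), so adding an FM to a configuration never perturbs the draws of
the others and event lists are bit-reproducible. What the simulator does
**not** emulate: correlated failures across plans, detection upstream of
the first check, drift in efficacy over time, and severity outcomes — so
passing parameter-recovery tests demonstrates correctness of the estimator
under its own assumptions, not robustness to everything real logs contain.

`bias_experiment()` runs scenario grids and reports truth, Monte-Carlo mean
estimates and bias. The two canonical scenarios behave as the algebra
predicts: a weaker second check (e.g. efficacies 0.9 and 0.6) makes
$1 - N_2/N_1$ overstate the common efficacy, so both the occurrence count
and the undetected probability — hence both O and D — are underestimated;
under-reporting with equal efficacies thins $N_1$ and $N_2$ equally, so CE
is unbiased while occurrence is underestimated in proportion to the
recording rate (80% recording gives roughly a 20% shortfall).

## Numerical and reporting choices

* Continuous values drive all downstream arithmetic; rounding is only for
  reporting. `N0` continuous 10.67 rounds to 11, but the occurrence
  fraction uses 10.67 (that is what makes the continuous O come out 5.8).
* Rounding is nearest integer with ties half away from zero.
* `n1 > 0, n2 = 0` is a valid estimate (CE = 1, undetected probability 0,
  D = 1). `n1 = 0` is `insufficient_data`; `n2 >= n1` is `breakdown` —
  both are per-FM status flags, never batch-stopping errors, because a
  sufficiently large sample is the remedy, not dropping the FM.
* The RPN is reported under both conventions — integer scores (the default
  ranking convention) and continuous scores (what one-decimal consensus
  tables effectively multiply) — because mixing them silently is how
  incomparable RPNs get compared.
* Both checks are assumed to share one CE; no correction for unequal
  efficacies is attempted (the bias direction is characterised instead by
  `bias_experiment()`).

## Study sizes used by the shipped tests

The test suite exercises the estimator's statistical properties at a
simulated clinic of 200 000 plans with `p_occ = 0.005` and per-check
efficacy 0.75 — roughly a thousand occurrences, the scale at which the
estimator's asymptotics are visibly in force: parameter recovery to within
0.02 on CE and 0.0005 on the occurrence fraction, bias signs under the two
assumption violations, and 95% bootstrap-interval coverage (500 simulated
clinics, checked to lie in [0.90, 0.99] for both CE and N0). Percentile
intervals on clinics with only a handful of catches — like the worked
example's 10 — are approximate and can undercover; there the intervals
should be read as indicative, and a larger sample is the route to
precision.

## Known limitations

* O, S and D occupy broad categories by design; the estimator inherits the
  coarseness of whatever anchor table it is given.
* The equal-efficacy assumption is load-bearing. Pairing checks of very
  different rigour (e.g. a physician review and a time-pressured chart
  rounds) biases both O and D downward.
* Severity is never estimated from data; it is supplied externally, and
  the interdependence of S with O and D means very different (O, S, D)
  triplets can produce comparable RPNs (10 x 2 x 10 = 200 vs
  5 x 6.2 x 6 = 186).
* The consistency verdict is a per-FM diagnostic; no multiplicity
  correction is applied across failure modes.
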