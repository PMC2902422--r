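---
title: "Probabilistic verbal autopsy interpretation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic verbal autopsy interpretation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacompare)
```

## The problem

Where vital registration is weak, Demographic Surveillance Systems
ascertain causes of death through verbal autopsy (VA): a structured
interview with the caregivers of a deceased person, yielding roughly a
hundred binary indicators (symptoms, signs, medical history) plus a
narrative. Two interpretation traditions coexist: review by local
physicians, who each assign a single cause from an abridged ICD-10-style
code list and reconcile disagreements; and probabilistic computer
interpretation, which converts the binary indicators into ranked probable
causes with a fixed knowledge base of conditional probabilities.
`vacompare` implements both arms, the harmonization needed to compare
them, the agreement and cause-specific mortality fraction (CSMF)
statistics that summarise the comparison, and a synthetic-cohort
generator with known truth so the whole chain can be validated.

## The Bayesian engine

The engine treats the causes $C_1 \dots C_m$ as mutually exclusive
hypotheses with prior probabilities $P(C_k)$ — the population CSMF — and
the indicators $I_1 \dots I_n$ as conditionally independent given the
cause, with a fixed probability base $P(I_j \mid C_k)$. For a single
indicator, Bayes' theorem in its two-hypothesis form gives

$$
P(C_k \mid I_j) =
  \frac{P(I_j \mid C_k)\,P(C_k)}
       {P(I_j \mid C_k)\,P(C_k) + P(I_j \mid \lnot C_k)\,(1 - P(C_k))},
\qquad
P(I_j \mid \lnot C_k) =
  \frac{\sum_{k' \ne k} P(I_j \mid C_{k'})\,P(C_{k'})}{1 - P(C_k)} .
$$

Applying this across all causes and renormalizing is algebraically
identical to the multi-cause update
$P(C_k \mid I_j) \propto P(I_j \mid C_k) P(C_k)$; the package implements
the latter (and property-tests the equivalence through
`va_complement_likelihood()`). Indicators reported **yes** are applied in
sequence; under conditional independence the order is irrelevant.

Three modelling decisions deserve emphasis:

* **Only "yes" responses update.** In VA data the absence of a reported
  symptom conflates "did not occur", "was not observed" and "was not
  asked", so a `N`/`.` response is treated as non-evidence by default.
  `update_negative = TRUE` switches on $(1 - P)$ updating for explicit
  `N` responses for users who trust their negatives.
* **Conditional independence** of indicators given cause is assumed —
  it is what licenses sequential multiplication. Clinically correlated
  symptom clusters (e.g. the cough/fever/weight-loss overlap between
  pulmonary TB and HIV/AIDS) violate it, and misattribution between such
  causes is the expected failure mode.
* **Log-space accumulation.** Products of up to ~100 probabilities
  underflow double precision; updates are summed as logarithms and
  renormalized with the max-shift trick. A zero entry in the base
  contributes a large negative sentinel rather than $-\infty$, so a
  single impossible indicator annihilates a cause without generating
  NaNs; a case in which *every* cause is annihilated is flagged
  uninterpretable and reported indeterminate rather than aborting the
  cohort run.

### Prior adjustment for local prevalence

The prior can be adapted to local malaria and HIV/AIDS epidemiology:
each disease is declared `high` or `low` prevalence and the affected
causes' priors are scaled (defaults: high keeps the prior, low multiplies
it by 0.1) before renormalization — see `va_prevalence()`. The default
configuration, `malaria = "low", hiv = "high"`, describes an urban
East-African population where parasitological malaria prevalence is
below 1% while adult HIV prevalence exceeds 10%. The 0.1 multiplier is a
package convention (one order of magnitude of down-weighting);
both multipliers and the affected-cause lists are configurable.

### Reporting thresholds

From the posterior the engine reports at most three causes with
likelihoods in percent. Two thresholds control the reduction, chosen to
reproduce the qualitative 1–3-causes-or-indeterminate behaviour of
fielded VA interpreters:

* `tau_top = 0.4`: no assignment at all (indeterminate) unless the
  leading cause reaches posterior 0.4;
* `tau_rel = 0.5`: secondary causes are reported only if their posterior
  is at least half the leading cause's.

Ties are broken by cause order in the dictionary, making the whole
engine deterministic. Both thresholds are arguments of
`va_interpret()`/`va_select_causes()`.

## Cause dictionaries and harmonization

The engine's 27-cause dictionary and the physicians' 60-code abridged
ICD-10-style list shipped in `inst/extdata/` are reconstructions built
from the causes a comparative VA study would name (eclampsia and the
haemorrhages collapsing into one maternity-related group; rabies,
tetanus and typhoid into other acute/infectious; kidney disease and the
cancers into noncommunicable/chronic; malaria, meningitis, measles
retained stand-alone). Both are plain `source_code,group` CSVs and fully
user-replaceable; the analysis logic, not the dictionary, is what the
package embodies. Each maps onto the same 14 broad groups
(`va_cause_groups()`). Thirteen of these are the conventional named
groups; the fourteenth, `other_unspecified`, absorbs residual and
ill-defined codes present in any practical code list. `"indeterminate"`
is deliberately *not* one of the 14: it is a statement about the
evidence, not a cause, and is carried as a pass-through 15th category so
that cohort counts always reconcile.

`va_harmonize()` reduces ranked assignments to one group per case at a
chosen rank; an unmapped code is always an error naming the code, never
a silent drop.

## Agreement statistics

`va_cross_tabulate()` builds the square contingency table;
`va_percent_agreement()` reports the diagonal fraction, optionally after
removing the indeterminate row and column (the sensitivity analysis
restricted to deaths where both methods committed). `va_kappa()`
computes unweighted multi-category Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$, with the asymptotic large-sample
(Fleiss–Cohen–Everitt) standard error and a symmetric
$\kappa \pm 1.96\,\mathrm{SE}$ interval. Unweighted kappa is the right
match for a single-kappa-per-stratum comparison; weighted variants are
out of scope. Sensitivity/specificity against physician review are
deliberately absent: physician review is not a gold standard, and the
package follows the field in reporting agreement, not accuracy against
either method.

`va_rank_agreement()` repeats the comparison against the model's
second- or third-ranked cause on the subset of deaths holding that many
causes — the natural question when one method returns ranked lists and
the other a single code.

## CSMF analysis

`va_csmf()` tabulates counts and fractions per group. Two denominator
conventions exist because both appear in practice: `all_cases` (default)
keeps indeterminate as an explicit category so fractions sum to 1 over
the stratum; `determined_only` drops it from the denominator, which is
the comparable scale when a reference distribution (such as a synthetic
truth) has no indeterminate mass. `va_rollup()` aggregates the 14 groups
into the four major categories (infectious, noncommunicable, injuries,
maternal/perinatal/nutrition); `other_unspecified` rolls up with
noncommunicable as the residual non-infectious, non-external burden.

`va_compare_csmf()` adds the CSMF accuracy summary
$1 - \sum_g |a_g - b_g| \,/\, 2(1 - \min_g b_g)$ — a community-standard
extension, not part of the original comparison design — which is 1 iff
the two distributions coincide and is used here as the synthetic
recovery criterion.

## The synthetic study design

Real VA series and expert probability bases are confidential or
unpublished, so validation runs on synthetic cohorts whose truth is
known. The generator deliberately matches the engine's generative
assumptions (categorical cause, conditionally independent Bernoulli
indicators) — that is the point: it isolates the pipeline's correctness
from model misspecification. What it emulates, and what not:

* **Cohort template.** Defaults mirror an eight-year urban surveillance
  series: 1,823 deaths, 31.4% under five (of which a fifth neonatal),
  4.6% aged 5–17, 64% adult; male excess (56%) and a two-site 66/34
  split as cosmetic metadata. The default true CSMF over the 27 causes
  puts ~58% of deaths on infectious causes (HIV/AIDS, pneumonia/sepsis
  and TB leading), 14% each on noncommunicable causes and injuries, and
  the remainder on maternal/perinatal/nutritional and unspecified causes
  — the burden profile of a poor urban population with high HIV
  prevalence.
* **Probability base.** `va_simulate_probbase()` gives each cause a
  signature subset of indicators (every indicator informative for
  exactly one cause) elevated to
  `base_rate + informativeness (1 - base_rate)` over a background
  `base_rate`. Defaults 0.9 and 0.05 make a strongly informative base:
  ~4 signature indicators per cause at 0.905 against a 5% background.
  As informativeness tends to 0 the posterior collapses to the prior.
* **Missingness.** Responses are masked to `.` at 10% by default.
  Injury-cause deaths get `missingness + 0.6 (1 - missingness)` ≈ 64%
  masking, emulating the emptiness of the structured section for deaths
  whose information lives in the narrative. The visible consequence —
  reproduced in every default run — is that the engine's indeterminates
  are dominated by injury deaths.
* **Physician panel.** Three independent coders each assign the true
  cause with probability θ (default 0.7), otherwise an error from a
  confusion kernel (uniform over the other causes unless supplied). Any
  cause held by ≥2 coders is final; when all three differ, a consensus
  meeting succeeds with probability γ (default 0.8) and picks uniformly
  among the three proposals, else the death is indeterminate. The
  single-Bernoulli consensus meeting is the simplest abstraction of a
  process no study describes mechanistically; θ and γ are free
  simulation parameters, not estimates of any real panel. The
  indeterminate rate has the closed form
  $(1-\gamma)\,P(\text{all three differ})$, which the tests verify.
* **Not emulated:** narrative text, recall decay with interview delay,
  inter-coder correlation, and real symptom correlation structure. A
  pairwise-dependence injection option was considered and left out of
  the default design; passing tests therefore demonstrate pipeline
  correctness under the model's own assumptions, *not* robustness of
  the engine to misspecified real data.

All randomness flows from one master seed; per-stage seeds are derived
deterministically (and kept below $2^{31}$), so a fixed configuration
reproduces byte-identical cohorts and reports.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle rather
than against itself:

* posterior vs. exhaustive joint-probability enumeration
  $P(\text{cause}, \text{pattern})/P(\text{pattern})$ on random bases of
  ≤4 causes × ≤6 indicators (200 instances, tolerance $10^{-9}$);
* single-indicator updates vs. the two-hypothesis Bayes formula (1,000
  draws);
* kappa vs. an independent margin-product implementation on 1,000 random
  tables (and frozen cross-checks of the standard error against an
  external statistical library);
* the 2-of-3 rule vs. exhaustive enumeration of all 27 coder patterns;
* CSMF recovery: at n = 2,000, informativeness 0.9, missingness 0.1 and
  a uniform engine prior (so recovery is driven by the indicators, not
  the prior), the engine's determined-only CSMF attains accuracy ≥ 0.90
  against the truth, and panel-vs-engine kappa rises monotonically in
  coder accuracy θ ∈ {0.3, 0.6, 0.9};
* an end-to-end run of the full 1,823-case template whose stratified
  report must reconcile to cohort totals.

These sizes keep the whole suite under a minute while leaving the
Monte-Carlo assertions (law-of-total-probability indicator prevalence at
n = 5,000 within 3 SDs; panel indeterminate rate at n = 6,000) with
comfortable power.

## Degenerate inputs and numeric conventions

* Posterior normalization is asserted to $10^{-9}$ everywhere.
* A prior with $P(C_k) = 1$ makes the complement likelihood undefined
  (division by $1 - P(C_k)$): domain error.
* Kappa is undefined when expected agreement $p_e = 1$ (all margin mass
  in one category) and on empty tables: errors, not NaN.
* Percent agreement after excluding indeterminates errors if no cases
  remain.
* An all-zero indicator row in a probability base is rejected at
  validation: such an indicator could never be observed under any cause.
* Likelihood ties at selection are broken by dictionary order, so
  reported likelihoods are non-increasing (not strictly decreasing) in
  rank.

## Known limitations

* The default dictionaries are reconstructions; users comparing real
  cohorts should supply their study's own code lists and mapping CSVs.
* The engine shares its generative model with the simulator, so synthetic
  performance is an upper bound on real-data performance.
* The kappa interval is the symmetric large-sample approximation; exact
  or bootstrap intervals are not provided.
* Narrative text is outside the model entirely: causes whose evidence is
  narrative-borne (injuries above all) will be under-determined, and the
  package reproduces exactly that behaviour.
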