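---
title: "Identifying team-based primary care practices and modelling diabetes care quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying team-based primary care practices and modelling diabetes care quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcteams)
```

## The problem

Administrative claims do not record which providers work together as a
practice, yet practice organisation — in particular whether primary care
physicians (PCPs) work alone or in teams with nurse practitioners (NPs) and
physician assistants (PAs) — is exactly the exposure of interest when
comparing the quality of chronic-disease care. `pcteams` implements a
claims-only workflow that (1) reconstructs practices from patient-sharing
networks, (2) classifies them into four team compositions, (3) builds an
attributed cohort of older diabetic patients, (4) computes claims-based
quality measures, and (5) contrasts team types with practice-clustered mixed
models. Because the real inputs for such studies are restricted, the package
ships a seeded synthetic claims generator with known ground truth, so every
stage is verifiable end to end.

## Practice identification from patient sharing

Within each service area, two primary-care providers are linked when at
least 30 distinct patients have at least one office-visit claim
(CPT 99201–99205, 99211–99215) from each of them; the edge weight is that
shared-patient count. Primary-care providers are CMS specialties 01, 08, 11
and 38, plus NPs (50) and PAs (97) carrying a primary-care taxonomy flag.
The weighted graph is clustered with Walktrap (random-walk agglomeration,
walk length 4, via `igraph`), cut at the maximum-modularity merge level.
Newman's weighted modularity

$$Q = \sum_c \left[ \frac{w_{in}(c)}{W} - \left( \frac{s(c)}{2W} \right)^2 \right]$$

is implemented directly in the package (`modularity_q()`) and cross-checked
in the tests against both a brute-force double-sum oracle and
`igraph::modularity()`. An area contributes practices only when its
partition reaches $Q \ge 0.4$; the boundary is inclusive (the gate is
configurable). Surviving clusters are then filtered in a fixed order —
solo-provider clusters, clusters sharing a provider with another cluster,
compositions outside the four team types, and finally practices with fewer
than 20 attributed diabetic patients — with the first failing reason
recorded. Weighted edges and weighted modularity are the default because the
shared-patient count carries the tie strength; an unweighted mode is
available (`weighted = FALSE`) since the choice is not determined by the
workflow itself.

Team type is a function of the member specialty multiset only: `PCP`
(physician specialties exclusively), `PCP_NP`, `PCP_NP_PA`, `PCP_PA`;
anything else (e.g. NP-only clusters) is `other` and excluded.

## Cohort construction

Patients are attributed to a practice by at least two office visits to its
providers during the measure year; patients qualifying at two or more
practices are excluded. The eligibility cascade then applies, first-fail
wins, in the narrative order of the study design: complete two-year
enrollment, no Medicare Advantage, alive through the measure year, age 66
or older on January 1 of the measure year (the birthday boundary is
inclusive), no long-term-care nursing facility use (a claim with CPT
99304–99310, 99315, 99316 or 99318 not billed by a skilled nursing
facility), and known rural/urban residence. Attribution against the final
practice list is resolved in two passes because the practice-size floor
depends on attribution itself: practices are gated and classified first,
patients attributed, and the under-20-patient practices then leave the study
together with their patients.

## Quality measures

* **Process flags** — eye examination, HbA1c testing and nephropathy
  monitoring are flagged by at least one claim matching the corresponding
  code set; specialist contact (endocrinology, cardiology, nephrology)
  requires an office-visit or consultation code (99201–99205, 99211–99215,
  99241–99245) billed by a provider of that specialty. Code sets are
  configuration, not code: the shipped defaults are small synthetic
  stand-ins, because the real HEDIS/NDC value sets and the AHRQ prevention
  quality indicator logic are licensing-restricted. A disabled (empty) code
  set yields `NA`, never `FALSE`.
* **Continuity** — the Modified Continuity Index from $N$ visits and $k$
  distinct providers, in the normalised form
  $\mathrm{MMCI} = \frac{1 - k/(N+0.1)}{1 - 1/(N+0.1)}$, which approaches
  the documented 0–1 endpoints; $N=1$ returns 1 by convention. The
  unnormalised variant $1 - k/(N+0.1)$ sits behind
  `normalized = FALSE` because the index is cited in both forms in the
  applied literature. It is computed at three provider levels: any
  provider, any primary-care provider, and the patient's own practice.
* **Adherence** — proportion of days covered (PDC) for antidiabetic fills:
  a fill of $s$ days supply covers the closed interval
  $[\text{fill date}, \text{fill date}+s-1]$; overlapping intervals are
  merged so each day counts once; the denominator starts at the later of
  the window start and the diabetes diagnosis date. PDC is reported for
  patients with at least one antidiabetic fill.
* **Utilization** — any ED visit (inpatient stay with positive ED charge,
  or outpatient facility claim with revenue code 0450–0459 or 0981) and any
  potentially preventable hospitalization (inpatient stay bearing a
  diagnosis code from the configured ambulatory-care-sensitive list).

## Statistical models

Covariate balance across the four team types is summarised by the maximum
absolute standardized mean difference over all six pairwise comparisons,
with 0.1 as the conventional meaningfulness threshold. Continuous variables
use $|m_a-m_b|/\sqrt{(s_a^2+s_b^2)/2}$, binary variables the proportion
version, and multi-level categorical variables the Yang–Dalton generalized
(Mahalanobis-type) form over the first $L-1$ levels — chosen because the
workflow needs a single scalar per multi-level covariate and this is the
standard generalisation.

Outcome models are random-intercept GLMMs with one Gaussian intercept per
practice, fitted with `lme4`: binomial-logit via adaptive Gauss–Hermite
quadrature (7 points by default; the tests verify the marginal
log-likelihood against brute-force numeric integration to $10^{-6}$),
normal-identity via REML, and negative-binomial log-link for visit counts
(Laplace approximation — `glmer.nb` does not support higher-order
quadrature). Contrasts are reported against the PCP-only reference group as
Wald-interval odds ratios on the exponentiated link scale; adjusted means
for continuous and count outcomes come from `emmeans`. Convergence
diagnostics are surfaced in the fit object (`converged`,
`convergence_messages`); a non-converged fit refuses to yield an ICC.

The intraclass correlation — the practice share of outcome variance — uses
the family-appropriate decomposition: $\sigma^2_b/(\sigma^2_b+\sigma^2_e)$
for normal outcomes, the latent-scale $\sigma^2_b/(\sigma^2_b+\pi^2/3)$ for
binomial-logit (the conventional reading of "proportion of variance" for
logistic models), and for the negative binomial a latent-scale form with a
log-normal unit-level variance approximation
$\ln(1 + 1/\mu + 1/\theta)$, overridable via `unit_variance`. The scale is
recorded in `scale_note`.

## The synthetic generator

`sim_config()` defines the study conditions; `simulate_claims()` realises
them deterministically (per-table child seeds derived from one master seed
by fixed offsets). The generator plants: practices of 3–8 providers in the
four team compositions; 60 diabetic patients per practice; office visits
over a two-year window with a 92% chance of staying in the home practice,
2% of visiting a foreign practice in the same area, and the remainder going
to area specialists (which generates the specialist-contact measures);
binary care measures drawn from
$\operatorname{logit}(p) = \operatorname{logit}(\text{base}) +
\text{team effect} + b_{\text{practice}} + x^\top\beta$
with $b \sim N(0, 0.5^2)$ and small age/sex/dual-eligibility effects;
antidiabetic refill sequences whose supply and gap distributions imply a
mean PDC near 0.79; and eligibility flaws (enrollment gaps, Medicare
Advantage, deaths, under-66 ages, LTC claims, unknown rurality) at low
rates so the cascade is exercised. Baseline rates and team effects default
to the magnitudes reported for team-based diabetes care (e.g. eye-exam odds
ratios of roughly 1.04–1.10 for teams with NPs or PAs).

Two defaults are deliberate desk-scale choices rather than attempts at
realism. First, within-practice visits pick a provider uniformly
(`usual_provider_weight = 0`): with only 60 patients per practice, a
concentrated visit pattern would starve pairwise shared-patient counts
below the 30-patient edge threshold and no network could be detected at
any clustering quality. The cost is that simulated continuity indices
(own-practice MMCI around 0.6) sit below the 0.85–0.9 typical of real
claims, where panels of thousands of patients allow both concentration and
dense sharing. Second, the expected 12 office visits per patient per year
refers to all primary-care office visits and matches overall visit volumes
in older diabetic populations, but the split across providers is flatter
than reality for the same reason. Passing tests therefore demonstrate that
the machinery recovers planted structure under these conditions, not that
real networks are this clean: real patient-sharing graphs have hub
providers, cross-area commuting and coding noise the generator does not
emulate.

## Numerical and design notes

* Determinism: identical configuration (including seed) yields
  byte-identical bundle tables and pipeline CSVs; the acceptance suite
  checks this with file hashes.
* The modularity of an edgeless graph is undefined (`NA`) and fails the
  gate; isolated providers form singleton clusters and are subsequently
  dropped by the solo-provider filter.
* Ages use the birthday rule (completed calendar years), so a 66th birthday
  exactly on the index date is included.
* Day counting for PDC uses closed integer date intervals; merging treats
  back-to-back intervals (gap 0) as contiguous coverage.
* The Walktrap tie-breaking order is whatever `igraph`'s deterministic
  implementation produces; runs are reproducible but the order is not a
  package-level contract.
* Problem sizes in the shipped analysis scripts and tests (10 areas × 10
  practices × 60 patients; 50 Monte-Carlo replicates at 200 practices ×
  100 patients for the coverage study) were chosen as the smallest designs
  at which the structural and statistical claims are sharply testable.

## Known limitations

* The preventable-hospitalization flag is diagnosis-list membership, not
  the full AHRQ indicator logic with its exclusion rules; the interface
  accepts richer code sets but not rule programs.
* Drug exposure is modelled at the drug-class level; there is no NDC
  mapping.
* Practice-level covariates (NP scope-of-practice regulation, ACO
  affiliation) are carried as synthetic attributes only and are not
  derived from any external roster.
* Communities are hard partitions: overlapping practice membership is
  excluded by design (cross-practice providers void their clusters).
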