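---
title: "Disease-driven multimorbidity clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-driven multimorbidity clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

People with eczema or asthma accumulate other diagnoses — allergic and
non-allergic — at rates that are poorly characterised. A disease-driven way
to study this is to cluster *diagnostic categories* rather than patients:
for every pair of chapters of a morbidity coding system (here the 19
alphabetic Read chapters A–U, skipping I and O), estimate how strongly the
two chapters co-occur within individuals, and then build networks and
dendrograms of chapters from those pairwise co-occurrence strengths,
stratified by age, sex and exposure (eczema or asthma) status. Clusters
defined this way have a direct clinical reading: a chapter cluster is a set
of body systems whose conditions co-occur in the same people with at least
some stated probability.

`morbclust` implements this pipeline end to end, together with a synthetic
electronic-health-record (EHR) generator that supplies inputs with the
statistical structure the method assumes, since real UK primary-care
extracts of this kind are licensed and cannot be redistributed.

## The co-occurrence model

The similarity between chapters $c_1$ and $c_2$ is the **Jaccard index**:
the probability that a person has first records in *both* chapters given a
record in *at least one*,

$$J(c_1, c_2) = \frac{|c_1 \cap c_2|}{|c_1 \cup c_2|}.$$

Rather than using the raw proportion, the index is modelled so it can be
standardized to populations of clinical interest. For each pair we restrict
to the union population (anyone with a record in either chapter — the
*union restriction*, which stops large never-affected populations from
washing out associations) and fit a random-intercept logistic regression

$$\mathrm{logit}\, P(y_i = 1) =
  \beta_0 + \beta_f f_i + \beta_a a_i + \beta_s s_i + \beta_x x_i + u_{p(i)},
  \qquad u_p \sim N(0, \sigma_u^2),$$

where $y_i$ indicates first records in both chapters, $f_i$ is years of
followup remaining after the first chapter record, $a_i$ the age at that
record, $s_i$ sex, $x_i$ the exposure flag (eczema or asthma, depending on
the condition analysed) and $u_p$ a general-practice random intercept
absorbing practice-level recording and socioeconomic differences. One model
is fitted per pair per condition, with exposure as a covariate — so the 19
chapters yield 171 models per condition.

When a person has records in both chapters, the covariates are taken at the
**earlier** of the two first records. This is the only definition that also
applies to single-chapter members of the union, so it keeps the covariates
defined on every row; its side effect is discussed under *Null models and
selection* below.

Predicted indices are evaluated at **standardized profiles**: age at first
record 18 or 50 years (chosen for clinical interest), each sex, exposed and
unexposed, five years of followup (one and ten as sensitivity), always at
an *average practice* ($u = 0$). Two conditions × two statuses × two sexes ×
two ages give the 16 primary strata. Profiles deliberately condition on the
practice effect rather than integrating over it: the target is a typical
practice, not a population-averaged probability.

## Networks and hierarchical clusters

Each stratum's predicted indices fill a symmetric $19 \times 19$ matrix;
the **Jaccard distance** is $1 - J$. Two summaries are derived:

* **Networks.** An undirected graph over all 19 chapters with an edge
  wherever $J \ge 0.30$ — a 30%+ probability of co-occurrence within the
  followup window, chosen as a clinically meaningful risk. The boundary is
  inclusive, and isolated chapters are kept so every stratum shares a fixed
  node layout.
* **Clusters.** Complete-linkage agglomerative clustering of the distance
  matrix, cut strictly below distance $0.70$ (i.e. co-occurrence
  probability strictly above 30%). Under complete linkage the cut is a
  diameter bound: every two chapters in a cluster co-occur with more than
  30% probability. Ward linkage (Lance–Williams update on squared
  distances) is available as a sensitivity analysis; the package reports
  the Rand agreement between the two partitions, with Ward cut to the same
  number of clusters since its heights live on a different scale.

Chapter L (pregnancy/childbirth/puerperium) can only be recorded for
women. Pairs involving L are fitted on women only with the sex covariate
dropped; in male strata every L cell is flagged, carries distance 1, and L
is edgeless.

## Estimation and numerical choices

* Maximum likelihood via adaptive Gauss–Hermite quadrature with 15 nodes
  (through `lme4::glmer`), adequate for a single scalar random effect.
  Tests cross-check the reported marginal likelihood against brute-force
  numerical integration of the practice intercept on a small dataset.
* Continuous covariates (followup, age) are standardized internally for the
  optimizer and estimates are back-transformed to the per-year scale, as is
  the fixed-effect covariance (used for optional delta-method standard
  errors — a diagnostic; the analysis reports point predictions only, and
  no hypothesis tests are performed anywhere in the pipeline).
* $\hat\sigma_u$ below $10^{-4}$ is reported as exactly 0; boundary fits are
  expected when practices are homogeneous and are not an error.
* Pairs with union below 50, or fewer than 10 persons in either outcome
  class (configurable), are *flagged and excluded* rather than imputed;
  flagged cells carry distance 1 and contribute no edge. A constant outcome
  is a precondition error.
* Agglomeration uses deterministic tie-breaking (the earliest cluster pair
  in scan order), so identical inputs give identical trees; dendrograms
  serialise to Newick with midpoint height-splitting (two leaves merged at
  0.4 give `(A:0.2,B:0.2);`), making cophenetic distances of the parsed
  tree equal the merge heights.
* All CSV exports use fixed 6-decimal formatting, so reruns with the same
  configuration and seed are byte-identical; a JSON manifest records the
  configuration, seed and per-file checksums.

## The synthetic EHR generator

The generator emulates the features the analysis relies on, with defaults
fixed once as the package's study conditions:

* **Structure.** Persons nested in general practices (25 practices × 120
  persons by default) with a practice random intercept (SD 0.3 on the
  log-odds scale); 55% female; adult entry ages uniform on [18, 80] with a
  20-year observation window.
* **Chapter prevalence.** Per-chapter baseline log-odds chosen so lifetime
  recording probabilities resemble a general primary-care population
  (near-universal respiratory/musculoskeletal recording, rare perinatal and
  congenital chapters); log-odds increase 0.02 per year of entry age
  (−0.05 for pregnancy), a 0.1 female contrast, and a 0.4 shift per
  exposure carried.
* **Dependence.** A Gaussian copula on latent liabilities with
  equicorrelation 0.3 (or a full correlation matrix). The copula leaves
  marginal prevalences exactly logistic while giving one dependence knob;
  empirical pairwise Jaccard indices increase monotonically in it.
* **Exposures.** Eczema and asthma are drawn independently at 15%
  prevalence each. Exposed persons receive exactly the records the case
  algorithms require — one eczema diagnosis plus two therapy records on
  distinct calendar days, or one asthma morbidity code — plus
  Poisson-distributed extras, so algorithm edge cases (same-day therapies,
  minimal records) occur in data.
* **Event times.** One morbidity event per occurring chapter at an age
  uniform over the observation window — the least-informative choice, which
  still exercises the age and followup covariates.

What it does **not** emulate: Read-term-level coding, consultation
frequency, deprivation structure, calendar-time and Covid-era recording
effects, registration-quality inclusion filters, or correlation between the
two exposures. Passing tests therefore demonstrate correctness of the
*method* on data satisfying its assumptions, not fidelity of any particular
real-world cluster.

A second, direct simulator (`generate_pair_glmm_dataset`) draws rows
straight from the pair-level regression with known coefficients and is the
ground truth for parameter-recovery tests: with 50 practices × 200 rows the
slope, sex, exposure and variance parameters are recovered within tight
tolerances in nearly all replicates. The intercept is an exception worth
recording: its sampling SD under that design is ≈ 0.12, because the
practice-mean ambiguity ($\sigma_u/\sqrt{50} \approx 0.07$) and the
extrapolation of age and followup to zero dominate; recovery-rate targets
tighter than that are unattainable by any consistent estimator at this
sample size.

## Null models and selection

One subtlety deserves emphasis. In the population generator, *even with all
covariate effects set to zero*, followup is informative about the outcome:
a person with records in both chapters dates their covariates from the
earlier of two first records, which is stochastically earlier than the
single record of a one-chapter person, leaving more residual followup. The
conditional prediction at a fixed short followup therefore sits below the
marginal Jaccard index — by construction, not by bug. Null-consistency
checks (prediction equals the raw outcome proportion at any profile) are
accordingly run on the direct simulator, where covariates are drawn
independently of the outcome under a null truth; the closed-form check that
independent chapters at prevalence one-half give a Jaccard index of
$p^2/(2p - p^2) = 1/3$ is run on the population generator, where it
concerns the margins only.

## Cohorts, matching and summaries

The case algorithms mirror validated primary-care definitions: eczema
requires at least one diagnostic record plus two therapy records on
separate days (ages floored to whole days; same-day duplicates count once);
asthma requires any asthma morbidity record ever. Both are monotone in the
record set. Each exposed person is matched to up to five controls sampled
uniformly *with replacement* among pool members with the same practice and
sex and entry age within 5 years; persons without eligible controls get an
empty match set and are logged. Matching is recorded for cohort description
(and its table-style summary, with integer percentages for chapter
prevalences and one-decimal percentages for cohort overlaps), but the
regressions deliberately break matching — the union restriction removes
matched members asymmetrically — and adjust for the matching factors
directly. Entry age stands in for age at matching.

## Problem sizes

The shipped test-suite and the acceptance script size their simulations to
the smallest scales at which the checks are statistically meaningful:
parameter recovery at 50 practices × 200 rows over 20 replicates; null
checks at n = 20{,}000; the full 19-chapter, two-condition pipeline at 25
practices × 120 persons with followups 1/5/10 and both linkages; clustering
oracles at up to 7 leaves over 100 random matrices. These sizes are the
package's own trade-off between Monte-Carlo precision and runtime.

## Known limitations

* Chapter-level (not term-level) analysis; the Jaccard index compares
  poorly across very different prevalences, so a single 30% threshold may
  be conservative for rare-versus-common chapter pairs.
* Temporal direction of co-occurrence is deliberately ignored; no causal
  reading is supported.
* Followup and age enter linearly on the log-odds scale; no interactions.
* Predictions condition on an average practice; population-averaged
  (marginal) predictions are out of scope.
* The synthetic generator's realism limits are listed above; real-data
  cluster memberships cannot be reproduced from it and are not a target.
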