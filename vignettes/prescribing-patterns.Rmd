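---
title: "Detecting prescribing patterns from EHR mention data"
author: "prescreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prescribing patterns from EHR mention data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prescreg)
```

## The problem

Health-care institutions rarely have a computable record of *why* each
medication was prescribed.  Conditions and medications appear in
outpatient notes, are extracted and normalized by an NLP pipeline, and end
up as unlinked per-visit mentions.  `prescreg` infers, at the population
level, which medications are used to treat an index condition, and which
comorbidities push prescribers toward one drug class rather than another.
Everything downstream of NLP extraction is in scope; the extraction
itself is not — the package consumes a long-format *mention table* with
one row per (patient, visit, concept), where a concept is a normalized
condition or medication identifier.

## The case/control model

Let $Y_i = 1$ if patient $i$ has ever had the index condition and $0$
otherwise, and let $x_i$ be binary indicators of every other condition and
medication mentioned at one selected visit.  The association model is the
main-effects logistic regression

$$\Pr(Y = 1 \mid X = x) =
  \frac{\exp(\beta_0 + \beta^\top x)}{1 + \exp(\beta_0 + \beta^\top x)},$$

where each $\beta_j$ is the log of the *adjusted* odds ratio for concept
$j$, adjusted for every other selected concept.  No interaction terms are
used: the working assumption is that each concept shifts the log odds of
case status by the same amount regardless of the rest of the record.  The
adjustment is the point of the method — a naive marginal 2x2 tabulation
(the built-in baseline) will flag any drug whose indication merely
co-occurs with the index condition.

Fitting proceeds in four steps:

1. **Cohort construction** (`build_case_control()`).  Cases are patients
   with at least one visit mentioning the index condition, controls the
   rest.  One visit is sampled uniformly per patient (for cases, among
   visits mentioning the condition) and features are the concepts
   mentioned at that visit, excluding the index condition itself.  The
   per-visit feature window is the default because per-visit quantities
   are the operative summaries of such cohorts; `feature_window =
   "history"` switches to the full record.
2. **Screening** (`screen_features()`).  Pearson correlation of each
   column with the labels; the two-sided p-value comes from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and columns
   with $p < 0.05$ are kept.  The threshold is a dimension-reduction
   device and is deliberately not multiplicity-adjusted.  Perfectly
   correlated columns (duplicate vocabulary labels for one concept) are
   collapsed to one representative.
3. **LASSO selection** (`lasso_select()`).  L1-penalized logistic
   regression over 100 log-spaced penalties down to $10^{-4}$ of the null
   penalty, with 5-fold cross-validation stratified by label.  The chosen
   penalty is the largest whose mean out-of-fold deviance is within one
   standard error of the minimum (the 1-SE rule), which prefers sparser
   models.  The binary indicators are left unstandardized by default so
   the penalty treats all columns on the same 0/1 scale; `standardize =
   TRUE` restores the common alternative.
4. **Refit and ranking** (`fit_final_logistic()`).  Ordinary
   maximum-likelihood logistic regression on the selected columns yields
   adjusted odds ratios and two-sided Wald p-values (a likelihood-ratio
   option was considered unnecessary for per-coefficient reporting),
   ranked by p-value with odds-ratio tie-breaks; p-values below double
   precision print as 0 and the tie-break does the ordering.
   Benjamini–Hochberg adjusted p-values support discovery counting at a
   fixed false discovery rate.

`drug_association()` chains the four steps and returns a classed model
object with `print`, `summary`, `coef`, `predict`, `plot` (the CV
deviance path) and `residuals` methods.

Two caveats are inherent to the design and are not corrected for: the
step-4 p-values are computed on the same data used for selection, so they
inherit post-selection optimism; and one-visit sampling discards
information in longer histories.  Both are noted rather than fixed
because the procedure is meant as an institutional monitoring tool, not a
confirmatory analysis.

## The drug-class preference model

For the comparison among $K$ drug classes, the population is restricted
to patients with a visit mentioning both the index condition and a
class-mapped medication.  One such visit is drawn per patient and the
outcome is drawn uniformly among the distinct classes mentioned there (a
visit often mentions several classes; the multiplicity survives up to the
draw).  With comorbidity indicators $x$ (medications are excluded by
design), the model is the multinomial logit

$$\Pr(C = c \mid X = x) =
  \frac{\exp(\beta_{0c} + \beta_c^\top x)}
       {\sum_{k=1}^{K}\exp(\beta_{0k} + \beta_k^\top x)}.$$

Per-class coefficients are identified only up to a per-feature common
shift, so the package reports the symmetric sum-to-zero parameterization
(tagged in the model) and treats only pairwise differences as meaningful.
`interpret_pair()` returns $\exp(\beta_{ac} - \beta_{rc})$ — the factor by
which a comorbidity multiplies the odds of class $a$ over the reference
class.  For the published asthma coefficients (A2 blocker 0.018, beta
blocker −0.043) the difference is 0.061 and the factor $e^{0.061} = 1.06$:

```{r}
cf <- matrix(c(0.018, -0.043), nrow = 1,
             dimnames = list("asthma", c("A2Blocker", "Beta_Blocker")))
interpret_pair(cf, "asthma", "A2Blocker", "Beta_Blocker")
```

Because per-coefficient p-values are computationally expensive for
penalized multinomial fits, none are computed; comorbidities are ranked
by their *drop-out penalty* — the largest penalty at which they keep any
nonzero class coefficient along the path (`rank_comorbidities()`).  The
cross-validation and 1-SE machinery is the same code path as the binary
pipeline.  How many top comorbidities to report is a user parameter
(`top_n`, default 13).

## The tabulation baseline

`tabulate_medications()` forms, per medication, the 2x2 table of use
against case status, the sample cross-product odds ratio $ad/bc$ (zero
cells yield 0 or infinity with a flag; no continuity correction, the
conditional-MLE odds ratio is available as an option), and a two-sided
Fisher exact p — the sum of hypergeometric probabilities of tables, with
the observed margins, no more probable than the observed one (the most
common two-sided convention; probability ties are tolerated to about one
part in $10^7$).  Rankings break the abundant underflow-to-zero p ties by
odds ratio.

## The synthetic EHR generator

Real institutional EHR data cannot be redistributed, so the package ships
a generator (`sim_config()`, `generate_population()`) whose planted
structure makes every downstream stage testable:

* latent conditions drawn sequentially in config order, with directed
  comorbidity odds multipliers applied from already-drawn parents, so
  configured marginals stay interpretable;
* treatment medications drawn conditionally on conditions; for
  class-mapped treatments the patient receives a class medication with
  probability $1-\prod(1-p_m)$, the class from a multinomial logit whose
  baseline utility is the log of the class's summed prescribing
  probability plus the configured comorbidity log-odds shifts, and one
  medication within the class proportionally to its prescribing
  probability;
* background-noise medications independent of any condition;
* visit counts $1 + \mathrm{NegBin}(\text{size}=0.5,
  \mu=\text{mean}-1)$ — at least one visit each, standard deviation above
  the mean as in real clinic data;
* per-visit recording noise: every latent concept is mentioned at each
  visit independently with `recording_prob` (the same rate for
  conditions and medications, absent any reason to separate them).

Determinism is strict: the master seed spawns one RNG sub-stream per
patient, and every config block consumes a fixed number of uniforms per
patient (draws are made and discarded even when a gate is closed), so
editing one block leaves the rest of a patient's draws untouched.

The generator emulates presence/absence structure only.  It does not
model free text, negation or temporality, diagnosis codes, demographics,
onset dates, or informative visit timing, and recording noise is
independent across visits — so passing recovery tests here shows the
statistics behave as designed under the stated generative model, not that
the method is robust to NLP error or to confounding by variables the EHR
never records.

The study conditions used by the recovery test suite are fixed in code:
20,000 patients, an index condition at prevalence 0.30, three
comorbidities (prevalence 0.10–0.15, odds multiplier 4 given the index
condition), five true treatments with prescribing probabilities 0.60–0.85,
three confounder-only medications at 0.8, fifty noise medications at
0.02–0.05, mean 4 visits, recording probability 0.9.  The class-preference
suite uses 10,000 patients, two classes and a +1.0 log-odds asthma effect.
These sizes keep every property estimable (binomial standard errors well
below the asserted margins) at workstation run times; they are the
package's chosen reference conditions, not tuning knobs.

## Evaluation

`load_reference()` reads a medication–indication reference (the
high-precision-subset format: `medication_id,condition_id`);
`precision_at_k()` (default $k = 30$, mirroring the top-30 reading
protocol) and `discovery_report()` score a ranking against it.  Discovery
counting applies Benjamini–Hochberg at level $q$ to medication rows only
— conditions selected by the model are excluded because the protocol
counts drugs — and a zero-discovery report shows `NA`, never 0, to avoid
silently flattering the method.  On synthetic data, `truth_recovery()`
scores recall of planted treatments and counts confounder-only drugs in
the top $k$.

## Numerical and design choices

* **1-SE rule**: the penalty chosen is the largest with mean CV deviance
  within one standard error of the minimum mean CV deviance — the
  standard reading of the rule; the fold SE is the between-fold standard
  deviation divided by $\sqrt{K}$.
* **Folds** are stratified by outcome so no fold loses a class, and are
  deterministic given the seed.
* **Penalty grid**: glmnet's data-derived null penalty down to ratio
  `1e-4` over 100 points; the chosen penalty always sits on the grid.
* **Separation**: columns whose 2x2 table against the labels has an
  empty cell are flagged in the association table (their Wald statistics
  are unreliable); an error is raised only when the full model separates
  without any single flaggable column.
* **Degenerate inputs**: zero-variance columns are dropped before
  screening; designs with no cases, no controls, or fewer than two
  patients per arm error immediately; a single-feature penalized fit is
  padded internally with an all-zero column that can never be selected.
* **Underflow**: p-values below about `1e-308` are reported as 0; the
  documented odds-ratio tie-break keeps such rows ordered.
* **Minimum-count filters**: none beyond zero-variance removal — rarely
  mentioned drugs may simply fail selection, which is reported, not
  hidden.

## Known limitations

Control visits are sampled uniformly over each control's visits, with no
visit-type restriction and no case/control matching (deliberately out of
scope).  Whether a case's features should exclude visits before condition
onset is unresolved; the sampled visit always mentions the condition, so
onset is implicitly respected for cases.  The indication reference is
assumed pre-normalized to the mention vocabulary; no name-granularity
matching is attempted.
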