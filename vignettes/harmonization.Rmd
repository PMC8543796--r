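---
title: "Pre-statistical harmonization of multi-study item banks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-statistical harmonization of multi-study item banks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemharmony)
```

## The problem

Behavioral and psychiatric symptoms are measured with many instruments
(NPI and its variants, DEMQOL, Blessed, BOUP, depression screens, problem
behavior checklists), and pooling item-level data across studies that used
different instruments is a powerful way to gain power and generalizability.
Before any pooled latent-variable model can be fit, however, the items have
to be made *comparable*: the same construct may be coded yes/no in one study
and on a 0–3 severity scale in another, coded 1-based instead of 0-based,
coded in the opposite direction, stored with numeric missing-data sentinels
(96–99, −5), or administered only behind a screener question. Every one of
these differences, if left in the data, either biases a pooled model or
silently corrupts it.

`itemharmony` operationalizes this *pre-statistical harmonization* phase as
a deterministic, auditable pipeline: a crosswalk data model, a recoding
engine, an automated QC battery, and a per-study two-parameter logistic
(2PL) IRT check of configural invariance. The statistical co-calibration
that would follow (linking, factor-score estimation) is deliberately out of
scope: this package prepares and vets the inputs for that stage.

## The crosswalk

The central data structure is the crosswalk: one row per (construct, study)
pair, recording the study's source variable, instrument, question stem,
response options, declared missing codes, an optional gate variable (skip
pattern), a summary-score marker, and a *recode rule*. Recode rules use a
compact text grammar, e.g.

```
1->1;5->0;6,96,97,98,99->NA
```

which is total over the declared codes, maps to non-negative harmonized
scores starting at 0, and sends sentinels to the dedicated missing marker.
Missingness in memory is always `NA`, never a numeric code, so sentinel
pathology cannot be reintroduced downstream. Raw codes are integers by
contract; the documented instruments all use integer codes, and rejecting
anything else at parse time catches file corruption early.

The crosswalk is authored by people — judging that two differently worded
items measure the same construct is expert work — but everything *after*
that judgment is code: validation against the data (missing variables,
undeclared codes), recoding, exclusion, and model checks are deterministic
functions of the crosswalk plus the raw tables.

## Standardization

Harmonized items follow one polarity convention: higher = worse / more
severe. The standardization sequence is fixed:

1. recode (sentinel masking plus any reversal encoded in the crosswalk);
2. shift-to-zero for 1-based scales (guarded: shifting an already 0-based
   item is refused, so the shift can never be applied twice);
3. sparse-cell collapsing: an ordinal item with any non-zero category
   count below `min_cell` (default 5, the conventional small-cell
   criterion) is truncated to presence/absence — the 0 option is kept and
   scores ≥ 1 become 1;
4. optional dichotomization of all remaining ordinal items, the
   lowest-common-denominator coding required when the pooled analysis is a
   binary IRT model.

The fixed order makes runs reproducible and composes correctly: for a
4-option reversed 1-based scale, shift-then-reverse reproduces the map
`1→3, 2→2, 3→1, 4→0`. Every applied transform is written to an audit log
(study, construct, operation, parameters). Missing values only propagate;
no operation can decrease the number of missing entries, and the package
never imputes.

## The QC battery

Each check is a pure function emitting flags, not corrections — an
anti-correlated item *may* be substantively reversed, so changes require an
explicit crosswalk edit:

* **Sentinel codes** (`detect_missing_codes`): raw items whose maximum
  falls in [90, 100] or that contain negative values. Applied to raw codes
  only; harmonized ranges are small by construction, so the rule is never
  re-applied after recoding.
* **No variability** (`detect_no_variability`): non-missing min = max, or
  all missing. Constant items carry no information for a latent trait and
  are excluded.
* **Scale discrepancies** (`crosstab_ranges`): a construct whose observed
  (min, max) differs across the studies carrying it — differential scoring
  (0–3 vs 0/1) or 1-based coding.
* **Reverse-coding candidates** (`detect_reverse_candidates`): any item
  whose Pearson correlation with another item in the same study falls below
  −0.2. Pearson is used because it is defined for mixed binary/ordinal
  scores and matches a plain correlation-matrix workflow; correlations are
  pairwise-complete with a minimum overlap of 20 pairs (skip patterns
  create blockwise missingness, and tiny overlaps produce noise
  correlations). The rule is symmetric in a pair, so both the reversed item
  and its partners are flagged; the payload names the most negative partner
  and the pair count, and the curator decides which side to reverse. No
  significance screen is applied — the raw correlation and pair count are
  reported and judgment is left to the user.
* **Conditional items** (`exclude_conditional`): metadata-driven removal of
  every item with a declared gate. Severity/frequency follow-ups behind a
  presence screener duplicate the screener's information and inflate
  apparent reliability; gate cycles are a structural error.
* **Summary scores**: excluded by the `is_summary_score` marker, never
  inferred — identifying a column as a precomputed total is a documentation
  fact, not a statistical one.

## The per-study 2PL check

With harmonized binary items in hand, the package fits a 2PL IRT model in
each study separately — a configural-invariance check: the same
unidimensional structure should hold everywhere before pooling is
attempted. The item response function is

$$P(X_{ij} = 1 \mid \theta_i) = \frac{1}{1 + \exp(-a_j(\theta_i - b_j))}$$

with discrimination $a_j$ (analogous to a factor loading) and difficulty
$b_j$ (the trait level at which endorsement probability is 50%), and a
standard-normal prior on $\theta$.

Estimation is marginal maximum likelihood via EM over a fixed 41-node
Gauss–Hermite quadrature grid. The E-step computes each respondent's
posterior over the nodes (missing responses simply contribute nothing to
their item's likelihood term); the M-step solves one weighted logistic
regression per item by Newton steps with step-halving, which guarantees a
non-decreasing marginal log-likelihood trace — recorded in the result and
asserted in the tests to 1e-10. Convergence is declared when the
log-likelihood changes by less than `tol` (default 1e-6); `max_iter`
defaults to 500. The trait is oriented so that the mean discrimination is
positive. Standard errors come from the inverse cross-product of
per-respondent score vectors (the full 2J × 2J block), delta-methodized to
the (a, b) parameterization.

Two numerical guards matter in practice. Items with 0% or 100% endorsement
are rejected with a pointer to the QC filters rather than fitted (their
parameters are not identified). And discriminations are bounded at
`a_max = 3.5` by default: with few items and small n the likelihood can
send a slope to infinity (a Heywood case), and beyond slopes of about 4 the
41-node grid can no longer integrate the almost-step-shaped item response
function accurately. The bound binds only when the data carry essentially
no information about the slope, and it keeps the reported log-likelihood
quadrature-accurate to better than 1e-4 per respondent against a fine-grid
oracle. Ordinal items reaching the IRT stage are an error, not silently
dichotomized — the pipeline dichotomizes upstream, and silent coercion here
would hide an ordering bug.

## Limited-information fit statistics

The full 2^J response-pattern chi-square is degenerate at realistic sample
sizes, so fit is assessed on univariate and bivariate margins with an
M2-type quadratic form,

$$M_2 = n\,(p - \hat\pi)' C_2 (p - \hat\pi),$$

where $p$ stacks the J sample endorsement proportions and the J(J−1)/2
pairwise joint-endorsement proportions, $\hat\pi$ are the model-implied
values, and $C_2 = \Xi^{-1} - \Xi^{-1}\Delta(\Delta'\Xi^{-1}\Delta)^{-1}
\Delta'\Xi^{-1}$ with $\Xi$ the asymptotic covariance of the margins under
the model (unions of up to four item curves, computed by quadrature) and
$\Delta$ the Jacobian of the margins in the item parameters. Degrees of
freedom are $J + J(J-1)/2 - 2J$. From M2:

* RMSEA $= \sqrt{\max(M_2 - df, 0)/(df \cdot n)}$;
* CFI $= 1 - \max(M_2 - df, 0)/\max(M_2^{(b)} - df^{(b)}, 0)$, with mutual
  independence (free per-item thresholds, no trait) as the baseline — when
  the baseline itself fits, the ratio is 0/0 and CFI is reported as not
  computable;
* SRMR = root mean square of residual inter-item correlations (observed
  minus model-implied Pearson correlations of the binary items).

With missing data, margins are pairwise-complete and the effective n is the
median pairwise count — an approximation appropriate for the low,
unstructured missingness left after conditional exclusion.

Classification follows the conventional cutoffs: RMSEA < 0.05 excellent,
0.05–0.08 (inclusive) mediocre, above poor; CFI ≥ 0.90 good; SRMR < 0.08
good. Under the correctly specified model, the suite verifies M2 ≈ its df
and median RMSEA near 0 across replicates.

## Residual diagnostics and couplets

Local dependence — an item pair sharing association beyond the common trait
— is flagged from two views: residual correlations (observed minus
model-implied, threshold |r| > 0.3) and bivariate standardized residuals of
each pair's 2×2 observed-vs-expected table,
$z = (O - E)/\sqrt{n\pi(1-\pi)}$ per cell, summarized by the largest |z|
and thresholded at 3. Flagged pairs ("couplets") are reported for curator
action — exclude one item or model the residual covariance downstream;
estimating models with residual covariances or bifactor structure is out of
scope. A pairwise tetrachoric matrix (bivariate-normal ML on each 2×2
table, continuity correction 0.5 for zero cells) is available for
inspection of the latent-scale association structure.

## The synthetic generator

Restricted-access source data cannot ship with a toolkit, so the generator
is a first-class module: it produces multi-study banks with *known truth*
for every check. Responses come from the same latent-response mechanism the
models assume: $z = a\theta + \gamma u + \varepsilon$ with standard-logistic
$\varepsilon$, cut at thresholds $b + (m - k/2) \cdot 0.8$ — which yields
exactly the 2PL for binary items and a graded mechanism for ordinal ones.
Defects are applied *after* generation, so each has an exact truth record:
reversal flips raw codes, 1-based studies shift codes up, sentinels replace
a configured fraction of responses (defaults mirror the documented
dialects: 96–99 and −5, at 5%), gated follow-ups are blanked where the gate
is 0, constant items are overwritten, and couplet pairs share a specific
factor. The couplet loading is the *standardized* loading of that factor on
the latent-response scale (converted internally to a logit slope); at the
default 0.6 and n = 1000 the planted pair produces bivariate standardized
residuals comfortably above the flag threshold.

The generator emits the raw study tables, the curated crosswalk (recodes
that mask, shift, and un-reverse — the end state of a documentation
effort), the naive crosswalk (masking and shifting only — the state
*before* directionality review, on which the reverse screen must fire), and
the truth record.

The default bank (`default_bank_config`) is three studies of 1000
respondents, sixteen binary items with a ∈ [1, 2.5] and b ∈ [−1.5, 1.5],
one 4-level/binary scale discrepancy, and one planted defect of every
class. Real study sizes in this literature span roughly 60 to 14,000;
validation uses 500–4000 where each property is informative, large enough
for stable estimates and small enough that the whole suite runs in well
under a minute per property. What the generator does **not** emulate:
marginal distributions of real instruments, demographic structure, rater
effects, longitudinal drift, or informative missingness. Passing the suite
therefore shows the *machinery* is correct — detection rules recover
planted defects, the estimator recovers generating parameters — not that
any particular real pooling effort will fit well.

## Design choices made where the design was open

* **Order of operations** (mask → shift → reverse → truncate/collapse):
  reproduces the published worked recodes by composition and makes audit
  logs comparable across runs.
* **Pearson, not tetrachoric, for the reverse screen**: the screen runs on
  possibly mixed binary/ordinal data where tetrachorics are undefined, and
  a sign flag needs only the sign. Tetrachorics are reserved for
  latent-scale inspection at the IRT stage.
* **Thresholds in one place** (`pipeline_config`): reverse threshold −0.2,
  min_cell 5, overlap floor 20, residual thresholds 0.3 and 3, quadrature
  41 nodes, tolerance 1e-6.
* **Human-in-the-loop reversal and exclusion**: flags never rewrite the
  crosswalk.
* **Determinism as a contract**: two runs with equal inputs, config and
  seed produce byte-identical reports; the manifest records input digests
  so this is checkable.

## Known limitations

Ordinal items are ultimately dichotomized for the binary IRT stage, losing
granularity (a graded-response fit is a natural extension). The effective-n
convention for M2 under missingness is an approximation. The independence
baseline makes CFI undefined when items are mutually independent — reported
honestly as not computable rather than coerced. Summary-score detection is
metadata-driven only. And the package neither creates the expert judgment
embedded in a crosswalk nor replaces it; it makes that judgment auditable
and testable.
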