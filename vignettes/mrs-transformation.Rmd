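---
title: "Methods: the mRS-RS transformation and its evaluation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mRS-RS transformation and its evaluation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsrs)
```

## The problem

The modified Rankin Scale (mRS) is the standard ordinal measure of
functional disability after stroke (0 = no symptoms ... 5 = severe
disability, bedridden; 6 = death).  Administering it requires a trained
interviewer, so large stroke quality registers such as the Swedish
Riksstroke instead collect self-administered questionnaires at the
three-month follow-up.  A transformation algorithm (mRS-RS) maps seven of
those self-reported questions onto mRS grade bands, letting
questionnaire-based register research be compared with interview-based mRS
studies.  This package implements such a crosswalk as a data-driven rule
engine, together with everything needed to evaluate it: agreement
statistics, a conditional inference tree as a machine-learnt comparator,
and a synthetic cohort simulator (the real register data are
access-restricted, so the simulator is the package's test bed).

Grade 6 never occurs in this setting - deceased patients do not answer the
follow-up questionnaire - so the data model covers grades 0-5 and the
loader rejects grade 6 explicitly.

## The transformation rules

Each rule targets one grade band and combines a *disjunction block* (at
least one condition must hold; may be empty) with a *conjunction block*
(all conditions must hold).  The default rule set is:

| band | disjunction (any)                 | conjunction (all)          |
|------|-----------------------------------|----------------------------|
| 5    | -                                 | Q2=3, Q3=3, Q4=2, Q5=2     |
| 4    | Q3=3 or Q4=2 or Q5=2              | Q6=2, Q7=3                 |
| 3    | Q1=2 or Q2=2 or Q3 in {1,2}       | Q6=2                       |
| 0-2  | Q1 in {3,4} or Q6 in {1,2} or Q7 in {1,2} | Q2=1, Q3=1, Q4=1, Q5=1 |

Rules are data (`default_ruleset()`, YAML-loadable via `read_ruleset()`),
not code, so corrected codings or earlier algorithm generations can be
swapped in without touching the engine.

**Precedence.**  The source tabulation of these rules does not state an
evaluation order, and its clauses overlap: every answer vector satisfying
the band-5 rule also satisfies the band-4 rule (Q3=3 implies the band-4
disjunct, and such patients report unresolved problems and no return to
prior life).  We therefore evaluate severity-descending with
first-match-wins - the only order under which band 5 is reachable at all.
This is a documented design choice of the package, not a claim about the
original procedure; the rule file order is honoured as given, so users can
run sensitivity analyses with other precedences.

**Unclassified outcomes.**  Because the blocks combine OR and AND
conditions, part of the answer-code space satisfies no rule (e.g. a
respondent not living at home but otherwise fully independent).  Such
vectors yield `"unclassified"` rather than an error; this is exactly the
mechanism by which a real cohort shrinks to its analysable subset, and the
pipeline always reports the unclassified count next to the analysis
denominator.

**Code book.**  The register's authoritative answer wordings and code
assignments are not publicly available; the shipped code book
(`default_codebook()`, flagged `reconstructed`) is inverted from the codes
the rules use, with "Do not know" (and, for Q1, "Have no relatives/friends
or have no contact") as excluded codes.  Whether Q4 or Q6 carry a third
substantive category cannot be settled from public material; the
reconstruction keeps them binary plus the excluded code.  Users holding
the official code book can supply it as YAML, and rule validation enforces
that excluded codes never appear in rule conditions.

Missing answers are exclusion reasons, not imputation targets, mirroring
the complete-case inclusion criterion of register analyses of this kind.

## Agreement statistics

Classifier output is summarised against the interview-based reference mRS
with a severity-ordered confusion matrix (rows = true band), from which we
compute classification accuracy, the no-information rate (largest true-band
prevalence - the accuracy of always guessing the modal band), the
under/over-estimation split of the off-diagonal mass, and the
Fleiss-Cohen quadratic weighted kappa

$$K_w = \frac{P_{o,w} - P_{e,w}}{1 - P_{e,w}}, \qquad
  w_{ij} = 1 - \frac{(i-j)^2}{(k-1)^2},$$

with $P_{o,w} = \sum w_{ij} p_{ij}$ and
$P_{e,w} = \sum w_{ij}\, p_{i\cdot} p_{\cdot j}$.  Quadratic weights are
the appropriate choice for an ordinal scale: a one-band miss loses little
weight, an extreme miss loses all of it.

**Variance.**  No variance formula accompanies the published CIs, so the
package uses the classical large-sample variance of weighted kappa under
the alternative (Fleiss, Cohen & Everitt 1969), with a Wald interval
truncated to $[-1, 1]$.  The acceptance suite checks this empirically:
over 1000 cohorts of n = 500 drawn from a population with known
$K_w = 0.6$, the 95% interval covers the population value in about 93-94%
of replicates, inside the 95% ± 3 pp band expected of an asymptotic
interval at this n.

**Direction convention.**  "Over-estimated" means the assigned band
indicates *worse* disability than the reference (above the diagonal when
rows are the true bands in severity-ascending order).  The convention is
stated here because prose summaries of such tables are directionally
ambiguous.

**Interpretation bands.**  Landis-Koch labels follow the printed
inequalities (slight ≤ 0.20, fair 0.21-0.40, moderate 0.41-0.60,
substantial 0.61-0.80, almost perfect ≥ 0.81).  Values in the unprinted
gaps are rounded half-up to two decimals first, so 0.805 reads "almost
perfect" and 0.804 "substantial".

**Denominators.**  Rule-based mapping is evaluated on classified records
only; the tree classifies everything after exclusions.  The two
procedures therefore have different analysis denominators, and every
report states its own n - the package never silently reconciles them.

## The conditional inference tree

The comparator classifier is a from-scratch conditional inference tree:
recursive partitioning in a permutation-test framework, so that variable
selection is a multiplicity-adjusted hypothesis test and growth stops when
no association is significant - no pruning step is needed.

At a node with observations $i = 1..n$, each candidate question $X_j$ is
tested against the band scores $h(y_i)$ through the linear statistic
$T_j = \sum_i g_j(x_i)\, h(y_i)$, where $g_j$ is the raw code for ordinal
questions and the indicator vector of observed codes for nominal ones
(Q2, the living-situation question, is the nominal one by default; the
code book's `type` field controls this).  Under the null of no
association, permuting $y$ against $x$ gives the exact conditional mean
and covariance of $T_j$ in closed form:

$$\mu_j = \Big(\sum_i g_j(x_i)\Big)\,\bar h, \qquad
  \Sigma_j = \frac{V_h}{n-1}\Big(n \sum_i g_j g_j^\top -
  \big(\sum_i g_j\big)\big(\sum_i g_j\big)^\top\Big),$$

with $V_h$ the (population-style) variance of the scores.  The quadratic
form $(T-\mu)^\top \Sigma^+ (T-\mu)$, using the Moore-Penrose inverse and
df = rank($\Sigma$), is referred to a chi-square distribution.  A
Monte-Carlo permutation p-value (`node_test(..., nresample=)`) is
available purely as a verification oracle; the acceptance suite checks
the analytic moments against 10^5 permutations and the type-I error of the
root split (≤ α within simulation error over 500 null cohorts).

Design parameters, with defaults and reasons:

* `alpha = 0.05` - the conventional two-sided testing level; it is the
  stopping rule, so it directly controls tree size.
* Bonferroni adjustment over the non-degenerate candidate questions
  (constant predictors get the sentinel p = 1 and are neither counted nor
  selectable).
* `minsplit = 50` - the minimal-split rule guarding against overfitting on
  registry-sized cohorts; a node of 49 records is a leaf no matter how
  strong the association.
* `minbucket = 7` - the customary minimum child size in this tree
  tradition; the split search simply skips partitions violating it.
* Ordinal targets are scored with equally spaced band indices 1..k; the
  p-values are invariant to affine rescaling of these scores (tested), so
  only the ordering matters.
* Splits are binary: thresholds for ordinal questions, proper code
  subsets for nominal ones, chosen to maximise the absolute standardised
  two-sample statistic of the scores.
* Prediction ties in a leaf resolve toward the less severe band.  This is
  deliberately *not* tuned to reproduce any particular published tree
  shape: class imbalance can make a tree unable to predict a rare band
  (the comparison report flags bands with zero predictions), and we
  reproduce that mechanism without forcing it.
* A code unseen at an internal node during training routes in the node's
  majority direction; there are no surrogate-split chains.
* Train/test splitting (default 80/20) requires an explicit seed, which
  every report echoes - there is no hidden default partition.

## The synthetic registry

Real register data cannot be redistributed, so the simulator stands in for
them.  Its factorisation is deliberately the simplest one that (a) makes
the rule set perfectly recoverable in the noise-free limit and (b) lets
agreement degrade smoothly as noise rises:

1. A true grade is drawn from the marginal distribution
   0.21/0.27/0.23/0.15/0.07/0.05 (renormalised - the published rounded
   percentages sum to 98%), the three-month functional-outcome
   distribution of a first-ever-stroke cohort.
2. The grade's canonical answer profile is looked up
   (`canonical_profile_for_grade()`); each profile satisfies exactly its
   band's rule and no more-severe rule.
3. Within band 0-2, the Q7 "return to prior life" shading is redrawn with
   probability `dispersion` from the distribution shared across grades
   0-2 (weighted by their marginals).
4. Each question is independently contaminated: missing with probability
   `missing_rate`, an excluded "Do not know"-type code with
   `dontknow_rate`, else replaced by a uniform other valid code with
   probability `noise`.

Two constructions deserve explanation.  First, every band 0-2 profile
carries Q6 = 1 ("problems completely gone"): any 0-2 pattern with
residual problems and preserved indoor mobility would satisfy the band-3
rule and be captured by it under severity-descending precedence, breaking
the closure property that a canonical profile maps back to its own band.
Second, `dispersion` defaults to 1: grades 0, 1 and 2 then differ in
nothing the questionnaire records, which is precisely the structural
property of the real instrument - three coarse response categories cannot
separate "no symptoms", "no significant disability" and "slight
disability" - that motivates merging those grades.  A consequence the
acceptance suite exploits is a computable ceiling for any classifier on
the full 0-5 scale: mass(3) + mass(4) + mass(5) + max over the 0-2
marginals, ≈ 0.551 under the defaults, while the merged-band view of the
same records remains perfectly classifiable.  Setting `dispersion < 1`
plants a partially recoverable Q7 signal instead, for power studies.

What the simulator does **not** emulate: correlated answer errors (e.g.
cognition-dependent response bias across all seven questions), clinical
covariates (age, sex, stroke severity), repeated strokes, or the joint
answer distribution of the real register, which is unknowable from public
material.  Passing tests on simulated cohorts therefore certify the
*machinery* - rule engine, statistics, tree, plumbing - not the clinical
validity of the crosswalk on any real population.

## Numerical choices

* Rank of the permutation covariance: eigenvalues above `1e-10` times the
  largest; the Moore-Penrose inverse comes from `MASS::ginv`.
* Split-criterion ties break toward the earlier candidate (lower
  threshold / first enumerated subset), making tree growth fully
  deterministic for fixed data and configuration.
* Kappa with degenerate margins ($P_{e,w} = 1$) raises an explicit error
  rather than returning 0/0.
* Landis-Koch banding rounds half-up to two decimals (see above); R's
  banker's rounding is deliberately not used there.

## Problem sizes

The shipped test suite simulates at desk scale: cohorts of 300-1200
records for recovery and monotonicity properties, 4000 for the full-scale
ceiling, 10000 for marginal calibration, 500 null cohorts for type-I
error, 10^5 permutations for the moment checks, and 1000 replicates for
CI coverage.  These sizes were chosen so each property's sampling error is
well inside its assertion slack while the whole suite stays fast.

## Limitations

The code book is a reconstruction; the rule engine follows the printed
codes literally even where their semantics (notably Q6 code 2 appearing in
both the band-3 conjunction and the band 0-2 disjunction) cannot be
cross-checked against the register's questionnaire.  The precedence order
is our choice, documented above.  The kappa CI is asymptotic; for very
small cohorts a resampling interval would be preferable.  And all
empirical guarantees are relative to the simulator's independence
assumptions - external validation on real register data remains the
responsibility of whoever applies the crosswalk.
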