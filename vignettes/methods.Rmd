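---
title: "Methods: elicitation, value solving, aggregation and survey statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elicitation, value solving, aggregation and survey statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`vaxmcda` ranks candidate pathogens for vaccine research investment with an
additive multi-criteria value model elicited from experts. This vignette
documents the model, the algorithms, and the numerical choices, so results
can be interpreted and audited without reading the source.

## The additive value model

A *criterion scheme* fixes a set of criteria (by default eight: deaths
under 5, deaths 5+, years lived with disability, socioeconomic burden,
outbreak disruption, inequity, antimicrobial resistance, unmet needs) and
an ordered set of performance levels shared by all criteria (by default
five, Very low to Very high). A respondent's *value system* assigns every
criterion level a point value $v_{c,\ell} \ge 0$, non-decreasing in
$\ell$, with $v_{c,1} = 0$ and the top-level values (the criterion
*weights*) summing to 100. A pathogen scored at level $\ell_c$ on each
criterion has total weight $\sum_c v_{c,\ell_c}$; pathogens are ranked by
total weight.

## Pairwise elicitation

Respondents never state weights directly. Instead they answer two-criterion
choice questions: two hypothetical pathogens that differ on exactly two
criteria, with neither dominating the other and everything else tied.
Choosing one of them ranks a *level increment* on one criterion (the value
gain from level $a$ to level $b$) against an increment on the other.

The engine maintains a transitively closed preference graph over all level
increments (80 increments on the 8 x 5 scheme). Two structural facts seed
the graph before any question is asked:

- *containment*: within a criterion, a wider level jump is worth at least
  any narrower jump it contains (monotonicity of values);
- answered questions add strict (or, if allowed, indifference) edges, and
  the closure is recomputed exactly after every answer.

Question selection is deterministic: among undetermined comparisons the
engine asks the smallest-span trade-off first (adjacent-level questions
are cognitively easiest), and among those it picks the question whose
answer is *guaranteed* to determine the most currently undetermined
comparisons, whichever way it is answered (a minimax elimination score
computed through the closed graph), with remaining ties broken by a fixed
lexicographic order. Answers that would close a preference cycle are
rejected at entry. A session is complete when all undominated
two-criterion comparisons are determined; transitivity typically answers
about nine of every ten comparisons (around 300 questions out of 2,800 on
the default scheme).

## Solving point values

Completed sessions are turned into point values by linear programming.
Variables are the free level values $v_{c,\ell}$ ($\ell \ge 2$) and a
separation $\varepsilon$; constraints are level monotonicity, one row per
elicited strict preference ($d_i - d_j \ge \varepsilon$ for the compared
increments), equality rows for indifferences, and the normalisation
$\sum_c v_{c,L} = 100$. The solver maximises $\varepsilon$, the *max-min
gap*: the returned values are the system that satisfies every elicited and
implied preference with the largest worst-case margin, a central point of
the feasible region rather than an arbitrary vertex. The normalisation is
imposed inside the program (not by rescaling afterwards) because without a
scale constraint the maximised gap is unbounded; both formulations give
the same ranking. The LP is solved with `boot::simplex`.

Two details matter in practice:

- **Constraint reduction.** When a session contains no indifference
  answers, the engine passes only the covering relation (transitive
  reduction) of the completed preference closure to the LP instead of all
  explicit answers. Every cross-criterion covering pair is strict, so each
  entailment chain carries at least one gap, and within-criterion weak
  covering pairs are containments already implied by the monotonicity
  rows; the reduced program therefore has the same optimum whenever the
  solved gap is positive, at roughly a tenth of the size.
- **Inconsistent respondents.** Acyclicity of the preference graph does
  *not* guarantee that an additive representation exists: an error-prone
  respondent can rank increments pairwise-consistently while contradicting
  their sum decompositions (for example preferring every part of one
  criterion's jump yet preferring the other criterion's whole jump). The
  gap variable is therefore allowed to go negative (implemented by a
  shifted variable, so the program is always feasible): for a consistent
  respondent the solution is identical to the original program, while for
  an inconsistent one the solver returns the value system whose worst
  preference violation is smallest. The solved gap is recorded on the
  value system — strictly positive iff the answers admit an exact additive
  representation. If the reduced program solves with a non-positive gap,
  the engine re-solves on the full explicit answer set (the reduction
  argument needs a positive gap).

### What elicitation can and cannot identify

Two-criterion questions determine, directly or by transitivity, the
relation on *all undominated two-criterion comparisons* — that is what
"complete" means for a session. They do **not** identify a unique total
order over all $L^C$ alternatives: alternatives differing on three or more
criteria with near-tied sums can legitimately permute across value systems
that satisfy every elicited constraint, and no sequence of two-criterion
questions can separate them. The package's recovery guarantees are
accordingly stated on the determined relation: for noiseless respondents
the solved values reproduce the true relation on every comparison the
method determines (verified exhaustively in the test suite, including
against brute-force enumeration on small schemes). Full-ranking agreement
on all alternatives is *not* claimed, because it is not attainable from
this question type.

## Scoring pathogens

Regional score matrices grade each pathogen 1..L on each criterion.
Quantitative criteria are scored comparatively within a region: pathogens
are ranked on the burden measure and binned into rank quintiles
(`floor((rank - 1) * L / n) + 1`, ties sharing the lower level), so zero
burden is always level 1 and identical burdens always receive identical
levels. Qualitative criteria are scored against an external rubric and
enter as data. Every cell carries a provenance code (`regional_data`,
`inferred`, `preliminary`) that propagates into reports but never changes
arithmetic. Scores are comparative within a region and must not be
compared across regions.

## Aggregation

Regional mean point values are arithmetic means of the respondents' value
matrices, which preserves the sum-to-100 normalisation and — by linearity —
makes ranking by mean values identical to ranking by mean per-respondent
totals. Regional top-k lists include boundary ties rather than breaking
them arbitrarily. The global list is the union of regional top-k lists,
ordered by the number of regions listing the pathogen, then best regional
rank, then name. Robustness is probed leave-one-out: omitting a criterion
zeroes its additive contribution (no renormalisation — rankings are
scale-free, so renormalising cannot change the order) and the report gives
the pathogens dropped from and added to the baseline global list per
omitted criterion.

## Respondent statistics

- **Exclusions.** Per respondent the first fully-completed submission is
  kept; incompletes, duplicate completes (same normalised identity hash)
  and straight-lined sessions are excluded, with
  `received = analysed + incomplete + duplicates + straight_lined`.
  Reported percentages round half away from zero.
- **Fisher exact tests** use full hypergeometric enumeration with the
  probability-mass two-sided rule (no mid-p), matching `stats::fisher.test`.
- **Adjusted mean differences** in criterion weights are ordinary least
  squares of each weight on the covariate set, with aliased terms dropped
  and reported.
- **Clustering.** To avoid the collinearity of full value matrices,
  clustering works on a PCA composite of each respondent's Medium and
  Very-high level values (16 features), standardised, keeping the smallest
  leading component set reaching 80% explained variance. k-means (25
  restarts, fixed seed) is run for each candidate k, and four votes choose
  k by consensus: the elbow (maximum discrete curvature of the
  within-cluster sum of squares), maximum mean silhouette width, the gap
  statistic (uniform reference, first-SE-max rule; a vote below the
  candidate range is clamped to its minimum and flagged), and a
  Calinski-Harabasz / Davies-Bouldin battery. The consensus is the mode,
  smaller k on ties.
- **Cluster membership** is modelled by logistic regression with Wald 95%
  intervals; separation is detected and affected terms reported as
  non-estimable. The design's resolution is summarised by the minimum
  detectable odds ratio: the continuity-corrected two-proportion power
  equation is solved by bisection for the detectable prevalences above and
  below baseline, converted to odds ratios. A side with no detectable
  prevalence in (0, 1) is reported `NA` (small clusters).
- **Completion bias** is checked with a logistic generalized estimating
  equation over *all* submissions: exchangeable working correlation
  (moment estimate), robust sandwich standard errors, implemented directly
  from the estimating equations. With singleton clusters it reduces
  exactly to ordinary logistic regression, which the tests verify.

## The synthetic-study generator

The generator exists so that every stage — including the statistics that
need hundreds of respondents — can be exercised and tested offline. Its
defaults describe a realistic survey and are treated as fixed study
conditions, not tuning knobs:

- two latent weight-profile clusters mixed 65/35 (one emphasising
  antimicrobial resistance and outbreak disruption, one mortality), with
  individual weights drawn Dirichlet around the cluster means and level
  spacings by ordered stick-breaking;
- covariates (region, experience, expertise flags, organisation, Gavi
  eligibility, income group, language) drawn from fixed margins,
  independent of cluster;
- a logistic completion model (about half of submissions complete), 2%
  duplicate and 2% straight-liner contamination, and a 5% chance of any
  strict verdict being flipped — flipped answers that the engine rejects
  as cycle-creating fall back to the truthful verdict, so sessions always
  terminate;
- regional score matrices from latent pathogen severities with
  cross-region correlation 0.7 and a five-pathogen globally dominant
  subset, mapped to levels by the same rank-quintile rule as burden
  scoring.

Known limits: covariates are sampled independently within respondent
(no realistic correlation between, say, organisation and income group);
verdict errors are independent flips rather than difficulty-dependent;
and qualitative and quantitative criteria share one latent severity model.
None of these affect what the generator is for — validating the pipeline's
arithmetic and its statistical calibration.

## Reproducibility

Every stochastic step is seeded: the same `study_config` gives
byte-identical results, and `run_study` writes a manifest with the package
version, seed and a hash of the configuration. The acceptance script
(`scripts/acceptance.R`) recomputes the headline power-calculation targets
from the installed package alone.
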