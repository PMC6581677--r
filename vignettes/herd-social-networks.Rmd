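---
title: "Social network analysis of managed herds with herdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social network analysis of managed herds with herdnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdnet)
```

## The problem

Farmed cattle do not choose their herd mates: animals are moved between
groups for breeding and pasture management, and each move creates a new
*group composition* whose social structure must re-form.  `herdnet`
implements the full analysis chain for studies that quantify this process
from two kinds of field observation:

* **scan sampling of nearest neighbours** — at fixed intervals, each
  individual's single nearest neighbour is recorded; accumulated counts
  define a weighted, undirected social network per composition;
* **agonistic interaction logs** — supplants, avoidances and aggressions,
  each with a winner and a loser, from which a dominance hierarchy is
  estimated.

From these the package derives individual centralities, tests homophily,
models centrality on socio-demographic predictors, and quantifies what a
transfer does to the network.  A synthetic-herd generator produces data
with the same statistical structure so every stage is testable without
field data.

## Data model and conventions

Four CSV tables (see `?load_tables`) describe a study: a roster with one
row per residence interval, a scan log, an agonistic log and a
composition manifest.  Conventions that matter downstream:

* **Dates** are ISO-8601; intervals are closed on the start and open on
  the end.  Year-only birth dates are imputed to July 1 (mid-year), so a
  year-precision record is at most half a year off; `compute_age()` is
  anniversary-based and returns exact integers on birthdays.
* **Familiarity** counts the groupmates an individual has co-resided with
  (same location, overlapping intervals) for *strictly more than* 90 days
  before the composition starts.  Co-residence accumulates without decay;
  a transfer only interrupts it while the two animals are at different
  locations.  The threshold is configurable (`threshold_days`).
* **Post-change exclusion.** Relationships and hierarchies are unstable
  immediately after a change of composition or enclosure, so association
  scoring starts on day `exclusion_days + 1` (default day 8).  The scan
  dialect carries an optional `day` column (offset from composition
  start) that drives this window; without it all scans are used.

## Association matrices

Each scan contributes one directed designation (focal chose neighbour);
`build_association_matrix()` sums directed counts into one symmetric
matrix, so a mutual nearest-neighbour pair gains 2 on its dyad per scan.
Whether field studies count such a scan once or twice is rarely stated;
the symmetrized-sum convention is documented here and the matrix is the
only place the choice enters.  Daily matrices added with
`aggregate_daily()` equal a single build over the pooled log.

## Dominance: Modified David's Score

For each dyad with $n_{ij} = w_{ij} + w_{ji} > 0$ interactions, the win
proportion $P_{ij} = w_{ij}/n_{ij}$ is shrunk toward chance by the amount
of evidence,

$$D_{ij} = P_{ij} - \frac{P_{ij} - 0.5}{n_{ij} + 1},$$

and the score combines unweighted and weighted win and loss sums:
$DS_i = w_i + w^{(2)}_i - l_i - l^{(2)}_i$ with $w_i = \sum_j D_{ij}$,
$w^{(2)}_i = \sum_j D_{ij} w_j$, $l_i = \sum_j D_{ji}$,
$l^{(2)}_i = \sum_j D_{ji} l_j$.  Ranks run from the highest score
(rank 1) down.  Two choices were genuinely open and are documented
toggles:

* *zero-interaction dyads* contribute 0 to every sum (not 0.5): absent
  evidence should add no score, and this preserves the zero-sum property
  among interacting dyads;
* the *chance correction* above is the "modified" part; plain $P_{ij}$
  is available via `correction = "raw"`.

Rank ties are broken deterministically by id and reported.

## Centralities and the group-size correction

`strength()` is the row sum of the association matrix (social activity);
`eigenvector_centrality()` is the entrywise non-negative dominant
eigenvector, unit Euclidean norm (popularity: connections to
well-connected partners).  The exact symmetric eigendecomposition is the
default; power iteration (`tol` 1e-10) is available and the residual
$\lVert Ae - \lambda e\rVert_\infty$ is asserted in the tests.  On a
disconnected network the dominant eigenvector concentrates on the
strongest component; the function warns and lists components rather than
silently zeroing individuals.

Group size mechanically inflates both metrics, so
`correct_for_group_size()` adjusts them before regression.  The default
`"residual"` mode fits the pooled regression $y = ax + b$ on group size
$x$ and returns $y - a(x - \bar x)$: the size trend is removed, the mean
is preserved.  A `"literal"` mode returning $y \cdot b$ is shipped for
reproducing analyses that used that rule, but multiplying by a constant
intercept cannot remove a size effect, which is why it is not the
default.  Both record the fitted $(a, b)$.

## Homophily: difference matrices and Mantel tests

Attribute-difference matrices (`difference_matrix()`) code age and rank
as absolute pairwise differences and sex as an inequality indicator.
`mantel_test()` correlates the vectorized upper triangles and builds the
null by simultaneously permuting rows and columns of one matrix —
respecting the non-independence of dyads.  Numerical conventions:

* sampled p-values use the +1/+1 rule (the observed statistic belongs to
  the null set), so $p \ge 1/(n_{perm}+1) > 0$;
* when $N! \le 5000$ the null is enumerated exhaustively and the p-value
  is exact;
* `sided` has no default.  Reported matrix correlations mix signs (e.g.
  negative age-difference correlations mean same-age individuals
  associate), and a silent default would hide the direction of the
  hypothesis being tested.

Per-composition p-values are combined across compositions with Fisher's
method ($-2\sum\log p_k$ on $2k$ df; `combine_pvalues()`), with Stouffer
as an option.  Fisher is a documented default, not a claim about what
any particular historical analysis used.

## Mixed models, model averaging, permutation inference

Centralities (and their between-composition differences) are modelled as
Gaussian linear mixed models with a random intercept per individual,
fitted by maximum likelihood — not REML — so that AICc is comparable
across fixed-effect subsets.  `all_subsets_inference()` fits every
subset of at most six candidates, converts AICc differences to Akaike
weights, and reports each term's relative variable importance (RVI, the
summed weight of models containing it).  "Best models" are those within
$\Delta\mathrm{AICc} \le 2$ (a conventional cut; configurable), and
estimates are model-averaged over the best models containing the term.
Candidates are screened by `compute_vif()` ($1/(1-R^2)$) and perfect
collinearity aborts before any fitting.

Significance uses node-label permutations
(`node_label_permutation()`): responses are permuted across individuals
*within each composition* (preserving composition-level structure; a
whole-table mode exists), the model is refitted, and each coefficient
gets a left and a right tail p-value under the +1 rule.  The permuted
statistic is the estimate itself.  Wald $z = |\hat\beta|/SE$ values are
reported alongside but inference rests on the permutation tails.  Sex is
excluded from the difference models: transferred animals are few and
their sex is confounded with age there.  A zero residual variance (a
degenerate but legal fit, e.g. a constant response) yields `NA` standard
errors rather than an error.

## Transfers

For two adjacent compositions of one group,
`build_transfer_record()` restricts both association matrices to the
shared individuals (at least three), correlates them with a Mantel test
— the *stability* of dyadic relationships across the change — counts
transferred individuals (added plus removed; an enclosure-only change is
a "0" change), and computes per-individual deltas of the corrected
centralities and of dominance rank.  Deltas default to the
group-size-corrected metrics, matching the corrected-metric convention of
the centrality models; raw-metric deltas are an option.  An individual
with no agonistic record in one composition gets a missing rank delta,
never an imputed one.  `stability_vs_transfers()` then asks whether
stability depends on how many animals moved (permutation Spearman), and
`mean_stability()` summarizes the correlation coefficients.

## The synthetic herd generator

`herd_scenario()` fixes the study conditions; `generate_herd()` draws a
reproducible data set from them.  What is emulated:

* **neighbour choice**: focal $i$ picks neighbour $j$ with probability
  $\propto \exp(-\beta_{age}|a_i-a_j| - \beta_{rank}|r_i-r_j| +
  \beta_{sex}\,1[s_i = s_j] + \beta_{fam}\,1[\text{familiar}])$, where
  rank is the rank of the *latent* dominance score — generation stays
  separable from inference.  Draws are independent across focals within a
  scan (no mutual-nearest-neighbour constraint; the association builder
  symmetrizes anyway).
* **agonistic outcomes**: dyads interact $\mathrm{Poisson}(\lambda
  \cdot days)$ times; $i$ beats $j$ with probability
  $\mathrm{logistic}(k(score_i - score_j))$, $score = \gamma \cdot age +
  \mathcal N(0, \sigma_d)$.
* **residence histories** are written so the familiarity the analysis
  computes matches the scenario's intent: founders share 180 pre-study
  days, arrivals are co-reared elsewhere (familiar among themselves,
  strangers to residents on arrival).

Default conditions mirror the scale of published scan-sampling studies
of managed cattle: group sizes 12–13 (within the reported 8–21 range),
300 scans per composition collected on observation days of 60 scans,
interaction rate 0.3 per dyad-day (≈ 20 interactions per dyad over a
composition), homophily coefficients $\beta_{age} = 0.5$,
$\beta_{rank} = 0.3$, $\beta_{sex} = 0.5$, $\beta_{fam} = 0.7$, dominance
steepness $k = 1$, and a four-composition timeline over one group: a
five-animal transfer, an enclosure-only change, and a single removal.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatial structure of the enclosure, weather
and seasonal activity changes, mother–calf bonds, reciprocity in
neighbour choice, and drift of relationships within a composition.  The
generator validates the machinery (does the pipeline recover known
structure?), not the biology.

## Numerical choices and degenerate inputs

* Permutation p-values are never 0 (+1/+1 rule; exhaustive mode is exact).
* Constant matrices or vectors make correlations undefined and raise
  errors instead of returning `NA`.
* All-zero association matrices: strength is 0, eigenvector centrality is
  an error (undefined), the pipeline records `NA`.
* Rank ties: deterministic id order, ties reported.
* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed and persists them in its outputs,
  so a report bundle is byte-reproducible.

## Problem sizes used by the test suite

The suite validates the statistical guarantees at desk scale, chosen as
the package's own test design: dominance oracle equivalence on 100
random 5–8 individual matrices; Mantel and node-label calibration on 500
null simulations each at 99 permutations (rejection counts checked
against the exact binomial 99% interval around 0.05); latent-hierarchy
and homophily recovery over 100 generator seeds at field-scale scan and
interaction counts; coefficient coverage over 200 mixed-model
replicates of 50 individuals × 4 compositions; and a byte-identity check
of two pipeline runs at reduced permutation counts (200 Mantel / 100
node-label).

## A worked example

```{r example, eval = FALSE}
library(herdnet)

cfg <- run_config(scenario = herd_scenario(), seed = 1)
res <- run_pipeline(cfg, "herd_run")

res$transfers$transfers      # stability of each composition change
res$homophily                # per-composition and combined Mantel results
res$models$strength_corrected$terms   # Table-style model output
```

## Known limitations

* The Gaussian family is assumed throughout the mixed models; count-like
  responses (raw strength at low scan numbers) are only approximately
  Gaussian.
* The literal group-size correction is reproduced, not endorsed.
* Exhaustive permutation switches at $N! \le 5000$, i.e. $N \le 6$ for
  matrices; at $N = 7$ a sampled null with 1000 permutations is used.
* The familiarity clock has no decay and no partial-day accounting; the
  convention (total overlap days, strict threshold) is stated rather than
  inferred.
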