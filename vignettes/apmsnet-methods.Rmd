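---
title: "Scoring replicated AP-MS pull-downs: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring replicated AP-MS pull-downs: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsnet)
```

# The measurement model

An endogenous AP-MS experiment purifies a chromosomally tagged bait
protein on an affinity column and identifies everything that co-elutes.
The package's unit of data is one emPAI value per (protein, bait,
biological replicate, elution fraction). emPAI,
$10^{N_\mathrm{obs}/N_\mathrm{able}} - 1$, is a label-free relative
abundance proxy: $N_\mathrm{obs}$ distinct peptides observed for the
protein, $N_\mathrm{able}$ distinct tryptic peptides the instrument could
in principle have seen. Two properties of this design drive every
modelling decision downstream:

* **absence is informative but noisy.** A protein missing from one
  replicate may be below the detection limit, lost to stochastic
  sampling, or genuinely absent. The container (`pulldown_matrix`)
  therefore distinguishes "not observed" from an explicit zero, and the
  summaries decide explicitly when absence becomes a zero.
* **the column itself binds protein.** A no-bait purification from the
  untagged strain measures this sticky background directly, and the
  scoring subtracts it rather than modelling it.

## The median-max summary

Per bait and protein the package computes, in order: the maximum emPAI
over elution fractions within each replicate; subtraction of the
protein's control baseline, floored at zero; and the median across the
replicate slots. The maximum absorbs elution-profile shifts — the same
fraction number in two replicates can hold different parts of the elution
peak, so only the peak height is comparable. The median across exactly
$k$ replicate slots (absent replicate = 0) means a protein seen once in
three replicates has median-max 0: presence in at least two replicates is
required before any abundance evidence counts. The same positional-median
convention defines the control baseline, which is why a protein seen in
only one of three control replicates has baseline `median(x, 0, 0) = 0`.
Both policies are configurable (`median_missing = "drop"` medians only
observed values) because the positional convention, while the
conservative default, is a choice rather than a fact of the data.

## Pseudo-confidence and the high-confidence filter

Scores are median-max values divided by the bait protein's own median-max
— an observed bait scores exactly 1 and prey scores are interpretable as
"abundance relative to the bait". When the bait protein itself is
invisible to the instrument (the canonical case is a short
trypsin-refractory protein: no arginines and its one internal lysine
followed by proline, hence a single observable peptide), the top prey
normalizes instead, and `normalizer_source` records which rule fired.

The high-confidence filter keeps (bait, prey) iff the prey appeared in
all $k$ replicates with non-zero unadjusted median-max strictly above the
control baseline. Two deliberate choices here:

* **the control comparison uses unadjusted values on both sides.**
  Comparing the *subtracted* value against the baseline would count the
  control twice.
* **equality with the control is kept only under the sticky-bait rule.**
  If equality were always accepted, a noiseless sticky background would
  produce a spurious edge from every bait to every sticky protein —
  exactly the false positives the control exists to remove; the package's
  sticky-only simulation yields zero edges for this reason. Equality does
  carry evidence in one situation: when the bait protein is itself
  prominent in the control (it binds the column), its genuine partners
  ride into the control along with it. For such baits, prey observed in
  *every* control replicate and at control-level abundance in the
  pull-down are kept, flagged `dashed` — their score carries no abundance
  evidence beyond the control, and the network writers give them the
  conventional sentinel width 0.001 rather than a meaningful weight.

## The bootstrap significance test

Small studies cannot estimate false-positive rates from prey promiscuity,
so each (bait, prey) pair gets a resampling test instead. The null pool
for a bait is every replicate of every *dissimilar* bait plus the control
replicates — a candidate is admitted only if its dense replicate profile
(max-over-fractions, zero-filled) has Pearson $R < 0.3$ with every
replicate profile of the focal bait. Screening at the profile level is a
choice: replicates are the only per-run object available to correlate,
and screening removes baits that share a complex with the focal bait from
its null. An undefined correlation (constant profile) is treated as 0,
i.e. admissible: an empty candidate run carries no evidence of
similarity.

Each resample draws three values with replacement from the bait's
replicate maxima for the prey and three from the prey's values across the
pool (absence = 0: a pool replicate without the prey is evidence the prey
does not bind columns indiscriminately). The p-value is $1 - n/B$ with
$n$ the count of resamples where the bait median *strictly* exceeds the
pool median — ties favor the null, which makes the test conservative:
when a bait–prey complex is itself present in the control, the test
refuses significance even though the filter may keep the edge.

Determinism matters for a resampling test embedded in a pipeline: each
(bait, prey) pair derives its own RNG stream from (seed, bait, prey) by a
31-bit string hash, so row order, subsetting, or parallel evaluation can
never change a p-value. The minimum attainable non-zero p is $1/B$.

## Network validation statistics

* **Reciprocal confirmation.** Among unordered bait pairs with at least
  one directed edge, the fraction with both. An internal-consistency
  measure: a real complex containing two tagged baits should be seen from
  both sides.
* **Functional-role agreement.** The fraction of edges whose endpoints
  share a role label, against a null that permutes the label multiset
  over the network's proteins (not the whole genome — the question is
  whether *these* interactions sort into roles, given *these* proteins).
  The tail probability counts permutations whose agreement reaches or
  exceeds the observed value: ties go to the null, so a degenerate
  network where every labeling agrees equally returns p = 1 rather than
  0. Unannotated endpoints stay in the denominator and never agree by
  default (role vocabularies are incomplete; dropping such edges is
  available via `drop_unannotated`).
* **Profile correlations.** Each bait as its vector of pseudo-confidence
  scores over the union of observed proteins (control: median-max
  values), zero-filled. A bait highly correlated with the control is a
  column binder; a bait pair highly correlated with each other is a
  shared complex.
* **Co-expression.** Centered Pearson correlation of expression profiles
  for gene pairs, pairwise-deleted over shared non-missing conditions
  (at least 3). Interacting pairs are the network's edges; the
  non-interacting universe defaults to bait × observed-protein pairs not
  in the edge set — the contrast the pull-down design actually probes —
  with all-vs-all available. The two distributions are compared by a
  Welch two-sample t-test (unequal variances, two-tailed) and a frequency
  polygon over 20 bins of width 0.1 spanning $[-1, 1]$; percentile ranks
  of transcript abundance use `rank/n × 100` with average ranks for ties,
  the maximum mapping to 100.
* **Orthologous coverage.** Reciprocal best hits at e-value ≤ 1e-4 in
  both directions, ties broken by bitscore then subject id (the stated
  tie-break is a convention; many-to-one pre-reciprocity handling is not
  standardized). Coverage counts reference pairs whose members both map
  into the study (one of them a bait) and the fraction re-observed.

# The synthetic generator

`simulate_pulldowns()` exists so that every stage is testable without
study data, with planted ground truth. Its defaults are the study
conditions the scoring scheme was designed around: 12 baits, biological
triplicates, six elution fractions, a shared prey pool of 90 so prey
recur across baits, three reciprocal bait pairs, and a ~30-protein sticky
background present in all runs including the control. Where the design
leaves a quantity open, a value was fixed once at what is realistic for
bacterial AP-MS on a Q-TOF: bait emPAI mean 3 with prey at 20–80% of
bait, sticky mean 1, log-normal noise with sdlog 0.5 (CV ≈ 53%, typical
of biological-replicate label-free quantification), 5% per-replicate
dropout, elution peaks of width one fraction whose centers jitter ±1
fraction between replicates (the phenomenon that motivates
max-over-fractions), a detection floor of 0.01, eight role labels
inherited by complex members with probability 0.7 (20% of proteins
unannotated), and expression over 106 conditions with co-complex genes
loading 0.8 on a shared latent factor.

What it emulates faithfully: triplicate structure, elution-peak shifts,
control-visible sticky binders, missingness-as-absence, role and
co-expression signal concentrated in complexes. What it does not:
peptide-level sampling (emPAI is drawn directly unless routed through the
digestion module), intensity-dependent dropout, correlated noise between
co-eluting proteins, shared sub-complexes between baits beyond pool
reuse, and contaminant proteins absent from the control. Passing the
recovery tests therefore demonstrates the *scoring logic* — not that the
method would achieve the same precision on real spectra.

Two behaviours of the published rule set are worth knowing and are
visible in the simulations. First, under multiplicative noise roughly
half of the sticky background passes the median-vs-median control
comparison (P(median of 3 noisy draws > median of 3 noisy draws) = 1/2
for exchangeable noise); the filter is a coarse screen, and the bootstrap
— whose null pool contains those very control replicates — is what
separates sticky prey from real ones. Second, recall degrades quickly
with dropout because the all-replicates rule is absolute: a prey missing
from one replicate of every bait that binds it is unrecoverable.

# Numerical and degenerate-input choices

* Adjusted abundances are floored at 0; scores are non-negative by
  construction and equivariant under global rescaling of all emPAI
  values.
* Equality tests against the control baseline are exact floating-point
  comparisons; both sides derive from the same arithmetic on the same
  table, so representable values compare correctly.
* A bait whose every median-max is 0 yields an empty score slice with a
  warning rather than 0/0.
* An empty null pool (every candidate correlated with the focal bait) is
  an error from `build_null_pool()` suggesting a higher `r_threshold`;
  `significance_table()` catches it per bait and reports `NA` p-values
  with a warning instead of aborting the whole table — the test is
  undefined for that bait, not for the study. Sticky-heavy datasets make
  this reachable: a shared background correlates every pair of runs.
* Constant vectors yield `NA` correlations in `profile_correlations()`
  and `pair_coexpression()`; inside pool screening they are treated as 0
  (see above).
* Writers emit rows and columns in sorted, deterministic order;
  `write_pulldown_table()` prints the shortest decimal that parses back
  to the same double, so write–read–write is byte-stable.

# Problem sizes used by the tests

The test-suite simulations use 3–6 baits over 50–120 proteins, bootstrap
sizes of 400–10,000 and permutation counts of 500–20,000; the
monotone-degradation property averages 20 seeds per dropout level; the
acceptance script runs the full default study scale (12 baits, 300
proteins, B = 10,000, 100,000 permutations). These sizes were chosen so
each check exercises the asymptotics it asserts (binomial Monte-Carlo
error bounds are computed per test) while the whole suite stays
interactive.

# Known limitations

* emPAI is a coarse abundance proxy; the scoring inherits its saturation
  at 9 and its insensitivity to protein length beyond the observable
  count.
* The high-confidence filter has no notion of partial evidence: two of
  three replicates, however abundant, is rejection.
* The bootstrap conditions on the observed pool; with few dissimilar
  baits the pool is small and p-values coarse.
* AP-MS cannot distinguish direct from bridged interactions; edges are
  co-purification claims, not contact claims.
* The permutation null holds the network topology fixed; it asks about
  label arrangement only.
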