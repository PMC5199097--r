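---
title: "Methods: distances, delimitation and dating for short mitochondrial alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distances, delimitation and dating for short mitochondrial alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aylacostoma)
```

## The problem and the data

The High Paraná River (Argentina–Paraguay) held a small radiation of
*Aylacostoma* snails, most now extinct after the river's impoundment. The
only molecular window on the extinct *A. stigmaticum* is a 234-column
alignment of a short fragment of the mitochondrial 12S rRNA (third
domain), sequenced from an 80-year-old dried museum shell, together with
sequences from captive *A. brunneum* (3 specimens) and *A. chloroticum*
(7 specimens). Each species carries a single 12S haplotype, so the whole
dataset is determined by its 13 variable columns, the per-species base
totals, and the sample sizes — all of which are published as tables.

`build_study_alignment()` exploits this: it reconstructs an alignment that
is *statistically indistinguishable* from the study data. The 13 variable
columns carry exactly the published states (including the single-column
gap at position 225 carried by *A. stigmaticum* and *A. brunneum*); the
221 invariant columns carry the base multiset implied by subtracting the
variable-column contributions from the per-species totals. The builder
*solves* for that multiset per species and refuses to proceed unless all
three species imply the same non-negative solution (they do: A=78, C=28,
G=36, T=79). The arrangement of invariant columns is shuffled by a seed;
every statistic in this package (distances, trees, partitions, dates)
depends only on column multisets, so the seed provably does not affect
any downstream number — a property the test suite checks directly.

What the reconstruction does **not** give you is the true GenBank
sequences: the invariant columns are an arbitrary arrangement. Any
analysis sensitive to column *order* (e.g. sliding windows, structure
prediction) would be meaningless on it, which is why the secondary
structure module takes a user-supplied annotation instead of predicting
one.

## Distances

Distances are computed from gap-aware pairwise site counts
(`pairwise_site_diffs()`): transitions are A↔G and C↔T mismatches,
transversions the rest; a gap-versus-base column is an indel event, never
a nucleotide difference, and adjacent single-gap columns merge into one
event. `compared_sites` counts columns ungapped in both sequences
("pairwise deletion" — the study setting; `"complete"` deletion removes
every gapped column globally, and on these data the two coincide because
the only gap column separates species in both modes).

The corrected distance is Kimura's two-parameter model:

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$$

with $P$, $Q$ the transition and transversion proportions. Saturated
pairs ($1-2P-Q \le 0$ or $1-2Q \le 0$) are returned as `NaN` with a
warning rather than silently clamped; neighbour joining refuses
non-finite matrices. Internal values are kept at full precision and only
rounded (6 decimals) at report time.

Standard errors come from a column bootstrap (`bootstrap_se()`): columns
are resampled with replacement, the statistic recomputed per replicate,
and the SE is the standard deviation across replicates. The default of
1000 replicates follows the study; the tests validate the bootstrap
against a binomial delta-method closed form and against the
$1/\sqrt{2}$ scaling law under column doubling.

## Neighbour joining

`nj_tree()` is the Saitou–Nei agglomeration on the distance matrix,
joining the pair minimising $Q(i,j) = (n-2)\,d_{ij} - \sum_k d_{ik} -
\sum_k d_{jk}$ with the standard two-point branch lengths and the
three-point formulas for the last join. Two numerical choices matter:

* **Tie-breaking** in the Q-minimisation is by lexicographically smallest
  pair of cluster labels. With ten identical-haplotype sequences, ties are
  the norm, not the exception; this rule makes every run reproducible.
* **Negative branch lengths** (a known NJ artefact) are clamped to zero
  with the deficit moved to the sister branch, preserving the path length
  through the join; the raw values are retained in a `raw_lengths`
  attribute.

NJ is consistent on additive matrices; the tests verify exact recovery of
100 random trees (4–8 tips) against the generating tree's path-length
matrix and agreement with an independent NJ implementation on non-additive
matrices. Split support (`bootstrap_support()`) resamples columns,
rebuilds the tree, and reports the percentage of replicates containing
each internal bipartition — support is attached to *splits*, not node
identities, so it is invariant to rerooting.

## Secondary-structure classification

Given a Vienna dot-bracket annotation of the alignment,
`classify_variable_sites()` labels every column at which a sequence pair
differs: `unpaired` for loop columns; for stem columns,
`stem_preserving` when **both** sequences form a canonical pair with the
partner column (Watson–Crick or GU wobble, T read as U) and
`stem_breaking` otherwise. GU is included deliberately: compensating
changes in rRNA stems routinely pass through wobble intermediates, and a
Watson–Crick-only rule would misclassify them. A gap at a paired column
is `stem_breaking` with an `indel-in-stem` note. The published structure
figure for this fragment is not available as a machine-readable string,
so the "ten loop / three stem" pattern of the study is validated against
a surrogate structure constructed in the tests (three stems placed at
variable transition columns with partners chosen so every species pairs
canonically); a user analysing real data should supply the real
annotation.

## Species delimitation

**Barcode-gap partitioning.** `abgd_partition()` implements a deliberately
simplified, fully specified variant of automatic barcode-gap discovery:
sort the distinct pairwise distances; among those at or above the prior
maximum intraspecific divergence $P$, find the first consecutive pair
$(d_i, d_{i+1})$ with $d_{i+1} - d_i > X\,d_i$ (default $X = 1.5$); use
$d_i$ as the clustering threshold, falling back to $P$ when no such gap
exists; partition by single-linkage connected components at the
threshold; recurse within groups until stable. The original published
partitioner adds a local-slope heuristic whose details are
under-specified; the variant here is monotone in the prior (group counts
never increase as $P$ grows — property-tested on random matrices) and
reproduces the study's behaviour: three groups at the seven ladder priors
up to 0.0215, then two, then one. `abgd_scan()` runs the default
geometric ladder of ten priors from 0.001 to 0.1 and also returns the 55
pairwise distances behind the trimodal histogram (`autoplot()`).

**K/θ.** Under the evolutionary genetic species concept, sister clades
with $K/\theta \ge 4$ (between-clade mean distance over within-clade
diversity) are distinct species with probability ≥ 0.95. The ratio is the
easy part; θ is not, because each species here is monomorphic at 12S, so
within-clade means are zero. Three policies are provided:

* `supplied` — an explicit θ, e.g. carried over from a more variable
  locus. The study's printed θ values (0.0043165, 0.0014333) cannot be
  derived from the 12S matrix (all within-clade means are zero) and their
  provenance is unstated; they are honoured verbatim under this policy,
  which reproduces the printed ratios 5.08, 9.31, 31.31.
* `max_within` — the larger within-clade mean; the natural choice when
  clades are variable.
* `watterson_upper` — for zero-variation clades, an upper bound
  $3/(a_n L)$ with $a_n = \sum_{i<n} 1/i$: the largest θ consistent with
  observing no segregating sites in a sample of $n$ sequences of length
  $L$ (at the 95% level). Because θ is an upper bound, $K/\theta$ is a
  lower bound and the ≥ 4 decision is conservative.
* `auto` (pipeline default) — `max_within` where positive, otherwise
  `watterson_upper`; every report states the policy actually applied.

## Clock test and dating

`tajima_rrt()` is Tajima's non-parametric relative rate test: over
columns ungapped in both ingroup taxa and the outgroup, count sites where
each ingroup taxon alone carries a unique state; under a clock the two
counts have equal expectation and $(m_1-m_2)^2/(m_1+m_2)$ is referred to
a 1-df chi-square (upper tail, no continuity correction, per the original
formulation). The statistic is asymptotic: the calibration test simulates
clock-like data long enough (5000 columns, ≈ 60 informative sites per
lineage) for the chi-square reference to hold, where the empirical size
is 0.05 ± 0.02; at a few dozen informative sites the discrete statistic
drifts a point or two above the nominal level, which is a property of the
test, not of this implementation.

Dating uses the net-divergence clock: $T = D_a / 2\mu$, where
$D_a = d_{XY} - (d_X + d_Y)/2$ is the between-group mean distance minus
the average within-group diversity, and $2\mu$ is the divergence rate
(0.6%/Myr for these snails, following the gastropod literature the study
relies on). The 95% interval is $(D_a \pm 1.96\,\mathrm{SE})/2\mu$ with
SE from the column bootstrap of $D_a$. Two details:

* **Singleton groups.** *A. stigmaticum* is a single sequence, so its
  within-diversity is undefined. The default `singleton_zero` policy
  enters 0 for it in $D_a$ (`borrow_sister` substitutes the sister
  clade's diversity instead). On these data the choice moves the outer
  date by ≈ 0.09 Myr.
* **What the fixture can and cannot reproduce.** From the published
  distance table, $D_a/0.006$ gives 3.66 Myr (chloroticum/brunneum) and
  6.39 Myr (stigmaticum vs the rest). The study prints 3.75 and 6.57; the
  exact distance variant behind those numbers is not stated and is not
  recoverable from the published tables. This package reports its own
  reproducible values and makes no attempt to force agreement; its dating
  claims are instead validated by parameter recovery on simulated clocks
  (below).

`date_all_splits()` walks a rooted guide tree over group names and dates
each internal split, taking the outlying side against the union of the
rest; `run_pipeline()` derives that guide tree by average-linkage
clustering of group mean distances when none is supplied (on the study
data this reproduces the sister-pairing of *A. chloroticum* and
*A. brunneum* with *A. stigmaticum* outside, as in the published trees).

## The clock simulator

`simulate_clock_alignment()` evolves sequences on the rooted three-taxon
clock tree `((A,B):inner, C):outer` under a K2P process, using the exact
branch transition probabilities (no discretisation), calibrated so the
expected K2P distance between tips split $t$ Myr ago is
$2\mu t$. Defaults are the study's conditions: splits at 6.57 and 3.75
Myr, $2\mu = 0.006$/Myr, 234 columns, and a transition/transversion rate
ratio of 10 — every one of the 14 observed differences in the real data
is a transition, and κ around 10 is typical for mitochondrial rRNA; the
generating model matches the analysis model by design, so recovery tests
probe estimation error, not model misspecification. Multiple sequences
per tip are identical copies (within-species 12S variation is absent in
the real data).

The simulator underpins three checks: (i) the K2P estimate is unbiased
for rate × time (20 × 50 kb replicates, 2% tolerance); (ii) dating
recovery — 100 datasets of 5000 columns with a 3.0 Myr inner split give a
mean estimated $T$ within 5% of truth and ≥ 90% coverage of the nominal
95% bootstrap CI (300 bootstrap replicates per dataset keep the suite
fast; the CI arithmetic is exact regardless); (iii) the relative-rate
test's type-I error. What the simulator does *not* emulate: rate
variation across sites, base-composition bias, within-species
polymorphism, indels, and sequencing error typical of historical DNA — so
green recovery tests certify the estimators under their own model
assumptions, not robustness on degraded real-world data.

## Problem sizes and determinism

All stochastic stages (fixture shuffling, bootstraps, simulations) take
explicit integer seeds and are byte-reproducible; the pipeline refuses to
run without one and logs a hash of the analysis settings. The shipped
test suite uses the sizes quoted above (e.g. 100 recovery datasets × 300
bootstrap replicates, 500 type-I simulations, 100 random trees), chosen
so Monte-Carlo error sits comfortably inside each asserted tolerance
while the whole suite runs in a few minutes on one core.

## Known limitations

* The fixture reconstructs column *multisets*, not the deposited
  sequences; order-sensitive analyses need the real alignment.
* The barcode-gap partitioner is a simplified variant; on data without a
  clean gap structure it may split where the published tool's slope
  heuristic would not (the recursive step keeps it monotone, which is the
  property that matters for the ladder summary).
* θ for monomorphic clades is an upper bound, not an estimate; K/θ
  decisions under `watterson_upper` are conservative by construction.
* Maximum parsimony, maximum likelihood and Bayesian tree inference and
  Bayesian (relaxed/strict clock) dating are out of scope; the in-scope
  clock check is the relative rate test, and reports say so.
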