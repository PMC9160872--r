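---
title: "Methods: expression level dominance and homeolog expression bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression level dominance and homeolog expression bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeobias)
```

# The problem

When two divergent genomes meet in an F1 hybrid or young allopolyploid,
each locus is present as a pair of *homeologs*, one copy inherited from
each parent. Two distinct questions arise from replicated RNA-seq of the
hybrid and both parents:

1. **Expression level dominance (ELD).** Is the hybrid's *total*
   expression at a locus (both homeologs summed) equal to the parental
   midpoint (additivity), equal to one parent but not the other
   (parental dominance), or outside the parental range (transgressive)?
2. **Homeolog expression bias (HEB).** *Within* the hybrid, are the two
   homeologs expressed at equal levels, irrespective of the total?

`homeobias` implements both analyses on transcript-level read counts,
together with the upstream plumbing (reciprocal best-hit pairing,
TPM/RPKM normalisation, expression filtering, Spearman sample QC) and a
simulator that plants known patterns and biases so every stage can be
validated end to end.

# Homeolog pairing

Homeolog pairs are defined by reciprocal best hits (RBH) between the two
parental transcript sets, computed from precomputed tabular alignment
hits (the standard 12-column dialect). Hits are pre-filtered at 90%
minimum identity and a maximum E-value of 1e-50 (both configurable) to
suppress out-paralog matches; a pair `(a, b)` is kept only when `b` is
`a`'s best surviving hit and vice versa. "Best" is the highest bit
score, with ties broken by lower E-value and then lexicographically
smaller subject id. The tie-break makes the order total, so the pair set
is invariant to input row order — without it, RBH output on tied tables
would depend on file ordering. RBH yields a strict 1:1 mapping by
construction; we make no attempt to recover 1:2 ortholog relationships
that ploidy differences might suggest, because best-hit reciprocity is
the only construction consistent with a unique pair per transcript.
Self-hits (possible only if the two parental id namespaces collide) are
an error, not silently dropped.

# Normalisation

TPM is used only for the detection filter (default: TPM >= 1 in at
least one sample, boundary inclusive). All between-group testing runs
on RPKM, `count * 1e9 / (length_bp * library_size)`. Two choices here
deserve comment:

* **Effective length.** The full transcript length is used; no
  fragment-length correction is applied, since no effective-length
  model is available for the input counts in general.
* **Library sizes.** By default the mapped total of a sample is the
  column sum of its count matrix. When the matrix covers only a subset
  of the transcriptome (as with the simulator's panel, or any targeted
  analysis), column sums are *compositional*: they shift with the very
  expression differences under study and can bias every cross-taxon
  RPKM comparison. An explicit per-sample mapped-total file
  (`read_lib_sizes()`, the `lib_sizes` config key) should therefore be
  supplied whenever aligner-reported totals exist; the simulator always
  emits one. No further between-taxon renormalisation is applied: RPKM
  comparability of hybrid homeolog sums against parental transcripts is
  assumed.

The detection filter is applied per taxon on the hybrid libraries: a
homeolog pair enters the analysis when **both** homeologs pass the TPM
filter within the hybrid, which is what "detected in the hybrid" means
operationally. Parental expression is not required for detection (an
unexpressed parental gene is itself informative for dominance); the
per-taxon scope is configurable through which samples are present in
the metadata.

# Pattern classification

For each pair and condition, three pooled-variance Student's t-tests
are computed on per-replicate RPKM: hybrid total vs P1, hybrid total vs
P2, and P1 vs P2. Groups are "different" when p < alpha (default 0.05)
and "equivalent" otherwise — equivalence is failure to reject, the only
reading under which the classical 12-pattern scheme is exhaustive. The
decision table (see `?classify_pattern`) maps the three outcomes and
the group means onto twelve Roman-numeral patterns plus a residual
`NO_CHANGE` class, binned as: additivity {I, XII}; P1 dominance
{IV, IX}; P2 dominance {II, XI}; transgressive up {V, VI, VIII};
transgressive down {III, VII, X}. The five-way bin is the robust,
authoritative semantic; the numeral orientation within a bin follows
the conventional layout (e.g. IV when the dominant P1 parent is the
higher-expressed one, IX otherwise) and is verified in tests only
through its swap symmetry: relabelling the parents maps IV<->II,
IX<->XI, I<->XII, III<->X, V<->VIII and fixes VI, VII and NO_CHANGE.

Intransitive triples (hybrid equivalent to both parents while the
parents differ) are folded into `NO_CHANGE` with a `conflict_flag`, as
are residual combinations such as a hybrid differing from both parents
while sitting exactly at a parental mean. Tests run on raw RPKM by
default because the procedure is defined directly on expression levels;
a `log2(x + 1)` option exists for users who prefer variance
stabilisation, but changing it changes the operating characteristics
and is off by default. No multiple-testing correction is applied inside
classification — the three tests per pair jointly *define* the
category — while FDR control is reserved for the bias tests below.
Degenerate replicate vectors are handled explicitly: identical constant
groups give p = 1 (no evidence of difference), and zero pooled variance
with unequal means gives p = 0 with a warning.

# Homeolog expression bias

The bias of a pair within the hybrid is

\[
B = \log_2 \frac{\tfrac1M \sum_{i=1}^{M} \mathrm{RPKM}_{\mathrm{Spt},i}}
               {\tfrac1N \sum_{j=1}^{N} \mathrm{RPKM}_{\mathrm{Spc},j}},
\]

the base-2 log ratio of replicate-mean RPKM of the paternal (Spt,
P1-derived) over the maternal (Spc, P2-derived) homeolog; with equal
replicate numbers (always true within one hybrid library set) the
prefactor cancels and B is the log ratio of RPKM sums. B = 0 is no
bias; B = 3 an 8-fold bias toward Spt; B = -3 the mirror image.
`fold_change()` maps any bias (or bias change) back to `2^|B|`.

Significance is assessed at count level. The two homeologs' reads are
summed over replicates and modelled binomially: under H0 (equal
underlying expression) the Spt read fraction is the length-expected
`pi0 = len_Spt / (len_Spt + len_Spc)` — a longer transcript draws
proportionally more reads at equal molar expression — and under H1 it
is the MLE. Twice the log-likelihood ratio is referred to chi-square
with 1 df. Running the statistic on RPKM but the test on counts is
deliberate: the ratio statistic matches the definition above, while
likelihoods are only well-defined on integer counts. Pairs with a zero
summed count in either homeolog at a condition are excluded from that
condition's test (and from any bias-change test involving it) rather
than patched with pseudocounts. Benjamini–Hochberg q-values are
computed across all testable pairs per condition, with significance at
FDR < 0.05 by default.

The bias change between two conditions is the identity
`delta = B2 - B1` — reported exactly as that difference — and its test
is the G-test of homogeneity of the homeolog proportion on the 2x2
table of summed counts (conditions x homeologs). Transcript lengths are
constant across conditions within a pair, so the length offsets cancel
and no length correction enters the 2x2 test. Following the convention
for this contrast, significance is called on the raw chi-square p-value
at 0.05 (configurable), without FDR adjustment.

A known limitation is shared with the method itself: the binomial /
G-test construction conditions on summed counts and therefore ignores
replicate-level biological overdispersion. Under negative-binomial
noise the tests are anti-conservative (they reject equal expression
more often than the nominal rate); calibration is exact in the Poisson
limit, which the test suite verifies. Beta-binomial replicate-level
likelihoods would address this but are outside the scope of this
implementation.

# The simulator

`simulate_experiment()` generates the full three-taxon design: P1 and
P2 count matrices over their own transcripts and an F1 matrix over the
concatenated reference (both homeologs), with metadata, lengths,
library sizes and a truth table. Defaults mirror the motivating study
design: 3 biological replicates per taxon per condition across the
ordered conditions 30C, 16C, 4C. Per pair, the generator draws

* transcript lengths uniform on 500–3000 bp (typical assembled
  transcript lengths), independently for the two homeologs;
* a log-normal baseline expression (sd 0.6 on the log scale, a
  moderate between-gene spread);
* a per-condition pattern bin from `pattern_frequencies`; the default
  frequencies (59.7% no change, 4% additivity, 8% P1-dominance, 19.9%
  P2-dominance, 0.2% transgressive up, 8.2% transgressive down) follow
  the unstressed-condition mixture reported for the motivating hybrid
  system;
* a per-pair true bias B from `bias_distribution`; the default draws a
  real bias for ~24% of pairs, skewed 2:1 toward the maternal
  subgenome with `|B| ~ N(2.2, 0.8)`, again matching the unstressed
  bias landscape. B is constant across conditions, so the bias-change
  null holds for every pair by default.

Parental means follow the planted bin (equal for no change; separated
`parental_fold`-fold, default 4, where the bin requires differing
parents, with the higher parent randomised; transgressive totals exceed
the parental range by `transgressive_factor`, default 2). The hybrid
total is split between homeologs so that the *RPKM* ratio is `2^B`,
i.e. expected counts in proportion `2^B * len_Spt : len_Spc`, which
makes the length-expected null of the bias test non-trivial. Counts are
negative binomial with `variance = mu + phi * mu^2` (default
`phi = 0.05`, a typical bulk RNA-seq biological dispersion; 0 gives
Poisson for analytic checks). Library sizes are reported as nominal
mapped totals (default 1e7) times a per-sample log-normal depth factor
(sd 0.05) that also scales the expected counts — the panel is treated
as a small window into a full library, which is why panel column sums
are *not* used as library sizes (see Normalisation).

What the simulator does not emulate: read-level effects (mapping bias,
paralog cross-mapping, positional coverage), assembly artifacts,
GC/length-dependent efficiency, correlated replicates, and condition
effects on overall expression level. Passing recovery tests on this
generator therefore demonstrates correctness of the statistics and
their implementation under the stated noise model, not robustness to
quantification artifacts in real libraries.

All randomness flows from the single `seed` through an isolated RNG
scope (`withr::with_seed`), so identical configurations reproduce
byte-identical fixtures and the caller's RNG stream is never consumed.

# Numerical and procedural choices

* `0 * log(0)` terms in the likelihoods are evaluated as 0; LRT
  statistics are clamped at 0 against floating-point negatives.
* t-tests use the classical pooled-variance form (not Welch), matching
  the procedure's specification; ties in the three-way decision table
  are resolved exactly as written in `?classify_pattern`.
* Spearman QC uses average ranks for ties; pairs involving a constant
  sample are reported `NA` with a warning, with the diagonal fixed
  at 1.
* The orthology stage's tie-break (bit score, then E-value, then
  subject id) is a total order, making the whole pipeline
  deterministic for fixed inputs; reruns are bit-identical.
* Conditions are contrasted consecutively in the configured order (the
  natural contrasts of a gradient design); `all_pairs = TRUE` enables
  every pairwise contrast.

# Problem sizes in the shipped tests

The test suite validates calibration and recovery at sizes chosen to
make Monte-Carlo error small relative to the tolerances asserted:
10,000 pairs for null calibration of the bias LRT (rejection rate in
(0.04, 0.06) at alpha 0.05; KS uniformity of p-values), 1,000 pairs per
planted bias value in {-2, ..., 2} for estimator recovery within
±0.05, 600 pairs across a uniform bin mixture for >= 90% bin-correct
classification at 4-fold parental separation and ~10% replicate CV, and
an exhaustive sweep of all 2x2 tables with condition totals up to 30
for oracle equivalence of the G-test. A 20-pair fixture generated at a
recorded seed is shipped under `inst/extdata/sim20` and is regenerated
bit-identically by the tests.
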