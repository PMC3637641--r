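---
title: "Methods: Rank Products, list meta-analysis, and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rank Products, list meta-analysis, and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmeta)
```

## The problem this package addresses

Small two-group transcriptome studies — five cases against five controls is
typical for native-tissue cystic fibrosis (CF) work — are underpowered for
moderated-variance statistics, and independently analysed studies of the
same biology (F508del-CFTR airway epithelium) produce gene lists that agree
only partially and sometimes in the opposite direction. `rpmeta` implements
the two halves of a response to that situation: a rank-based
differential-expression statistic that behaves well at small *n*, and
list-level machinery to quantify cross-study concordance, inversion, and
the directional intersection "signature" that survives all lists.

## The Rank Products statistic

For a study with `n_case` cases and `n_control` controls we form all
`k = n_case × n_control` pairwise log-ratios. In each comparison genes are
ranked (rank 1 = most up-regulated for the up analysis; ties get average
ranks), and the statistic is the geometric mean rank

$$RP_g = \Big(\prod_{i=1}^{k} r_{g,i}\Big)^{1/k},$$

computed in log space so large `N·k` never overflows. A gene consistently
near the top of every comparison has `RP` near 1. The up and down analyses
are the same computation with the ranking sign flipped; swapping the group
labels exchanges the two directions exactly (this is a tested invariant).

Significance is calibrated by permutation. For each gene,
`E_g = #\{null\ RP \le RP_g\}/B` pooled over all `B` permutations and all
`N` genes is the expected number of false positives at its rank-product
value, `p_g = E_g/N` is the per-gene p-value (floored at `1/(B·N)`:
a permutation p of exactly zero is an artifact of finite `B`), and

$$pfp_g = E_g / \mathrm{rank}_g$$

is the percentage of false prediction, RP's FDR analogue; `pfp·rank = E`
holds exactly by construction.

### Two nulls, and why the default is the structured one

Two null generators are provided and the distinction matters:

* `rp_permutation_null()` draws `k` *independent* uniform permutations of
  `1..N` as rank columns. This is the textbook null ("the order of all
  genes is random") and admits exact small-case oracles: for `N ≤ 4`,
  `k ≤ 2` the test suite enumerates all `(N!)^k` column combinations and
  checks the permutation estimates against the exact distribution.
* `rp_experiment_null()` simulates whole null *experiments*: an
  exchangeable matrix with the same `N` genes and the same replicate
  structure, from which the pairwise rank matrix is recomputed. Because the
  `k` pairwise comparisons share samples, their rank columns are positively
  correlated, and this null reproduces that correlation.

`rp_analyze()` defaults to the experiment null. The reason is quantitative:
with 5v5 replicates the 25 pairwise columns are far from independent, so
the independent-column null understates the spread of observed rank
products — on a pure-noise simulation (1000 genes, B = 1000) it declares
roughly 17% of genes significant at the nominal p ≤ 0.05, while the
experiment null gives 5.1% and a Kolmogorov–Smirnov distance from
uniformity of about 0.015. The independent null remains available
(`null = "independent"`) because it is the exactly-enumerable primitive and
the historical formulation; for inference it should be read as
anti-conservative at small replicate counts.

### Fold change

The matrix is on the log2 scale, so two conventions coexist in the
literature: `2^(Δ of log2 group means)` (geometric-mean ratio) and the
ratio of linear-scale group means. Both are reported (`fc` and
`fc_ratio_of_means`); `fc` is the one used by the cutoff filters. They
differ when within-group variance differs between groups.

## From statistics to gene lists

`detection_filter()` supports the two detection dialects found in array
work: keep probes called Present in more than a fraction (default 20%) of
samples, or detected at `p <` a threshold (default 0.01) in more than a
fraction (default 10%) of samples. Both comparisons are strict (`>`),
which is how fractions like "more than 10%" read; at the default
simulation settings the choice of `>` vs `≥` moves nothing because sample
counts are small and fractions land between thresholds almost surely.

`apply_cutoffs()` implements the strict list rule (defaults `p ≤ 1e-4` and
`pfp ≤ 0.05`, optional fold-change gate that respects direction), and
`size_targeted_list()` the "extended list" rule: take the best-ranked
probes with `pfp < 0.05` up to a target length, flagging (not padding) a
shortfall. Note the scale-dependence of the strict rule: `p ≤ 1e-4` is a
multiple-testing guard tuned to tens of thousands of probesets. On
desk-scale simulations of a few hundred genes the permutation p of a
genuinely regulated gene sits near `1e-4` simply because the pooled null
has real tail mass there, so the package's own simulations and the
acceptance script use the `pfp` criterion alone for list building — on the
standard three-study simulation it recovers every planted gene with zero
false positives.

`collapse_to_symbols()` resolves many-to-one probeset→symbol maps: the
probeset with the best (lowest) RP rank wins and contributes its statistics
verbatim; unmapped probesets are dropped and counted. No published
collapse rule exists for these lists; best-rank-wins is deterministic,
order-preserving, and makes the collapsed statistics traceable to a real
probeset. If, after collapsing, a symbol appears in both directions of one
study, `disjoin_directions()` keeps it in the direction with the better
rank — directional lists must be disjoint for the meta-comparison to be
well defined.

## Cross-study comparison

All comparisons operate on collapsed symbol lists as given; no reduction
to a common cross-platform universe is attempted (symbols private to one
platform simply cannot be shared). The comparison-matrix cell (row X,
column Y) is normalized by the *column* study's list size:

$$\mathrm{shared}(X,Y) = 100\,\frac{|X_d \cap Y_d|}{N_Y(d)},\qquad
\mathrm{inverted}(X,Y) = 100\,\frac{|X_{\bar d} \cap Y_d|}{N_Y(d)}.$$

This convention is the one under which the bundled published overlap rows
reproduce the published percentage matrix exactly (9/117 → 7.7,
9/115 → 7.8, 3/110 → 2.7, all checked in the tests); intersection counts
are symmetric, so `shared(X,Y)·N_Y = shared(Y,X)·N_X` is asserted as an
invariant. The `ALL` row counts *distinct* genes of the column list shared
(or inverted) with at least one other study; this definition reproduces
the published 16/117 → 13.7 and 17/220 → 7.7 for the reference-study
column. For other columns the distinct-gene definition cannot be validated
from published per-study rows alone (the pairwise overlaps among the other
five studies are not printed), so those ALL cells are computed under the
same definition but not asserted against published values. Display
percentages are rounded half-up to one decimal — half-even (the R default)
would print 13.675 as 13.68 — with full precision kept internally.

`intersect_signature()` intersects the selected up lists and, separately,
the down lists, and reports all `2^k − 1` Venn regions per direction.
Signature genes are regulated in the same direction in *every* selected
list; the membership table carries each list's fold change for the gene.

## Enrichment statistics

`hypergeom_enrich()` is the classical over-representation test:
`p = P(X ≥ k)` under Hypergeometric(`N_u`, `K`, `n`), fold enrichment
`(k/n)/(K/N_u)`, BH FDR computed independently within each annotation
category (mirroring how category-wise enrichment tables are reported). The
EASE variant (tail at `k − 1` hits, a jackknifed conservative score) is a
switch, not the default; published p-values from annotation servers also
depend on their era-specific backgrounds and are not reproduction targets.

`gsea_enrichment_score()` is the weighted running-sum statistic: hits add
`|w|^p/\sum |w|^p`, misses subtract `1/(L − n_{hits})`, and the enrichment
score is the extremum of largest magnitude. Two conventions are fixed
deliberately: a gene set covering the whole ranked list yields `ES = 0`
(with no misses there is no deviation to measure), and the p-value comes
from *gene-set* permutation — random same-size sets drawn from the list —
with the add-one estimator `p = (1 + \#\{|ES_0| \ge |ES|\})/(B + 1)`.
Phenotype permutation is deliberately not offered: with five samples per
group the phenotype-permutation null is too coarse to be useful, while
gene-set permutation is deterministic under a seed and calibrated (tested:
null p-values approximately uniform). The score itself is cross-checked in
the tests against an independent position-by-position re-walk and against
`fgsea`'s implementation of the same statistic.

## qPCR arithmetic

Standard curves: least-squares slope of mean CT against `log10` input over
a dilution series; `E = 10^{-1/slope}` (slope −3.3219 ⇔ `E = 2`, 100%),
percentage efficiency `(E − 1)·100`, and the 90–110% acceptance gate.
Efficiencies may be supplied as linear factors or percentages; they are
stored as factors.

Pfaffl fold change: technical replicates are averaged per sample first,
then per-group means form `ΔCT = CT_{control} − CT_{case}` per gene, and
`FC = E_t^{ΔCT_t}/E_r^{ΔCT_r}`. With several reference genes the geometric
mean of per-reference ratios is used (no published combination rule
exists; the geometric mean is the natural choice for ratios and reduces to
the single-reference formula). With all efficiencies at 2 the expression
collapses exactly to `2^{-ΔΔCT}`. Down-regulation is displayed as the
negative reciprocal (0.3 → −3.3), matching how validation tables are
printed. Group-difference tests run on per-sample reference-normalized
ΔCT values (two-sided t and Wilcoxon rank-sum); fully tied data return a
rank-sum p of 1 and an `NA` t-test p rather than an error.

## The synthetic data generator

`simulate_study()` draws per-gene baselines `N(8, 1.5)` on the log2 scale,
plants a constant `effect_log2fc` on every probeset of a regulated gene,
and adds i.i.d. Gaussian noise per probe × sample — the simplest
exchangeable model consistent with RP's rank-based assumptions. Defaults
mirror a small nasal-brushing study: 5v5 samples, 2-fold effects
(1 log2 unit), 0.25 log2 units of noise, ~10% of genes unexpressed in the
tissue, and 1–3 probesets per gene (85/12/3%), which exercises symbol
collapsing. Detection is Bernoulli Present per cell (0.9 expressed, 0.05
unexpressed) with detection p-values skewed low (Beta(0.4, 60)) for
Present cells and uniform otherwise, so both detection dialects have
signal to act on. `simulate_multi_study()` adds a concordant core shared
by all studies, an optional inverted set (up in the first study, down in
the others, and vice versa), per-study private regulated genes, and
partially overlapping gene universes standing in for different platforms.

What the generator does *not* emulate: intensity-dependent variance,
batch/lab effects, correlated gene modules, probe-level hybridization
physics, or realistic platform annotation mismatches. Passing tests
therefore demonstrate that the statistics do what they claim under their
own assumptions — calibration under exchangeable noise, recovery of
planted effects, exact bookkeeping — not that any particular biological
dataset will reproduce. Inter-study inversion in real data has no agreed
generating mechanism; the `inverted_fraction` knob is a modelling device
for exercising the inverted-overlap machinery, not an estimate.

The qPCR generator obeys `E^{-CT} \propto` input amount: a planted fold
change `F` shifts case CTs by `-\log F/\log E`; a per-sample loading
offset (removed exactly by reference normalization) and per-replicate
noise both use `ct_noise_sd`, so the zero-noise plate is exactly
deterministic.

## Numerical and design choices

* **Seeds are explicit arguments everywhere**; functions use
  `withr::local_seed()`, so the caller's RNG state is never touched, and
  identical seeds give bit-identical output (tested, including byte-level
  pipeline reruns).
* **Ties** get average ranks — deterministic and standard; continuous
  simulated data makes ties measure-zero anyway.
* **Degenerate inputs**: all-constant matrices rank to all-average ranks;
  constant sample vectors make the correlation distance undefined and
  raise an error naming the sample; empty gene lists are legal outputs of
  the filters; a gene set disjoint from a ranked list is an error.
* **Problem sizes in the checks**: the test-suite and acceptance-script
  simulations use 1000 genes × B = 1000 permutations for calibration
  checks, 1000 genes × B = 200 for recovery, and three studies of 250
  genes × B = 100 for the end-to-end signature run. These sizes give
  Monte-Carlo error comfortably inside the asserted tolerances (3·SE
  bounds throughout) while keeping a full run in tens of seconds.
* **Sample clustering** uses `1 − r` (Pearson, i.e. centred correlation)
  with average linkage (UPGMA), serialized as newick via `ape`.

## Known limitations

* The RP p-value is pooled across genes; it inherits the usual
  permutation granularity (`1/(B·N)` floor) and `pfp` can exceed 1 at
  middling ranks — it is an FDR estimate, not a probability.
* `comparison_matrix()` treats the supplied lists as the universe;
  percentages are not adjusted for platform coverage differences.
* The ALL-row definition is validated only for the reference-study column
  (see above); published summary means over such matrices depend on an
  averaging scheme that is not recoverable from the matrices alone, and no
  attempt is made to reproduce them.
* GSEA normalization (NES) and family-wise error machinery are out of
  scope; the running-sum score and gene-set permutation p are what is
  provided.
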