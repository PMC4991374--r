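---
title: "Methods: overlap enrichment, promoter motifs, and network topology for DAF-16 direct targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap enrichment, promoter motifs, and network topology for DAF-16 direct targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`foxotools` implements the three computational analyses that are run on a
transcription factor's direct-target gene list, in the concrete setting of
DAF-16, the *C. elegans* FOXO ortholog central to insulin-signaling
lifespan regulation. A *direct target* is a gene that is both
differentially expressed when the factor is perturbed and bound by the
factor at its promoter. Given such a list (canonically 109 genes), the
package answers three questions: does the list overlap earlier screens
more than chance; do its promoters carry the factor's binding elements;
and does it occupy a distinguished position in the protein-interaction
network.

## 1. Gene-set overlap enrichment

### Model

Two gene sets of sizes $m$ and $n$ drawn from a universe of $N$ genes
share $X$ genes; under the null that the $n$-set is a uniform random draw,
$X$ is hypergeometric:

$$P(X = i) = \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}}, \qquad
P\text{-value} = P(X \ge k) = 1 - \sum_{i=0}^{k-1} P(X = i),$$

with chance expectation $E[X] = mn/N$. The test is one-sided
(enrichment); the universe is the *C. elegans* genome, approximated as
$N = 20000$ (configurable everywhere).

Numerical choices: binomial coefficients are combined in log space via
`lchoose()` (log-gamma arithmetic), never as floating-point factorials,
so the test is exact at genome scale. The tail is summed directly over
$i = k, \dots, \min(m,n)$ rather than as $1 - \sum_{i<k}$, because the
complement form cancels catastrophically when the tail is $\ll 1$; the
two forms agree to $10^{-12}$ absolutely, which the tests assert. A
reported p-value is always the true positive tail — a published "p = 0"
is read as "below reporting precision", and `overlap_replication()`
shows the computed tails (between $4\times10^{-14}$ and
$6.5\times10^{-7}$ for those comparisons) next to the published zeros
rather than reproducing the zeros.

### Exclusions

`compute_overlap(set1, set2, exclude =)` removes the exclusion list from
*both* sets before sizing and intersecting. This generalizes the one-off
adjustment in the DamID comparison, where 14 of the 109 targets had been
collected from the compared screen itself and the target list was reduced
to $109 - 14 = 95$; as a symmetric flag it is reproducible rather than a
hand edit. Exclusion can only shrink the observed overlap, which is
tested as a property.

### Identifier handling

Normalization is whitespace trimming plus case folding to lower case
(the *C. elegans* gene-name convention), nothing more. Alias and
ortholog resolution (the original study mapped mammalian/fly targets to
worm genes through the Inparanoid database) is a resource lookup, out of
scope here; lists are compared as given.

## 2. Promoter motif scanning

### Elements and matching

The DAF-16 binding element (DBE) is scanned as the two orientation words
`GTAAACA` and `TGTTTAC`; the DAF-16 associated element (DAE), recognized
by the transcription factor PQM-1, as `TGATAAG` and `CTTATCA`. Scanning
is forward-strand only: reverse-orientation detection comes from listing
both orientation words explicitly, so an optional reverse-complement scan
is unnecessary for the default motifs and is deliberately not performed.
Matching is position-wise over the 15-letter IUPAC alphabet (`R` = A/G,
`Y` = C/T, ...). A sequence base `N` matches nothing — including a
consensus `N` — the conservative-unknown rule, so masked regions cannot
produce phantom hits. All window positions are tested and all matches,
including overlapping and self-overlapping ones, are reported; the scan
is a pure function of (sequence, motif list).

The loose DBE is the degenerate consensus `RTAAAYA`. Because `RTAAAYA`
generalizes only the forward word (`TGTTTAC` does not match it),
`dbe_motifs(loose = TRUE)` returns `RTAAAYA` together with its
reverse-orientation word `TRTTTAY`. This keeps the strand policy uniform
and makes loose-mode classification a true superset of strict mode in
either orientation, which the tests assert; with `RTAAAYA` alone a
promoter carrying only `TGTTTAC` would flip from positive to negative
under "loosening".

### Coordinates

The promoter window is the 1 kb of sequence immediately upstream of the
transcription start site (TSS), written 5'→3' and ending at the TSS. Hit
positions are reported as 1-based offsets from the window's 5' end.
Whether published per-gene positions count from the window's 5' end or
from the TSS inward is a convention the source material does not define;
`upstream_offset(start, width, L)` converts to the TSS-inward coordinate
($L - \mathrm{start} - w + 2$) so both are available, and neither is
asserted to be "the" published convention. Records whose length differs
from the nominal 1000 nt are scanned as-is with a warning.

### Classification

A gene is DBE-positive iff any DBE motif hits its promoter at least once
(similarly DAE); the two flags partition genes into `DBE_only`,
`DAE_only`, `both`, `neither`, and the four counts sum to the number of
genes. The driver `analysis/03_motif_scan.R` runs this on a synthetic
109-promoter set spiked to the observed pattern (30 DBE-carrying, 30
DAE-carrying, 7 both).

## 3. Interaction-network topology

The network is an undirected simple graph: self-loops are dropped and
duplicate edges (either orientation) collapsed at read time, with counts
reported. Edge-type annotations (physical / genetic / predicted) are
accepted as a third column and ignored — every measure here is
type-blind. Three node features are computed:

* **degree** $K_i$ — number of distinct interaction partners;
* **coreness** — the largest $K$ such that the node survives recursive
  removal of all nodes of degree $< K$ (the $K$-core peeling, whose
  result is independent of removal order); coreness $\le$ degree always;
* **target-neighbor ratio** $K^p_i / K_i$ — the fraction of a node's
  neighbors that belong to the target set, undefined for isolated nodes.

Degree and coreness are computed through `igraph` (the standard tool for
these measures); the test suite verifies coreness against an independent
brute-force peeling oracle on 100 random graphs, and degrees against
naive adjacency counts.

`compare_groups()` reproduces the published analysis surface: means of
the three features for *all* nodes, for *targets* present in the network,
and optionally for a target subgroup (e.g. the lifespan-regulating
subset), plus a two-sample KS comparison of targets against all other
network nodes per feature. Design choices where the source material is
silent: group means include only members present in the network (absent
targets are counted and reported, never imputed); the comparison group is
"network nodes not in the target set"; degree-0 nodes are excluded from
ratio means and ratio KS samples; a degenerate partition (targets =
everything) reports means and skips the KS test explicitly.

### KS test

The two-sample Kolmogorov-Smirnov statistic
$D = \sup_t |F_1(t) - F_2(t)|$ is evaluated exactly at all pooled data
points (ties are handled by evaluating both ECDFs at every pooled
value). The p-value is two-sided — assumed from the test's standard
description as sensitive to both location and shape, since sidedness is
not otherwise stated — and asymptotic, from the Kolmogorov series
$2\sum_{j\ge1}(-1)^{j-1}e^{-2j^2\lambda^2}$ at
$\lambda = \sqrt{n_1 n_2/(n_1+n_2)}\,D$, truncated when terms fall below
$10^{-12}$. The exact small-sample distribution is not implemented. On
continuous data the test holds its nominal level (the suite checks a
5% rejection rate within [3%, 7%] over 2000 null replicates of two
$n=50$ samples). On heavily tied integer data — network degrees — the
asymptotic p-value is conservative: under the exchangeable
(multiplier = 1) network null the empirical rejection rate at
$\alpha = 0.05$ is about 1%, so degree comparisons understate
significance slightly rather than overstate it. The property test
asserts the direction of that bias (no over-rejection).

## 4. What the synthetic data emulate — and what they do not

The study's real inputs (WormBase v220 promoter sequences, a 7,219-node
/ 41,132-edge integrated interaction network, GenAge/GenDR lists) are
not deposited, so every input is emulated by seeded generators whose
ground truth is recorded in JSON sidecars. Seeds are mandatory arguments,
never global state, and identical arguments give byte-identical files.

* `gen_overlap_pair(N, m, n, k, seed)` plants an exact `k`-gene
  intersection; downstream enrichment must recover exactly `k`.
* `gen_promoters(count, length, gc_fraction, spikes, seed)` draws
  i.i.d. backgrounds and overwrites them with exact motif words at known
  offsets. The default `gc_fraction = 0.5` (equiprobable bases) makes
  the chance hit rate of a 7-mer the closed form $(L-6)/4^7$ per
  orientation word, which the calibration test uses; real *C. elegans*
  promoters are AT-rich (GC $\approx$ 0.35) and the fraction is
  configurable, but an i.i.d. background at any composition suffices to
  test a deterministic scanner. Backgrounds are redrawn (bounded) until
  no accidental instance of any spiked word or its reverse complement
  survives, so planted counts are exact.
* `gen_planted_hub_network(n_nodes, background_mean_degree,
  target_count, degree_multiplier, within_target_bias, seed)` samples a
  Chung-Lu-style expected-degree graph in which targets carry
  `degree_multiplier`-times the background weight and target-target
  pairs get their connection odds scaled by `within_target_bias`. This
  model was chosen because the planted degree ratio is analytically
  controllable; it does not attempt the real network's topology
  (heavy-tailed degrees, literature ascertainment bias).

What passing tests therefore show: the statistics are exact, the scanner
misses nothing it is defined to find, and a planted target-versus-rest
signal of the published qualitative pattern (higher degree, higher
coreness, mutual interaction) is recovered reliably — at the planted
conditions of 600 nodes, 60 targets, multiplier 3, bias 2, the degree KS
test rejects in $\ge 90\%$ of 50 seeds. What they do not show: the
published network-dependent numbers (mean degrees 17.77 / 11.85 / 36.31,
motif counts 30/30/7/91, the KS p-values) depend on undeposited data and
cannot be verified; they guide the generators' qualitative ordering
only. The overlap-enrichment numbers, by contrast, depend only on
printed parameters and are reproduced exactly by
`overlap_replication()`.

## 5. Problem sizes and determinism

The test suite and drivers use sizes chosen to exercise every code path
while remaining quick on a single CPU: exhaustive enumeration oracles up
to $N = 14$ (about 1,000 parameter tuples), 100 random graphs of up to
50 nodes against the brute-force peeling oracle, 1,000 spiked and 1,000
motif-free 1 kb promoters, 2,000 KS null replicates, and 50
planted-network seeds at the 600-node study condition. Every random step
takes an explicit seed, so all results in the `analysis/` drivers and
the acceptance script are reproducible run-to-run.

## 6. Known limitations

* No multiple-testing correction anywhere — raw p-values are reported,
  matching the analysis being reproduced; add `p.adjust()` downstream if
  comparisons multiply.
* Identifier matching is purely lexical; lists using different
  nomenclatures must be harmonized upstream.
* Motif scanning is consensus-based (a word either matches or not);
  position weight matrices and motif discovery are out of scope, as is
  extracting promoter windows from genome assemblies — sequences arrive
  pre-extracted, and elements outside the supplied window are invisible.
* The asymptotic KS p-value is conservative on heavily tied discrete
  features (see above); exact/permutation p-values are not provided.
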