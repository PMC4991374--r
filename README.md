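# foxotools

Analyses for transcription-factor direct-target gene sets, built around
DAF-16, the *C. elegans* FOXO ortholog at the center of insulin-signaling
lifespan regulation. A *direct target* is a gene both differentially
expressed under the factor and bound by it at its promoter. Given such a
target list, three standard questions arise, and this package answers
each with a tested, reusable implementation:

1. **Overlap enrichment** — does the list share more genes with an
   earlier screen than chance? For sets of sizes *m* and *n* from an
   *N*-gene universe (the worm genome, approximated as *N* = 20000), the
   overlap *X* is hypergeometric and the test is the exact upper tail

   *P*(*X* ≥ *k*) = 1 − Σ<sub>i&lt;k</sub> C(m,i)·C(N−m,n−i)/C(N,n),

   with chance expectation *mn/N*, computed in log space so it is exact
   at genome scale. Exclusion lists are removed from both sets first
   (the treatment needed when part of a comparison screen derives from
   the target collection itself).
2. **Promoter motifs** — do the 1 kb promoter windows carry the DAF-16
   binding element (DBE, `GTAAACA`/`TGTTTAC`; degenerate form `RTAAAYA`)
   or the PQM-1-recognized DAF-16 associated element (DAE,
   `TGATAAG`/`CTTATCA`)? An IUPAC consensus scanner reports every match
   with its offset and classifies genes as DBE-only / DAE-only / both /
   neither.
3. **Network topology** — do the targets sit in a distinguished position
   of the protein-interaction network? Per-node degree, K-core coreness
   and target-neighbor ratio are profiled, and targets are compared with
   the rest of the network feature-by-feature with the two-sample
   Kolmogorov-Smirnov test.

Because the study's real inputs are not deposited, seeded synthetic-data
generators (`gen_overlap_pair()`, `gen_promoters()`,
`gen_planted_hub_network()`) emulate every input with recorded ground
truth, so the whole pipeline is exercised without downloads. The methods
vignette (`vignettes/daf16-target-analyses.Rmd`) documents the models,
parameter choices and limitations.

## Worked example

The six published comparisons of the 109-gene direct-target list are
fully determined by their printed parameters, so they can be recomputed
from scratch:

```r
library(foxotools)
overlap_replication()
```

```
      comparison    m   n  k     N published_expected published_p expected      p_value
  microarray_514  514 109 18 20000               2.80    0.000000  2.80130 3.420882e-10
 microarray_3396 3396 109 31 20000              18.50    0.001900 18.50820 1.938146e-03
   proteomics_86   86 109 12 20000               0.47    0.000000  0.46870 4.031626e-14
        damid_65   65  95  6 20000               0.31    0.000000  0.30875 6.451808e-07
      genage_681  681 109 17 20000               3.71    0.000000  3.71145 1.603174e-07
        gendr_48   48 109  4 20000               0.26    0.000135  0.26160 1.350339e-04
```

Each row is one comparison: e.g. the last says 4 of 48
dietary-restriction lifespan genes were among the 109 targets where only
0.26 would be expected by chance (p = 1.35e-4). The computed `expected`
column matches every published value at printed precision; a published p
of 0 means "below reporting precision", and the `p_value` column shows
the true tail instead. The full file-based path does the same from gene
lists on disk:

```r
pair <- gen_overlap_pair(N = 20000, m = 681, n = 109, k = 17, seed = 1,
                         dir = "results/data/overlap_pair")
s1 <- read_gene_list(pair$paths[["set1"]])
s2 <- read_gene_list(pair$paths[["set2"]])
compute_overlap(s1, s2, N = 20000)
#> overlap 'set1' (m = 681) vs 'set2' (n = 109), N = 20000:
#>   k = 17 observed, 3.71 expected by chance, p = 1.6e-07
```

## Analysis drivers

The `analysis/` scripts run the three analyses end to end on synthetic
inputs and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # seeded inputs + ground truth
Rscript analysis/02_overlap_enrichment.R  # replication table + file-based run
Rscript analysis/03_motif_scan.R          # DBE/DAE hits and classification
Rscript analysis/04_network_topology.R    # per-node topology + group summary
```

`03` reports the planted classification `DBE_only 23, DAE_only 23,
both 7, neither 56` with every spiked word recovered at its exact
offset; `04` recovers the planted hub signal (targets' mean degree 22.3
vs 7.5 network-wide, KS p ≪ 0.05).

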