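#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: a gene-set pair with a planted overlap at the longevity-list
# comparison sizes, 109 1 kb promoters with DBE/DAE words spiked to the
# observed classification pattern, and an interaction network with a
# planted high-degree, mutually interacting target subset. All three are
# seeded and come with ground-truth JSON sidecars.

suppressMessages(library(foxotools))

out_root <- "results/data"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

## 1. Overlap pair: 681-gene longevity list vs 109 targets, 17 shared
pair <- gen_overlap_pair(N = 20000, m = 681, n = 109, k = 17, seed = 211,
                         dir = file.path(out_root, "overlap_pair"))
cat("overlap pair: |set1| =", length(pair$set1),
    "|set2| =", length(pair$set2),
    "planted k =", pair$truth$k, "\n")

## 2. Promoters: 109 genes; 23 DBE-only, 23 DAE-only, 7 both, 56 neither
##    (so 30 genes carry a DBE and 30 carry a DAE, 7 of them both)
dbe_words <- c("GTAAACA", "TGTTTAC")
dae_words <- c("TGATAAG", "CTTATCA")
set.seed(223)
genes_dbe <- 1:23
genes_dae <- 24:46
genes_both <- 47:53
offsets <- function(n) sample(980, n)
spikes <- rbind(
  data.frame(gene_index = genes_dbe, motif = "DBE",
             word = sample(dbe_words, 23, replace = TRUE),
             offset = offsets(23)),
  data.frame(gene_index = genes_dae, motif = "DAE",
             word = sample(dae_words, 23, replace = TRUE),
             offset = offsets(23)),
  data.frame(gene_index = genes_both, motif = "DBE",
             word = sample(dbe_words, 7, replace = TRUE),
             offset = sample(480, 7)),
  data.frame(gene_index = genes_both, motif = "DAE",
             word = sample(dae_words, 7, replace = TRUE),
             offset = 500 + sample(480, 7))
)
prom <- gen_promoters(109, length = 1000, spikes = spikes, seed = 227,
                      dir = file.path(out_root, "promoters"))
cat("promoters:", nrow(prom$promoters), "records,",
    nrow(prom$truth$spikes), "planted motif words\n")

## 3. Interaction network: 600 nodes, 60 targets wired as hubs
net <- gen_planted_hub_network(n_nodes = 600, background_mean_degree = 6,
                               target_count = 60, degree_multiplier = 3,
                               within_target_bias = 2, seed = 229,
                               dir = file.path(out_root, "network"))
# a lifespan-regulating-like subset of the targets
sub <- gene_set(net$targets$members[1:17], "targets_lifespan")
write_gene_list(sub, file.path(out_root, "network", "subgroup.txt"))
cat("network:", igraph::vcount(net$network), "nodes,",
    igraph::ecount(net$network), "edges,",
    length(net$targets), "planted targets\n")
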