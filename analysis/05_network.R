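#!/usr/bin/env Rscript
# Co-abundance network of genera: edges require Spearman |r| > 0.5 and a
# sparCC permutation p-value surviving BH control at 5%; groups are
# connected components over the positive edges.

library(dogbiome)

seed <- as.integer(Sys.getenv("DOGBIOME_SEED", "1"))
abund <- read_abundance_tsv("results/data/abundance.tsv")
meta <- read_metadata_tsv("results/data/metadata.tsv")
lineages <- read.delim("results/data/lineages.tsv")

genus <- aggregate_rank(abund, lineages, "genus",
                        keep_unassigned = FALSE)
net <- build_network(genus, n_permutations = 999, seed = seed)
write_network_tsv(net, "results/network_edges.tsv")
write_network_graphml(net, "results/network.graphml")

grp <- network_groups(net, genus)
multi <- table(grp$membership)
multi <- multi[multi > 1]
message(sprintf("network: %d edges (%d negative) over %d genera; %d multi-genus groups",
                nrow(net$edges), sum(net$edges$sign == "negative"),
                length(net$nodes), length(multi)))
for (k in names(multi)) {
  message("  group ", k, ": ",
          paste(names(grp$membership)[grp$membership == as.integer(k)],
                collapse = ", "))
}
if (!is.null(grp$group_abundance)) {
  diet <- meta$diet[match(colnames(genus), meta$sample_id)]
  med <- apply(grp$group_abundance, 1, function(r) tapply(r, diet, median))
  write.table(data.frame(diet = rownames(med), med),
              "results/network_group_abundance.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
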