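#!/usr/bin/env Rscript
# Ordination of the genus-level profiles: Bray-Curtis distances on
# log-transformed data, principal coordinates, and a PERMANOVA for the
# diet effect across the Base / HPLC / LPHC sampling groups.

library(dogbiome)

seed <- as.integer(Sys.getenv("DOGBIOME_SEED", "1"))
abund <- read_abundance_tsv("results/data/abundance.tsv")
meta <- read_metadata_tsv("results/data/metadata.tsv")
lineages <- read.delim("results/data/lineages.tsv")

genus <- aggregate_rank(abund, lineages, "genus")
lg <- log_transform(genus)
D <- distance_matrix(lg - min(lg), "bray_curtis")
ord <- pcoa(D, k = 2)
diet <- meta$diet[match(colnames(genus), meta$sample_id)]
pm <- permanova(D, diet, n_permutations = 999, seed = seed)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       diet = diet, ord$coordinates),
            "results/pcoa_coordinates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_abundance_tsv(D, "results/bray_curtis.tsv")

rel <- ord$eigenvalues[1:2] / sum(pmax(ord$eigenvalues, 0))
message(sprintf("PCo1/PCo2 explain %.1f%% and %.1f%% of the (positive) inertia",
                100 * rel[1], 100 * rel[2]))
message(sprintf("PERMANOVA diet effect: pseudo-F = %.2f, p = %.4g (999 permutations)",
                pm$pseudo_F, pm$p_value))
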