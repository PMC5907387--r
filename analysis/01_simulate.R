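#!/usr/bin/env Rscript
# Generate the synthetic paired dietary-intervention study under the
# default design: 64 dogs of two breeds, half overweight, a shared
# baseline diet, randomization to HPLC or LPHC, detection limit 2e-5,
# diet effects planted on specific clades with a doubled response for
# overweight dogs on HPLC. Downstream scripts read the tables this writes.

library(dogbiome)

seed <- as.integer(Sys.getenv("DOGBIOME_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- study_config(seed = seed)
study <- simulate_study(config)

write_abundance_tsv(study$abundance, file.path(out, "abundance.tsv"))
write_abundance_tsv(study$abundance_raw, file.path(out, "abundance_raw.tsv"))
write_metadata_tsv(study$metadata, file.path(out, "metadata.tsv"))
write.table(study$lineages, file.path(out, "lineages.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, detection_limit = config$detection_limit,
       effects = as.data.frame(study$truth$effects),
       dog_diet = as.list(study$truth$dog_diet),
       dog_condition = as.list(study$truth$dog_condition)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

n_cens <- sum(study$abundance == 0)
message(sprintf("simulated %d dogs x %d taxa (seed %d); %d entries (%.1f%%) below the 2e-5 detection limit",
                config$n_dogs, config$n_taxa, seed, n_cens,
                100 * n_cens / length(study$abundance)))
message("wrote abundance, metadata, lineages and truth to ", out)
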