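#' Default taxon panel for synthetic studies
#'
#' A small panel of genera typical of the canine gut, with their phylum and
#' order, used to spread the configured number of synthetic species across
#' recognizable clades so that rank aggregation, taxon-ratio tests and
#' network grouping have meaningful labels to work with.
#'
#' @return data.frame with columns `genus`, `family`, `order`, `class`,
#'   `phylum`.
#' @export
default_taxon_panel <- function() {
  data.frame(
    genus  = c("Prevotella", "Bacteroides", "Clostridium", "Blautia",
               "Faecalibacterium", "Turicibacter", "Megamonas",
               "Lactobacillus", "Streptococcus", "Fusobacterium",
               "Sutterella", "Collinsella"),
    family = c("Prevotellaceae", "Bacteroidaceae", "Clostridiaceae",
               "Lachnospiraceae", "Ruminococcaceae", "Turicibacteraceae",
               "Veillonellaceae", "Lactobacillaceae", "Streptococcaceae",
               "Fusobacteriaceae", "Sutterellaceae", "Coriobacteriaceae"),
    order  = c("Bacteroidales", "Bacteroidales", "Clostridiales",
               "Clostridiales", "Clostridiales", "Erysipelotrichales",
               "Selenomonadales", "Lactobacillales", "Lactobacillales",
               "Fusobacteriales", "Burkholderiales", "Coriobacteriales"),
    class  = c("Bacteroidia", "Bacteroidia", "Clostridia", "Clostridia",
               "Clostridia", "Erysipelotrichia", "Negativicutes", "Bacilli",
               "Bacilli", "Fusobacteriia", "Betaproteobacteria",
               "Coriobacteriia"),
    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Fusobacteria", "Proteobacteria",
               "Actinobacteria"),
    stringsAsFactors = FALSE
  )
}

#' Default planted diet effects
#'
#' Log2 fold changes applied at the genus level (every species of the genus
#' inherits the effect). The high-protein/low-carbohydrate (HPLC) arm
#' carries the strong effects — saccharolytic genera (Lactobacillus,
#' Prevotella, Faecalibacterium, Megamonas) suppressed, proteolytic-leaning
#' genera (Streptococcus, Turicibacter, Clostridium, Blautia, Fusobacterium)
#' enriched — while the lower-protein/higher-carbohydrate (LPHC) arm gets a
#' milder push in the opposite direction. This concentrates the response in
#' a handful of clades, raises the Firmicutes:Bacteroidetes ratio under
#' HPLC, and lowers Prevotella:Bacteroides under HPLC relative to baseline
#' and LPHC.
#'
#' @return named list: genus -> named numeric vector of log2 fold changes
#'   keyed by diet.
#' @export
default_effect_map <- function() {
  list(
    Lactobacillus    = c(HPLC = -3.0, LPHC = 0.8),
    Prevotella       = c(HPLC = -2.5, LPHC = 1.0),
    Streptococcus    = c(HPLC = 2.5, LPHC = -0.5),
    Turicibacter     = c(HPLC = 2.0),
    Clostridium      = c(HPLC = 1.5, LPHC = -0.5),
    Blautia          = c(HPLC = 1.0),
    Faecalibacterium = c(HPLC = -1.0),
    Megamonas        = c(HPLC = -1.5, LPHC = 0.8),
    Fusobacterium    = c(HPLC = 1.0),
    Bacteroides      = c(HPLC = 0.5)
  )
}

#' Configuration of a synthetic paired dietary-intervention study
#'
#' Defaults reproduce the design of the study the package models: 64 dogs
#' of two breeds, half overweight (OW) and half lean/normal (LN), a shared
#' baseline diet followed by random assignment to one of two intervention
#' diets (HPLC or LPHC), paired baseline/post stool profiles, a relative-
#' abundance detection limit of 2e-5, diet effects concentrated on specific
#' clades, and a doubled response of OW dogs under HPLC.
#'
#' @param n_dogs number of dogs (each contributes one baseline and one post
#'   sample).
#' @param breeds character vector of breed labels, cycled over dogs.
#' @param condition_fraction_ow fraction of dogs in the overweight (OW)
#'   body-condition group; the rest are lean/normal (LN).
#' @param diets diet labels; the first is the baseline diet, the remainder
#'   are the intervention arms dogs are randomized to.
#' @param n_taxa number of species-level features.
#' @param detection_limit relative abundance below which a value is
#'   recorded as exactly zero.
#' @param effect_map named list mapping a genus or feature id to a named
#'   numeric vector of log2 fold changes keyed by intervention diet.
#' @param ow_response_multiplier scalar >= 1; scales the planted-effect mean
#'   and variance for OW dogs on HPLC.
#' @param dog_effect_sd log10-scale SD of the per-dog, per-taxon random
#'   effect (shared between a dog's two samples).
#' @param noise_sd log10-scale SD of per-sample measurement noise.
#' @param effect_sd log2-scale SD of the per-dog realization of each
#'   planted effect.
#' @param seed integer seed; the configuration fully determines the study.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_dogs = 64,
                         breeds = c("Labrador_retriever", "Beagle"),
                         condition_fraction_ow = 0.5,
                         diets = c("Base", "HPLC", "LPHC"),
                         n_taxa = 96,
                         detection_limit = 2e-5,
                         effect_map = default_effect_map(),
                         ow_response_multiplier = 2,
                         dog_effect_sd = 0.5,
                         noise_sd = 0.3,
                         effect_sd = 0.4,
                         seed = 42L) {
  if (n_dogs < 2) stop("n_dogs must be >= 2")
  if (detection_limit <= 0 || detection_limit >= 1) {
    stop("detection_limit must lie in (0, 1)")
  }
  if (ow_response_multiplier < 1) stop("ow_response_multiplier must be >= 1")
  if (length(diets) < 2) stop("need a baseline diet plus >= 1 intervention diet")
  fc <- unlist(effect_map)
  if (length(fc) && any(!is.finite(fc))) stop("all fold changes must be finite")
  structure(list(
    n_dogs = as.integer(n_dogs), breeds = breeds,
    condition_fraction_ow = condition_fraction_ow, diets = diets,
    n_taxa = as.integer(n_taxa), detection_limit = detection_limit,
    effect_map = effect_map, ow_response_multiplier = ow_response_multiplier,
    dog_effect_sd = dog_effect_sd, noise_sd = noise_sd, effect_sd = effect_sd,
    seed = as.integer(seed)
  ), class = "study_config")
}

# Build the species-level lineage table for a configured number of taxa.
build_lineages <- function(n_taxa, panel = default_taxon_panel()) {
  idx <- rep_len(seq_len(nrow(panel)), n_taxa)
  sp <- sprintf("sp%03d", seq_len(n_taxa))
  data.frame(
    feature = sp,
    superkingdom = "Bacteria",
    phylum = panel$phylum[idx], class = panel$class[idx],
    order = panel$order[idx], family = panel$family[idx],
    genus = panel$genus[idx],
    species = paste(panel$genus[idx], sp, sep = "_"),
    stringsAsFactors = FALSE, row.names = sp
  )
}

# Expand a genus/feature-keyed effect map into a feature x diet matrix of
# log2 fold changes; errors on keys matching neither a genus nor a feature.
expand_effect_map <- function(effect_map, lineages, diets) {
  eff <- matrix(0, nrow(lineages), length(diets),
                dimnames = list(lineages$feature, diets))
  for (key in names(effect_map)) {
    hit <- if (key %in% lineages$genus) {
      lineages$feature[lineages$genus == key]
    } else if (key %in% lineages$feature) {
      key
    } else {
      stop("effect_map references unknown taxon: ", key)
    }
    v <- effect_map[[key]]
    unknown <- setdiff(names(v), diets)
    if (length(unknown)) stop("effect_map references unknown diet: ", unknown[1])
    for (d in names(v)) eff[hit, d] <- eff[hit, d] + v[[d]]
  }
  eff
}

#' Simulate a paired dietary-intervention study
#'
#' Generates log-normal baseline taxon loads per dog (per-dog random effect
#' plus per-sample noise around long-tailed taxon means), multiplies
#' post-intervention loads by `2^effect` where each dog realizes its diet's
#' planted log2 fold change with configurable spread (mean and variance
#' scaled by `ow_response_multiplier` for OW dogs on HPLC), closes each
#' sample to relative abundances, and zeroes values below the detection
#' limit.
#'
#' @param config a [study_config()].
#' @return list of class `dog_study` with elements `abundance` (censored
#'   relative abundances, features x samples), `abundance_raw` (before
#'   detection-limit zeroing), `metadata` (one row per sample), `lineages`,
#'   `truth` (planted and realized effects, taxon means), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, {
    n <- config$n_dogs
    dogs <- sprintf("dog%02d", seq_len(n))
    breed <- rep_len(config$breeds, n)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    # stratify body condition within breed, then randomize diet within
    # breed x condition, mirroring the study's randomization
    condition <- character(n)
    cohort <- integer(n)
    for (b in unique(breed)) {
      i <- which(breed == b)
      n_ow <- round(length(i) * config$condition_fraction_ow)
      condition[i] <- sample(rep(c("OW", "LN"), c(n_ow, length(i) - n_ow)))
      cohort[i] <- sample(rep_len(1:2, length(i)))
    }
    arms <- config$diets[-1]
    diet <- character(n)
    arm_count <- stats::setNames(integer(length(arms)), arms)
    for (b in unique(breed)) for (cc in unique(condition)) {
      i <- which(breed == b & condition == cc)
      if (!length(i)) next
      # keep overall arm sizes balanced when strata are odd-sized
      alloc <- rep(arms[order(arm_count)], length.out = length(i))
      diet[i] <- sample(alloc)
      arm_count <- arm_count + table(factor(diet[i], levels = arms))
    }

    lineages <- build_lineages(config$n_taxa)
    taxa <- lineages$feature
    eff <- expand_effect_map(config$effect_map, lineages, config$diets)

    # long-tailed baseline means on the log10 scale
    mu <- stats::rnorm(config$n_taxa, mean = 0, sd = 1.6)
    names(mu) <- taxa
    b_dog <- matrix(stats::rnorm(config$n_taxa * n, 0, config$dog_effect_sd),
                    config$n_taxa, n, dimnames = list(taxa, dogs))
    mult <- ifelse(condition == "OW" & diet == "HPLC",
                   config$ow_response_multiplier, 1)
    # realized per-dog effect (log2): mean and variance scale with mult
    planted <- eff[, diet, drop = FALSE] != 0
    realized <- sweep(eff[, diet, drop = FALSE], 2L, mult, "*") +
      matrix(stats::rnorm(config$n_taxa * n, 0, config$effect_sd),
             config$n_taxa, n) *
        rep(sqrt(mult), each = config$n_taxa) * planted
    dimnames(realized) <- list(taxa, dogs)
    realized[!planted] <- 0

    log_base <- mu + b_dog +
      matrix(stats::rnorm(config$n_taxa * n, 0, config$noise_sd), config$n_taxa, n)
    log_post <- mu + b_dog +
      matrix(stats::rnorm(config$n_taxa * n, 0, config$noise_sd), config$n_taxa, n) +
      realized * log10(2)

    raw <- close_columns(cbind(10^log_base, 10^log_post))
    sample_ids <- c(paste0(dogs, "_baseline"), paste0(dogs, "_post"))
    colnames(raw) <- sample_ids
    censored <- raw
    censored[censored < config$detection_limit] <- 0

    metadata <- data.frame(
      sample_id = sample_ids,
      dog_id = rep(dogs, 2L), breed = rep(breed, 2L), sex = rep(sex, 2L),
      condition = rep(condition, 2L),
      diet = c(rep(config$diets[1], n), diet),
      intervention_diet = rep(diet, 2L),
      timepoint = rep(c("baseline", "post"), each = n),
      cohort = rep(cohort, 2L),
      stringsAsFactors = FALSE
    )
    truth <- list(
      effects = eff, realized_effects = realized, planted = planted,
      taxon_means = mu, dog_diet = stats::setNames(diet, dogs),
      dog_condition = stats::setNames(condition, dogs),
      detection_limit = config$detection_limit
    )
    structure(list(abundance = censored, abundance_raw = raw,
                   metadata = metadata, lineages = lineages, truth = truth,
                   config = config),
              class = "dog_study")
  })
}

#' Simulate single-copy marker genes from species loads
#'
#' Each species emits one gene per marker-gene family; a gene's base-scaled
#' count in a sample is the species load times the gene length times
#' log-normal noise, so length-normalized counts of genes from the same
#' species co-vary across samples.
#'
#' @param species_abundance species x sample matrix of (relative) loads.
#' @param n_families number of single-copy families (>= 2; the reference
#'   scheme uses 10).
#' @param length_range integer range of gene lengths in base pairs.
#' @param noise_sd log10-scale SD of multiplicative count noise.
#' @param seed integer seed.
#' @return object of class `marker_gene_table`: list with `genes`
#'   (gene_id, family, length, species) and `counts` (gene x sample).
#' @export
simulate_marker_genes <- function(species_abundance, n_families = 10,
                                  length_range = c(500L, 1500L),
                                  noise_sd = 0.1, seed = 1L) {
  if (NROW(species_abundance) == 0L) stop("empty species set")
  stopifnot_matrix(species_abundance, "species_abundance")
  if (n_families < 2) stop("n_families must be >= 2")
  with_seed(seed, {
    species <- rownames(species_abundance)
    fams <- sprintf("COG%02d", seq_len(n_families))
    genes <- expand.grid(species = species, family = fams,
                         stringsAsFactors = FALSE)
    genes$gene_id <- paste(genes$species, genes$family, sep = ".")
    genes$length <- sample(length_range[1]:length_range[2], nrow(genes),
                           replace = TRUE)
    genes <- genes[, c("gene_id", "family", "length", "species")]
    noise <- matrix(10^stats::rnorm(nrow(genes) * ncol(species_abundance),
                                    0, noise_sd),
                    nrow(genes), ncol(species_abundance))
    counts <- species_abundance[genes$species, , drop = FALSE] *
      genes$length * noise
    dimnames(counts) <- list(genes$gene_id, colnames(species_abundance))
    marker_gene_table(genes, counts)
  })
}

#' Simulate per-sample SNP allele-frequency profiles for two host groups
#'
#' Positions receive a base major-allele frequency; group B's means are
#' shifted by `between_shift` (clipped into \[0, 1\] with a warning if the
#' shift overshoots); samples scatter around their group mean with SD
#' `within_sd` and are clipped into \[0, 1\].
#'
#' @param n_group_a,n_group_b samples per group.
#' @param n_positions number of SNP positions (>= 1).
#' @param within_sd within-group SD of per-sample frequencies.
#' @param between_shift separation of the two group means.
#' @param seed integer seed.
#' @param mean_depth,breadth coverage summaries attached to every sample
#'   (defaults pass the 5x / 80% gate).
#' @return list with `freqs` (position x sample), `groups`, `coverage`.
#' @export
simulate_allele_freqs <- function(n_group_a, n_group_b, n_positions,
                                  within_sd = 0.05, between_shift = 0.5,
                                  seed = 1L, mean_depth = 20, breadth = 0.95) {
  if (n_positions < 1) stop("n_positions must be >= 1")
  with_seed(seed, {
    base <- stats::runif(n_positions, 0.05, 0.45)
    mean_b <- base + between_shift
    if (any(mean_b < 0 | mean_b > 1)) {
      warning("between_shift places some group means outside [0, 1]; clipped")
      mean_b <- pmin(pmax(mean_b, 0), 1)
    }
    n <- n_group_a + n_group_b
    means <- cbind(matrix(base, n_positions, n_group_a),
                   matrix(mean_b, n_positions, n_group_b))
    freqs <- means + matrix(stats::rnorm(n_positions * n, 0, within_sd),
                            n_positions, n)
    freqs <- pmin(pmax(freqs, 0), 1)
    ids <- c(sprintf("hostA_%02d", seq_len(n_group_a)),
             sprintf("hostB_%02d", seq_len(n_group_b)))
    dimnames(freqs) <- list(sprintf("pos%05d", seq_len(n_positions)), ids)
    list(freqs = freqs,
         groups = stats::setNames(rep(c("A", "B"), c(n_group_a, n_group_b)), ids),
         coverage = data.frame(sample_id = ids, mean_depth = mean_depth,
                               breadth = breadth, stringsAsFactors = FALSE))
  })
}

#' Maintenance energy requirement of a dog
#'
#' The allometric feeding equation MER = 139 x BW^exponent (kcal/day), with
#' body weight in kilograms. The exponent defaults to the conventional 0.75
#' metabolic-scaling value and is configurable.
#'
#' @param body_weight_kg body weight in kg (> 0).
#' @param exponent allometric exponent.
#' @return kilocalories per day.
#' @export
maintenance_energy <- function(body_weight_kg, exponent = 0.75) {
  if (any(body_weight_kg <= 0)) stop("body weight must be positive")
  139 * body_weight_kg^exponent
}
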