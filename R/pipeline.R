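#' Pipeline configuration
#'
#' Collects everything one analysis run needs: either a simulation block
#' (a [study_config()] or a list of its arguments) or paths to input
#' tables, per-stage toggles, stage parameters and an output directory.
#' Configurations round-trip through YAML via [read_pipeline_config()].
#'
#' @param simulation a [study_config()] or list of arguments for it;
#'   mutually exclusive with `input`.
#' @param input list with paths `abundance`, `metadata`, `lineages`
#'   (TSV); mutually exclusive with `simulation`.
#' @param stages named logical toggles; defaults enable `ordinate`,
#'   `shifts`, `gehan`, `prevalence`, `network`, `classify`, `motu`,
#'   `strain`.
#' @param params named list of per-stage parameter overrides
#'   (`gehan$n_permutations`, `network$n_permutations`,
#'   `permanova$n_permutations`, `classify$alpha`, ...).
#' @param outdir output directory (created on run); NULL = no files
#'   written.
#' @param seed base seed; per-stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input = NULL,
                            stages = list(), params = list(),
                            outdir = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(input)) {
    stop("exactly one of `simulation` and `input` must be given")
  }
  if (!is.null(input)) {
    need <- c("abundance", "metadata", "lineages")
    if (!all(need %in% names(input))) {
      stop("input block needs paths: ", paste(need, collapse = ", "))
    }
    missing <- !vapply(input[need], file.exists, logical(1))
    if (any(missing)) {
      stop("missing input file(s): ",
           paste(unlist(input[need][missing]), collapse = ", "))
    }
  }
  defaults <- list(ordinate = TRUE, shifts = TRUE, gehan = TRUE,
                   prevalence = TRUE, network = TRUE, classify = TRUE,
                   motu = TRUE, strain = TRUE)
  defaults[names(stages)] <- stages
  structure(list(simulation = simulation, input = input, stages = defaults,
                 params = params, outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with blocks `simulation` or `input`, plus
#'   optional `stages`, `params`, `outdir`, `seed`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(simulation = y$simulation, input = y$input,
                  stages = if (is.null(y$stages)) list() else y$stages,
                  params = if (is.null(y$params)) list() else y$params,
                  outdir = y$outdir,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}

pipeline_param <- function(config, stage, name, default) {
  v <- config$params[[stage]][[name]]
  if (is.null(v)) default else v
}

pipeline_write <- function(outdir, name, obj) {
  if (is.null(outdir)) return(invisible(NULL))
  path <- file.path(outdir, name)
  if (grepl("\\.json$", name)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (is.matrix(obj)) {
    write_abundance_tsv(obj, path)
  } else {
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Run the full dietary-intervention analysis
#'
#' Executes the enabled stages in dependency order on simulated or
#' ingested data: genus/phylum aggregation and ordination (PCoA +
#' PERMANOVA), paired compositional shifts with subgroup comparisons and
#' taxon-ratio tests, the censored-ratio Gehan screen with two-stage BH
#' correction, prevalence-change tests, the sparCC/Spearman co-abundance
#' network with positive-edge groups, the leave-one-out diet classifier,
#' marker-gene (mOTU) profiling, and strain-level SNP ordination. Every
#' stage draws its own seed derived from the base seed, logs its inputs
#' and row counts, and (when `outdir` is set) writes its artifacts plus a
#' machine-readable `summary.json`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_report` with per-stage results and a
#'   `summary` list of headline numbers.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[dogbiome] ", ...)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  seed <- config$seed
  report <- list(stages_run = character(0))
  summary <- list(seed = seed, schema_version = 1L)

  # ---- data ----
  if (!is.null(config$simulation)) {
    sc <- if (inherits(config$simulation, "study_config")) {
      config$simulation
    } else {
      do.call(study_config, c(config$simulation, list(seed = seed)))
    }
    study <- simulate_study(sc)
    abund <- study$abundance
    metadata <- study$metadata
    lineages <- study$lineages
    report$truth <- study$truth
    say("simulated study: ", sc$n_dogs, " dogs, ", sc$n_taxa, " taxa")
  } else {
    study <- NULL
    abund <- read_abundance_tsv(config$input$abundance)
    metadata <- read_metadata_tsv(config$input$metadata)
    lineages <- utils::read.delim(config$input$lineages,
                                  stringsAsFactors = FALSE)
    say("loaded ", nrow(abund), " features x ", ncol(abund), " samples")
  }
  pipeline_write(outdir, "abundance.tsv", abund)
  pipeline_write(outdir, "metadata.tsv", metadata)
  report$abundance <- abund
  report$metadata <- metadata
  report$lineages <- lineages

  genus <- aggregate_rank(abund, lineages, "genus")
  phylum <- aggregate_rank(abund, lineages, "phylum")
  sampling_diet <- metadata$diet[match(colnames(abund), metadata$sample_id)]

  # ---- ordination ----
  if (isTRUE(config$stages$ordinate)) {
    lg <- log_transform(genus)
    D <- distance_matrix(lg - min(lg), "bray_curtis")
    ord <- pcoa(D, k = 2L)
    pm <- permanova(D, sampling_diet,
                    n_permutations = pipeline_param(config, "permanova",
                                                    "n_permutations", 999L),
                    seed = seed + 101L)
    report$ordination <- list(pcoa = ord, permanova = pm, distance = D)
    summary$permanova_diet_p <- pm$p_value
    summary$permanova_pseudo_F <- pm$pseudo_F
    pipeline_write(outdir, "pcoa_coordinates.tsv",
                   data.frame(sample_id = rownames(ord$coordinates),
                              ord$coordinates))
    say("ordinate: PERMANOVA diet p = ", signif(pm$p_value, 3))
    report$stages_run <- c(report$stages_run, "ordinate")
  }

  # ---- paired shifts + ratios ----
  if (isTRUE(config$stages$shifts)) {
    shifts <- paired_shift(genus, metadata)
    diet_cmp <- compare_shifts(shifts, list(diet = "HPLC"))
    ow_cmp <- compare_shifts(shifts, list(diet = "HPLC", condition = "OW"))
    med <- stats::aggregate(shift ~ diet + condition, shifts, stats::median)
    largest <- med[which.max(med$shift), ]
    fb <- ratio_test(phylum, "Firmicutes", "Bacteroidetes",
                     groups = sampling_diet)
    pb <- ratio_test(genus, "Prevotella", "Bacteroides",
                     groups = sampling_diet)
    report$shifts <- list(table = shifts, hplc_vs_lphc = diet_cmp,
                          hplc_ow_vs_rest = ow_cmp, medians = med,
                          firmicutes_bacteroidetes = fb,
                          prevotella_bacteroides = pb)
    summary$shift_hplc_vs_lphc_p <- diet_cmp$p.value
    summary$shift_hplc_ow_vs_rest_p <- ow_cmp$p.value
    summary$largest_shift_group <- paste(largest$diet, largest$condition,
                                         sep = "/")
    summary$fb_ratio_test_p <- fb$test$p.value
    summary$pb_ratio_test_p <- pb$test$p.value
    pipeline_write(outdir, "paired_shifts.tsv", shifts)
    say("shifts: HPLC vs LPHC p = ", signif(diet_cmp$p.value, 3),
        "; largest subgroup ", summary$largest_shift_group)
    report$stages_run <- c(report$stages_run, "shifts")
  }

  # ---- censored-ratio Gehan screen ----
  if (isTRUE(config$stages$gehan)) {
    scr <- gehan_screen(abund, metadata,
                        n_permutations = pipeline_param(config, "gehan",
                                                        "n_permutations",
                                                        999L),
                        seed = seed + 202L)
    report$gehan <- scr
    summary$gehan_n_rejected <- sum(scr$rejected)
    summary$gehan_top_feature <- scr$feature[1]
    pipeline_write(outdir, "gehan_screen.tsv", scr)
    say("gehan: ", sum(scr$rejected), " features rejected at two-stage BH")
    report$stages_run <- c(report$stages_run, "gehan")
  }

  # ---- prevalence changes ----
  if (isTRUE(config$stages$prevalence)) {
    prev <- prevalence_test(abund > 0, sampling_diet)
    report$prevalence <- prev
    summary$prevalence_n_significant <- sum(prev$significant)
    pipeline_write(outdir, "prevalence.tsv", prev)
    say("prevalence: ", sum(prev$significant),
        " taxon/diet-pair effects after Bonferroni")
    report$stages_run <- c(report$stages_run, "prevalence")
  }

  # ---- co-abundance network ----
  if (isTRUE(config$stages$network)) {
    net <- build_network(genus[rownames(genus) != "unassigned", ,
                               drop = FALSE],
                         n_permutations = pipeline_param(config, "network",
                                                         "n_permutations",
                                                         499L),
                         seed = seed + 303L)
    grp <- network_groups(net, genus)
    n_multi <- sum(table(grp$membership) > 1L)
    report$network <- list(network = net, groups = grp)
    summary$network_n_edges <- nrow(net$edges)
    summary$network_n_groups <- n_multi
    pipeline_write(outdir, "network_edges.tsv", net$edges)
    say("network: ", nrow(net$edges), " edges, ", n_multi, " groups")
    report$stages_run <- c(report$stages_run, "network")
  }

  # ---- diet classifier ----
  if (isTRUE(config$stages$classify)) {
    post <- metadata[metadata$timepoint == "post", ]
    keep <- post$sample_id[post$diet %in% c("HPLC", "LPHC")]
    rep_cl <- loo_classify(abund[, keep, drop = FALSE],
                           post$diet[match(keep, post$sample_id)],
                           alpha = pipeline_param(config, "classify",
                                                  "alpha", 0),
                           seed = seed + 404L)
    report$classifier <- rep_cl
    summary$classifier_auc <- rep_cl$auc
    pipeline_write(outdir, "roc.tsv", rep_cl$roc)
    say("classify: LOO AUC = ", round(rep_cl$auc, 3))
    report$stages_run <- c(report$stages_run, "classify")
  }

  # ---- marker-gene (mOTU) profiling ----
  if (isTRUE(config$stages$motu)) {
    if (is.null(study)) {
      say("motu stage skipped: needs simulated species loads")
    } else {
      n_sp <- min(30L, nrow(abund))
      top <- order(-rowMeans(study$abundance_raw))[seq_len(n_sp)]
      mg <- simulate_marker_genes(study$abundance_raw[top, , drop = FALSE],
                                  noise_sd = pipeline_param(config, "motu",
                                                            "noise_sd", 0.1),
                                  seed = seed + 505L)
      groups <- link_marker_genes(mg, seed = seed + 506L)
      summary$motu_n_groups <- length(groups)
      if (length(groups)) {
        la <- lg_abundance(mg, groups)
        dl <- detection_limits(la)
        purity <- mean(vapply(groups, function(g) {
          length(unique(mg$genes$species[match(g$members,
                                               mg$genes$gene_id)])) == 1L
        }, logical(1)))
        report$motu <- list(mg = mg, groups = groups, abundance = la,
                            detection_limits = dl, purity = purity)
        summary$motu_purity <- purity
        summary$motu_global_detection_limit <- dl$global
        say("motu: ", length(groups), " linkage groups, purity ",
            round(purity, 3))
      }
      report$stages_run <- c(report$stages_run, "motu")
    }
  }

  # ---- strain-level SNP distances ----
  if (isTRUE(config$stages$strain)) {
    af <- simulate_allele_freqs(
      n_group_a = pipeline_param(config, "strain", "n_group_a", 12L),
      n_group_b = pipeline_param(config, "strain", "n_group_b", 12L),
      n_positions = pipeline_param(config, "strain", "n_positions", 400L),
      within_sd = pipeline_param(config, "strain", "within_sd", 0.05),
      between_shift = pipeline_param(config, "strain", "between_shift", 0.4),
      seed = seed + 606L)
    sp <- strain_pcoa(af$freqs, af$groups, coverage = af$coverage)
    within <- mean(sp$pairs$distance[sp$pairs$same_host])
    between <- mean(sp$pairs$distance[!sp$pairs$same_host])
    report$strain <- list(ordination = sp, within = within,
                          between = between)
    summary$strain_within_host_distance <- within
    summary$strain_between_host_distance <- between
    say("strain: within-host ", round(within, 3), " vs cross-host ",
        round(between, 3))
    report$stages_run <- c(report$stages_run, "strain")
  }

  report$summary <- summary
  pipeline_write(outdir, "summary.json", summary)
  class(report) <- "pipeline_report"
  report
}
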