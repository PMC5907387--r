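#' Marker-gene table
#'
#' Container for single-copy marker genes: a gene description table and a
#' gene-by-sample matrix of base-scaled counts.
#'
#' @param genes data.frame with columns `gene_id`, `family`, `length` (bp)
#'   and optionally `species` (ground truth from the simulator).
#' @param counts nonnegative gene x sample matrix; rownames must match
#'   `genes$gene_id`.
#' @return object of class `marker_gene_table`.
#' @export
marker_gene_table <- function(genes, counts) {
  stopifnot(all(c("gene_id", "family", "length") %in% names(genes)),
            identical(rownames(counts), genes$gene_id))
  if (any(genes$length <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(genes = genes, counts = counts), class = "marker_gene_table")
}

#' @rdname marker_gene_table
#' @param path file path; the TSV has columns `gene_id`, `family`,
#'   `length`, optionally `species`, then one column per sample.
#' @export
read_marker_genes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("gene_id", "family", "length", "species"), names(df))
  counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  mode(counts) <- "numeric"
  rownames(counts) <- df$gene_id
  marker_gene_table(df[, meta_cols, drop = FALSE], counts)
}

#' @rdname marker_gene_table
#' @param mg a `marker_gene_table`.
#' @export
write_marker_genes_tsv <- function(mg, path) {
  utils::write.table(cbind(mg$genes, mg$counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Length-normalized, log10(1 + x) transformed count matrix used for
# correlation-based linkage.
mg_log_coverage <- function(mg) {
  log10(1 + mg$counts / mg$genes$length)
}

#' Link marker genes into species-level linkage groups
#'
#' Correlates length-normalized, log-transformed marker-gene abundances
#' across all samples; a permutation null (each gene's samples shuffled
#' independently) sets the linking threshold at the smallest correlation
#' with empirical false-discovery rate at most `target_fdr`. Genes joined
#' by supra-threshold correlations are agglomerated strongest-edge-first
#' under the single-copy constraint (a group never holds two genes of one
#' family), so groups contain between 2 and K members; singletons are
#' discarded.
#'
#' @param mg a [marker_gene_table()].
#' @param target_fdr empirical FDR for the linking threshold.
#' @param n_permutations permutations for the null distribution.
#' @param seed integer seed.
#' @param method correlation flavor: `"pearson"` (default) or
#'   `"spearman"`.
#' @return list of linkage groups, each a list with `members`, `families`
#'   and `lineage` (NULL until annotated); the linking threshold is in
#'   attribute `threshold`.
#' @export
link_marker_genes <- function(mg, target_fdr = 0.02, n_permutations = 200L,
                              seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- mg_log_coverage(mg)
  n_genes <- nrow(x)
  n_samp <- ncol(x)
  if (n_samp < 8L) stop("need >= 8 samples to calibrate the permutation null")
  if (n_genes < 2L) stop("need >= 2 genes")
  ut <- upper.tri(diag(n_genes))
  obs_mat <- stats::cor(t(x), method = method)
  obs_mat[!is.finite(obs_mat)] <- 0
  obs <- obs_mat[ut]

  null_vals <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      xp <- t(apply(x, 1L, sample))
      cp <- stats::cor(t(xp), method = method)
      cp[!is.finite(cp)] <- 0
      cp[ut]
    }, numeric(sum(ut)))
  })
  null_sorted <- sort(as.numeric(null_vals))
  obs_sorted <- sort(obs, decreasing = TRUE)
  n_null <- length(null_sorted)
  # FDR(t) = expected null count >= t (add-one permutation estimator)
  # divided by the observed count >= t
  threshold <- NA_real_
  for (i in seq_along(obs_sorted)) {
    t_cand <- obs_sorted[i]
    null_ge <- n_null - findInterval(t_cand - 1e-12, null_sorted)
    fdr <- ((null_ge + 1) / (n_permutations + 1)) / i
    if (fdr <= target_fdr) threshold <- t_cand else break
  }
  groups <- list()
  if (!is.na(threshold)) {
    idx <- which(obs_mat >= threshold & ut, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(i = idx[, 1], j = idx[, 2],
                          r = obs_mat[idx])
      edges <- edges[order(-edges$r, edges$i, edges$j), ]
      fam <- mg$genes$family
      comp <- seq_len(n_genes)              # union-find, path-halving free
      find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
      members <- as.list(seq_len(n_genes))
      for (k in seq_len(nrow(edges))) {
        a <- find(edges$i[k]); b <- find(edges$j[k])
        if (a == b) next
        # single-copy constraint: merge only if no family repeats
        if (length(intersect(fam[members[[a]]], fam[members[[b]]])) == 0L) {
          comp[b] <- a
          members[[a]] <- c(members[[a]], members[[b]])
          members[[b]] <- integer(0)
        }
      }
      keep <- Filter(function(m) length(m) >= 2L, members)
      groups <- lapply(keep, function(m) {
        m <- sort(m)
        list(members = mg$genes$gene_id[m], families = fam[m], lineage = NULL)
      })
    }
  }
  names(groups) <- if (length(groups)) sprintf("LG%03d", seq_along(groups))
  attr(groups, "threshold") <- threshold
  groups
}

#' Abundance of linkage groups
#'
#' A group's raw coverage in a sample is the summed base-scaled counts of
#' its member genes divided by the summed member gene lengths; coverages
#' are then closed to relative abundances within each sample.
#'
#' @param mg a [marker_gene_table()].
#' @param groups linkage groups from [link_marker_genes()].
#' @return group x sample relative-abundance matrix.
#' @export
lg_abundance <- function(mg, groups) {
  if (length(groups) == 0L) stop("no linkage groups supplied")
  raw <- matrix(NA_real_, length(groups), ncol(mg$counts),
                dimnames = list(names(groups), colnames(mg$counts)))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (length(g$members) == 0L) stop("empty linkage group")
    i <- match(g$members, mg$genes$gene_id)
    if (anyNA(i)) stop("group member absent from marker-gene table")
    raw[k, ] <- colSums(mg$counts[i, , drop = FALSE]) /
      sum(mg$genes$length[i])
  }
  close_columns(raw)
}

#' Per-sample and global detection limits
#'
#' A sample's detection limit is the relative abundance of its
#' least-abundant non-zero feature; the global limit is the highest (least
#' sensitive) of the per-sample limits.
#'
#' @param abund relative-abundance matrix, features x samples.
#' @return list with `per_sample` (named vector) and `global`.
#' @export
detection_limits <- function(abund) {
  per_sample <- apply(abund, 2L, function(col) {
    nz <- col[col > 0]
    if (length(nz) == 0L) stop("sample with no non-zero feature")
    min(nz)
  })
  list(per_sample = per_sample, global = max(per_sample))
}

#' Annotate a linkage group by rank-wise unanimity
#'
#' Walking from superkingdom down, a rank's label migrates to the group
#' only when every member gene carries the same label there; species
#' additionally requires each member's percent identity to exceed its
#' family's clustering cutoff. The walk stops at the first disagreement.
#'
#' @param per_gene_lineages named list: gene id -> named character vector
#'   over the canonical ranks (NA where unannotated).
#' @param per_gene_identities named numeric: gene id -> percent identity of
#'   its best hit.
#' @param per_gene_families named character: gene id -> marker-gene family.
#' @param family_identity_cutoffs named numeric: family -> species-level
#'   identity cutoff.
#' @return named character vector over the canonical ranks (NA below the
#'   deepest adopted rank).
#' @export
annotate_lg <- function(per_gene_lineages, per_gene_identities,
                        per_gene_families, family_identity_cutoffs) {
  if (length(per_gene_lineages) == 0L) stop("need >= 1 annotated member")
  out <- stats::setNames(rep(NA_character_, length(TAXONOMIC_RANKS)),
                         TAXONOMIC_RANKS)
  genes <- names(per_gene_lineages)
  for (r in TAXONOMIC_RANKS) {
    labels <- vapply(per_gene_lineages, function(l) l[[r]], character(1))
    if (anyNA(labels) || length(unique(labels)) != 1L) break
    if (r == "species") {
      cutoffs <- family_identity_cutoffs[per_gene_families[genes]]
      if (any(is.na(cutoffs)) ||
          any(per_gene_identities[genes] <= cutoffs)) break
    }
    out[r] <- labels[[1]]
  }
  out
}
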