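#' Aggregate species-level abundances at a taxonomic rank
#'
#' Sums feature abundances by their taxon label at the requested rank;
#' features without a label at that rank are pooled into an `"unassigned"`
#' row (droppable via `keep_unassigned = FALSE`, after which columns are
#' re-closed).
#'
#' @param abund feature x sample matrix.
#' @param lineages data.frame with a `feature` column and one column per
#'   canonical rank, as in `dog_study$lineages`.
#' @param rank one of the canonical ranks.
#' @param keep_unassigned keep the pooled unassigned mass as its own row.
#' @return taxon x sample matrix.
#' @export
aggregate_rank <- function(abund, lineages, rank, keep_unassigned = TRUE) {
  if (!rank %in% TAXONOMIC_RANKS) stop("unknown rank: ", rank)
  lab <- lineages[[rank]][match(rownames(abund), lineages$feature)]
  lab[is.na(lab) | lab == ""] <- "unassigned"
  out <- rowsum(abund, group = lab)
  if (!keep_unassigned && "unassigned" %in% rownames(out)) {
    out <- close_columns(out[rownames(out) != "unassigned", , drop = FALSE])
  }
  out
}

#' Log-transform an abundance matrix with detection-limit pseudo-counts
#'
#' Computes `log10(x + pseudo)` with the per-feature pseudo-count of
#' [pseudo_counts()] (one tenth of the feature's smallest non-zero value)
#' or a fixed global pseudo-count.
#'
#' @param abund nonnegative feature x sample matrix.
#' @param pseudo_policy `"feature_min"` or `"fixed:<value>"`.
#' @return transformed matrix of the same shape.
#' @export
log_transform <- function(abund, pseudo_policy = "feature_min") {
  ps <- pseudo_counts(abund, pseudo_policy)
  log10(abund + ps)
}

bray_curtis <- function(x, y) {
  s <- sum(x + y)
  if (s == 0) return(0)
  sum(abs(x - y)) / s
}

weighted_jaccard <- function(x, y) {
  s <- sum(pmax(x, y))
  if (s == 0) return(0)
  1 - sum(pmin(x, y)) / s
}

#' Pairwise sample distances
#'
#' Bray-Curtis `sum|x-y| / sum(x+y)`, abundance-weighted Jaccard (Ruzicka)
#' `1 - sum(min) / sum(max)`, or Manhattan `sum|x-y|`, between the columns
#' of a matrix. The two ecological metrics require nonnegative input.
#'
#' @param x feature x sample matrix.
#' @param metric `"bray_curtis"`, `"weighted_jaccard"` or `"manhattan"`.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "weighted_jaccard",
                                          "manhattan")) {
  metric <- match.arg(metric)
  if (any(!is.finite(x))) stop("matrix must be finite")
  if (metric != "manhattan" && any(x < 0)) {
    stop(metric, " requires nonnegative entries")
  }
  f <- switch(metric, bray_curtis = bray_curtis,
              weighted_jaccard = weighted_jaccard,
              manhattan = function(a, b) sum(abs(a - b)))
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- f(x[, i], x[, j])
  }
  d
}

#' Principal coordinate analysis
#'
#' Gower-centers the squared distance matrix (`-0.5 * J D^2 J` with
#' `J = I - 11'/n`), eigendecomposes it, and scales the top-k eigenvectors
#' by the square roots of their eigenvalues. Axes with negative eigenvalues
#' are dropped (the eigenvalues are still reported); each retained axis's
#' sign is fixed so its largest-magnitude loading is positive.
#'
#' @param D symmetric distance matrix.
#' @param k number of coordinate axes requested.
#' @return list with `coordinates` (n x <= k), `eigenvalues` (all n) and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k > n) stop("k exceeds the number of samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- e$values
  keep <- seq_len(k)[vals[seq_len(k)] >= 0]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals[keep]), length(keep))
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", keep)
  list(coordinates = coords, eigenvalues = vals,
       negative_eigenvalues = vals[vals < 0])
}

permanova_f <- function(D2, labels) {
  n <- length(labels)
  k <- length(unique(labels))
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ss_within <- ss_within + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

#' Permutational multivariate analysis of variance
#'
#' Partitions squared distances between and within groups and evaluates
#' the pseudo-F statistic against label shuffles. With `mode = "exact"`
#' (two groups only) all distinct assignments of samples to the two group
#' sizes are enumerated and the p-value is the fraction with `F* >= F`;
#' otherwise p uses the add-one Monte Carlo estimator.
#'
#' @param D distance matrix.
#' @param labels group labels, >= 2 groups of >= 2 samples each.
#' @param n_permutations Monte Carlo permutation count.
#' @param seed integer seed.
#' @param mode `"monte_carlo"` (default) or `"exact"`.
#' @return list with `pseudo_F` and `p_value`.
#' @export
permanova <- function(D, labels, n_permutations = 999L, seed = 1L,
                      mode = c("monte_carlo", "exact")) {
  mode <- match.arg(mode)
  D <- as.matrix(D)
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L)) stop("each group needs >= 2 samples")
  D2 <- D^2
  f_obs <- permanova_f(D2, labels)
  n <- length(labels)
  if (mode == "exact") {
    if (length(sizes) != 2L) stop("exact mode supports exactly 2 groups")
    g1 <- names(sizes)[1]
    combos <- utils::combn(n, sizes[[1]])
    f_null <- apply(combos, 2L, function(i) {
      lab <- rep(names(sizes)[2], n)
      lab[i] <- g1
      permanova_f(D2, lab)
    })
    p <- mean(f_null >= f_obs - 1e-12)
  } else {
    f_null <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        permanova_f(D2, sample(labels)) }, numeric(1))
    })
    p <- (1 + sum(f_null >= f_obs - 1e-12)) / (n_permutations + 1)
  }
  list(pseudo_F = f_obs, p_value = p)
}

#' Paired baseline-to-post compositional shifts
#'
#' For each dog with both timepoints, the distance between its baseline and
#' post profile after log transformation. Because log10 relative abundances
#' are negative, the transformed matrix is shifted by its global minimum
#' before Bray-Curtis or Ruzicka distances are taken (an affine shift that
#' leaves Manhattan distances untouched); dogs missing a timepoint are
#' excluded with a message.
#'
#' @param abund feature x sample matrix of relative abundances.
#' @param metadata sample metadata with `sample_id`, `dog_id`, `timepoint`,
#'   `intervention_diet` (or `diet`), `condition`.
#' @param metric distance metric, as in [distance_matrix()].
#' @param transform apply the log transform first (the study's
#'   construction); set FALSE to use raw relative abundances.
#' @param pseudo_policy pseudo-count policy for the log transform.
#' @return data.frame with one row per complete dog: `dog_id`, `diet`,
#'   `condition`, `shift`.
#' @export
paired_shift <- function(abund, metadata, metric = "bray_curtis",
                         transform = TRUE,
                         pseudo_policy = "feature_min") {
  x <- if (transform) {
    lx <- log_transform(abund, pseudo_policy)
    lx - min(lx)
  } else abund
  diet_col <- if ("intervention_diet" %in% names(metadata)) {
    "intervention_diet"
  } else "diet"
  dogs <- unique(metadata$dog_id)
  rows <- lapply(dogs, function(d) {
    md <- metadata[metadata$dog_id == d, ]
    b <- md$sample_id[md$timepoint == "baseline"]
    p <- md$sample_id[md$timepoint == "post"]
    if (length(b) != 1L || length(p) != 1L ||
        !all(c(b, p) %in% colnames(x))) {
      message("dog ", d, " missing a timepoint; excluded")
      return(NULL)
    }
    f <- switch(metric, bray_curtis = bray_curtis,
                weighted_jaccard = weighted_jaccard,
                manhattan = function(a, b2) sum(abs(a - b2)))
    data.frame(dog_id = d, diet = md[[diet_col]][md$timepoint == "post"],
               condition = md$condition[1], shift = f(x[, b], x[, p]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Compare paired shifts between a focal subgroup and the rest
#'
#' Two-tailed Mann-Whitney-Wilcoxon test of the shift magnitudes of a
#' focal subgroup (e.g. HPLC-fed OW dogs) against all remaining dogs, or
#' between two explicit diet arms.
#'
#' @param shifts a [paired_shift()] table.
#' @param focal named list of column filters, e.g.
#'   `list(diet = "HPLC", condition = "OW")`; rows matching all filters
#'   form group 1, the rest group 2.
#' @return `htest` from [stats::wilcox.test()], with the group medians in
#'   `$medians`.
#' @export
compare_shifts <- function(shifts, focal) {
  sel <- rep(TRUE, nrow(shifts))
  for (col in names(focal)) sel <- sel & shifts[[col]] %in% focal[[col]]
  if (!any(sel) || all(sel)) stop("focal subgroup must be a proper subset")
  ht <- stats::wilcox.test(shifts$shift[sel], shifts$shift[!sel],
                           alternative = "two.sided", exact = NULL)
  ht$medians <- c(focal = stats::median(shifts$shift[sel]),
                  rest = stats::median(shifts$shift[!sel]))
  ht
}

#' Taxon-set abundance ratios with rank-based group tests
#'
#' Per sample, the ratio of summed numerator-taxon abundance to summed
#' denominator-taxon abundance; one tenth of the smallest non-zero
#' denominator value is added to both sums so ratios stay finite (and equal
#' 1 when the sets coincide). Two groups are compared by the two-tailed
#' Mann-Whitney-Wilcoxon test, three or more by Kruskal-Wallis with all
#' pairwise Wilcoxon follow-ups.
#'
#' @param abund taxon x sample matrix (aggregate to the desired rank
#'   first).
#' @param numerator,denominator non-empty character vectors of row names.
#' @param groups per-sample group labels (named by sample or in column
#'   order).
#' @return list with `ratios`, `test` (`htest`), and `pairwise`
#'   (data.frame of pairwise Wilcoxon p-values, NULL for 2 groups).
#' @export
ratio_test <- function(abund, numerator, denominator, groups) {
  if (length(numerator) == 0L || length(denominator) == 0L) {
    stop("numerator and denominator taxon sets must be non-empty")
  }
  missing <- setdiff(c(numerator, denominator), rownames(abund))
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  num <- colSums(abund[numerator, , drop = FALSE])
  den <- colSums(abund[denominator, , drop = FALSE])
  nz <- den[den > 0]
  pseudo <- if (length(nz)) min(nz) / 10 else {
    pn <- num[num > 0]
    if (length(pn)) min(pn) / 10 else 1e-10
  }
  ratios <- (num + pseudo) / (den + pseudo)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need >= 2 groups")
  if (length(unique(ratios)) == 1L) {
    test <- list(statistic = 0, p.value = 1, method = "degenerate (all tied)")
    class(test) <- "htest"
    return(list(ratios = ratios, test = test, pairwise = NULL))
  }
  if (length(lv) == 2L) {
    test <- stats::wilcox.test(ratios[groups == lv[1]],
                               ratios[groups == lv[2]],
                               alternative = "two.sided")
    pairwise <- NULL
  } else {
    test <- stats::kruskal.test(ratios, factor(groups))
    prs <- utils::combn(lv, 2L)
    pairwise <- data.frame(
      group1 = prs[1, ], group2 = prs[2, ],
      p_value = apply(prs, 2L, function(pr) {
        a <- ratios[groups == pr[1]]; b <- ratios[groups == pr[2]]
        if (length(unique(c(a, b))) == 1L) 1 else
          stats::wilcox.test(a, b, alternative = "two.sided")$p.value
      }),
      stringsAsFactors = FALSE
    )
  }
  list(ratios = ratios, test = test, pairwise = pairwise)
}

#' Leave-out robustness of a shift comparison
#'
#' Re-runs the focal paired-shift comparison after removing every subset of
#' genera of size 1..`max_k`, re-closing the composition each time, and
#' reports whether all subset removals keep the comparison below `alpha`.
#'
#' @param abund genus x sample matrix of relative abundances.
#' @param metadata sample metadata as for [paired_shift()].
#' @param focal focal-subgroup filter, as in [compare_shifts()].
#' @param max_k largest subset size removed.
#' @param alpha significance level for the "all significant" flag.
#' @param metric distance metric for the shifts.
#' @return list with `results` (data.frame: removed, k, p_value), `min_p`,
#'   `max_p`, `all_significant`.
#' @export
leave_out_robustness <- function(abund, metadata, focal, max_k = 3L,
                                 alpha = 0.05, metric = "bray_curtis") {
  g <- rownames(abund)
  if (length(g) < max_k + 1L) stop("too few genera for max_k = ", max_k)
  rows <- list()
  for (k in seq_len(max_k)) {
    subsets <- utils::combn(g, k, simplify = FALSE)
    for (s in subsets) {
      sub <- close_columns(abund[setdiff(g, s), , drop = FALSE])
      sh <- paired_shift(sub, metadata, metric = metric)
      p <- suppressWarnings(compare_shifts(sh, focal)$p.value)
      rows[[length(rows) + 1L]] <-
        data.frame(removed = paste(s, collapse = "+"), k = k, p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  list(results = res, min_p = min(res$p_value), max_p = max(res$p_value),
       all_significant = all(res$p_value < alpha))
}
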