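# Variation matrix t_ij = Var(log(x_i / x_j)) computed from the covariance
# of the log fractions: t = v_i + v_j - 2 * cov_ij.
variation_matrix <- function(logx) {
  C <- stats::cov(t(logx))
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

# Solve the sparCC basis variances given the variation matrix and a set of
# excluded (strongly correlated) pairs, then back out the correlations.
sparcc_solve <- function(tmat, excluded) {
  d <- nrow(tmat)
  M <- matrix(1, d, d)
  M[excluded] <- 0
  deg <- rowSums(excluded) # excluded is symmetric logical, FALSE diagonal
  diag(M) <- d - 1 - deg
  t_use <- tmat
  t_use[excluded] <- 0
  omega2 <- tryCatch(solve(M, rowSums(t_use)),
                     error = function(e) rep(mean(tmat) / 2, d))
  omega2[omega2 <= 0] <- min(omega2[omega2 > 0], 1e-12)
  omega <- sqrt(omega2)
  rho <- (outer(omega2, omega2, "+") - tmat) / (2 * outer(omega, omega))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

#' sparCC basis correlations of compositional data
#'
#' Estimates correlations of the unobserved absolute-scale (basis)
#' abundances from closed relative abundances. Zeros are replaced with
#' per-feature pseudo-counts, log fractions are taken, the variation
#' matrix `t_ij = Var(log(x_i/x_j))` is formed, and the basis variances
#' are solved from the linear system implied by
#' `t_ij = w_i^2 + w_j^2 - 2 rho_ij w_i w_j` under the sparse
#' mean-zero-correlation approximation. The most strongly correlated pair
#' exceeding `exclusion_threshold` is iteratively excluded from the system
#' (up to `max_exclusion_iters` times) and the system re-solved, so a few
#' genuinely correlated pairs do not bias the basis variances.
#'
#' @param fractions taxon x sample matrix of relative abundances (>= 4
#'   taxa).
#' @param exclusion_threshold absolute correlation above which a pair is
#'   excluded from the basis-variance system.
#' @param max_exclusion_iters maximum exclusion rounds.
#' @param pseudo_policy zero-replacement policy (see [pseudo_counts()]).
#' @return taxon x taxon correlation matrix, entries clipped to \[-1, 1\].
#' @export
sparcc_correlations <- function(fractions, exclusion_threshold = 0.1,
                                max_exclusion_iters = 10L,
                                pseudo_policy = "feature_min") {
  if (nrow(fractions) < 4L) stop("sparCC needs >= 4 taxa")
  x <- fractions + pseudo_counts(fractions, pseudo_policy)
  if (any(x <= 0)) stop("nonpositive entries after pseudo-count replacement")
  sparcc_from_logs(log(x), exclusion_threshold, max_exclusion_iters)
}

sparcc_from_logs <- function(logx, exclusion_threshold, max_exclusion_iters) {
  tmat <- variation_matrix(logx)
  d <- nrow(tmat)
  excluded <- matrix(FALSE, d, d)
  rho <- sparcc_solve(tmat, excluded)
  for (iter in seq_len(max_exclusion_iters)) {
    cand <- abs(rho)
    cand[excluded] <- 0
    diag(cand) <- 0
    m <- which.max(cand)
    if (cand[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(cand))
    excluded[ij[1], ij[2]] <- excluded[ij[2], ij[1]] <- TRUE
    rho <- sparcc_solve(tmat, excluded)
  }
  dimnames(rho) <- list(rownames(logx), rownames(logx))
  rho
}

#' Empirical two-sided sparCC p-values by permutation
#'
#' Each permutation shuffles every taxon's values across samples
#' independently (destroying all between-taxon association while keeping
#' marginals), recomputes the sparCC correlations, and the two-sided
#' p-value of a pair is the add-one fraction of permutations whose
#' absolute correlation reaches the observed one.
#'
#' @inheritParams sparcc_correlations
#' @param n_permutations number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `rho` (observed correlations) and `p` (p-value
#'   matrix, diagonal NA).
#' @export
sparcc_pvalues <- function(fractions, n_permutations = 999L, seed = 1L,
                           exclusion_threshold = 0.1,
                           max_exclusion_iters = 10L,
                           pseudo_policy = "feature_min") {
  if (n_permutations < 99L) stop("need >= 99 permutations")
  x <- fractions + pseudo_counts(fractions, pseudo_policy)
  logx <- log(x)
  rho <- sparcc_from_logs(logx, exclusion_threshold, max_exclusion_iters)
  d <- nrow(logx)
  count <- matrix(0L, d, d)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- t(apply(logx, 1L, sample))
      rho_b <- sparcc_from_logs(perm, exclusion_threshold,
                                max_exclusion_iters)
      count <- count + (abs(rho_b) >= abs(rho) - 1e-12)
    }
  })
  p <- (1 + count) / (n_permutations + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p)
}

#' Build a co-abundance network
#'
#' An edge joins two taxa when the magnitude of their Spearman rank
#' correlation exceeds `r_threshold` *and* their sparCC permutation
#' p-value survives Benjamini-Hochberg control at `fdr` over all pairs.
#' Edge signs follow the Spearman correlation.
#'
#' @param abund taxon x sample relative-abundance matrix.
#' @param r_threshold Spearman magnitude an edge must exceed.
#' @param fdr BH false-discovery rate for the sparCC p-values.
#' @param n_permutations,seed sparCC permutation controls.
#' @return list of class `coabundance_network` with `nodes` and `edges`
#'   (source, target, spearman_r, sparcc_rho, p, q, sign).
#' @export
build_network <- function(abund, r_threshold = 0.5, fdr = 0.05,
                          n_permutations = 999L, seed = 1L) {
  sp <- stats::cor(t(abund), method = "spearman")
  sv <- sparcc_pvalues(abund, n_permutations = n_permutations, seed = seed)
  ut <- which(upper.tri(sp), arr.ind = TRUE)
  p <- sv$p[ut]
  qv <- stats::p.adjust(p, "BH")
  keep <- abs(sp[ut]) > r_threshold & qv <= fdr
  edges <- data.frame(
    source = rownames(abund)[ut[keep, 1]],
    target = rownames(abund)[ut[keep, 2]],
    spearman_r = sp[ut][keep], sparcc_rho = sv$rho[ut][keep],
    p = p[keep], q = qv[keep],
    sign = ifelse(sp[ut][keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = rownames(abund), edges = edges),
            class = "coabundance_network")
}

#' Co-abundance groups and their summed abundance
#'
#' Partitions the network's nodes into connected components over the
#' positive edges only; when an abundance matrix is supplied, each
#' multi-node group's summed relative abundance per sample is reported.
#'
#' @param net a [build_network()] result.
#' @param abund optional taxon x sample matrix for group abundances.
#' @return list with `membership` (named integer vector) and
#'   `group_abundance` (group x sample matrix or NULL).
#' @export
network_groups <- function(net, abund = NULL) {
  pos <- net$edges[net$edges$sign == "positive", , drop = FALSE]
  g <- igraph::graph_from_data_frame(pos[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  membership <- igraph::components(g)$membership[net$nodes]
  group_abundance <- NULL
  if (!is.null(abund)) {
    multi <- names(which(table(membership) > 1L))
    if (length(multi)) {
      group_abundance <- t(vapply(multi, function(k) {
        colSums(abund[names(membership)[membership == as.integer(k)], ,
                      drop = FALSE])
      }, numeric(ncol(abund))))
      rownames(group_abundance) <- paste0("group", multi)
    }
  }
  list(membership = membership, group_abundance = group_abundance)
}

#' Write a network edge list as TSV, and export GraphML
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
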