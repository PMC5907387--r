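#' Doubly censored log-ratios from paired detection-limited measurements
#'
#' For each dog, the log10 ratio of the post-intervention to the baseline
#' measurement after adding a pseudo-count (one tenth of the lowest
#' non-zero value among the analyzed measurements, unless given). A pair
#' with the baseline below the detection limit yields a right-censored
#' ratio (the true fold change is at least this large); a pair with the
#' post sample below the limit yields a left-censored ratio; pairs with
#' both below the limit are dropped and counted.
#'
#' @param baseline,post nonnegative per-dog values, aligned (same length
#'   and order; names are carried through if present).
#' @param detection_limit values strictly below it count as undetected;
#'   defaults to treating exact zeros as undetected.
#' @param pseudo pseudo-count; default one tenth of the smallest non-zero
#'   value of `c(baseline, post)`.
#' @return object of class `censored_values`: data.frame with columns
#'   `value` and `status` (`observed` / `left` / `right`), attribute
#'   `n_excluded`.
#' @export
censored_log_ratios <- function(baseline, post, detection_limit = NULL,
                                pseudo = NULL) {
  if (length(baseline) != length(post)) stop("baseline and post must align")
  if (any(baseline < 0) || any(post < 0)) stop("negative abundances")
  detected <- function(x) if (is.null(detection_limit)) x > 0 else
    x >= detection_limit
  if (is.null(pseudo)) {
    nz <- c(baseline, post)
    nz <- nz[nz > 0]
    if (length(nz) == 0L) stop("no non-zero measurements to set a pseudo-count")
    pseudo <- min(nz) / 10
  }
  db <- detected(baseline)
  dp <- detected(post)
  keep <- db | dp
  value <- log10((post[keep] + pseudo) / (baseline[keep] + pseudo))
  status <- ifelse(!db[keep], "right", ifelse(!dp[keep], "left", "observed"))
  out <- data.frame(value = value, status = status,
                    row.names = names(baseline)[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("censored_values", "data.frame")
  out
}

censored_bounds <- function(cv) {
  lower <- ifelse(cv$status %in% c("observed", "right"), cv$value, -Inf)
  upper <- ifelse(cv$status %in% c("observed", "left"), cv$value, Inf)
  cbind(lower = lower, upper = upper)
}

#' Pairwise Gehan score of two possibly censored values
#'
#' With `lower(x)` the value for observed or right-censored x (else -Inf)
#' and `upper(x)` the value for observed or left-censored x (else +Inf):
#' +1 when `lower(a) > upper(b)` (a definitely larger), -1 when
#' `upper(a) < lower(b)`, and 0 when the order is indeterminate (touching
#' bounds score 0, the conservative convention).
#'
#' @param a,b one-row `censored_values` (or data.frames with `value` and
#'   `status`).
#' @return -1, 0 or +1.
#' @export
gehan_score <- function(a, b) {
  ba <- censored_bounds(a)
  bb <- censored_bounds(b)
  if (ba[1, "lower"] > bb[1, "upper"]) return(1L)
  if (ba[1, "upper"] < bb[1, "lower"]) return(-1L)
  0L
}

# Full score matrix among n censored values: S[i, j] in {-1, 0, 1}.
gehan_score_matrix <- function(cv) {
  b <- censored_bounds(cv)
  gt <- outer(b[, "lower"], b[, "upper"], ">")
  lt <- outer(b[, "upper"], b[, "lower"], "<")
  s <- matrix(0L, nrow(b), nrow(b))
  s[gt] <- 1L
  s[lt] <- -1L
  s
}

#' Two-sided Gehan generalized Wilcoxon test for doubly censored data
#'
#' The statistic is the sum of pairwise [gehan_score()] values over all
#' (group 1, group 2) pairs. Its two-sided p-value comes from permuting
#' group membership: exhaustively over all `choose(n, n1)` splits when that
#' count is at most `exact_limit` (p is the exact fraction of splits with
#' `|W*| >= |W|`), else by Monte Carlo with the add-one estimator.
#'
#' @param group1,group2 `censored_values` (or data.frames with `value`,
#'   `status`); both non-empty.
#' @param mode `"auto"` (exact when feasible), `"exact"` or
#'   `"monte_carlo"`.
#' @param n_permutations Monte Carlo permutation count.
#' @param seed integer seed for Monte Carlo.
#' @param exact_limit largest enumeration size for the exact mode.
#' @return list with `statistic` (W), `p_value`, `n_used`, `mode`.
#' @export
gehan_test <- function(group1, group2, mode = c("auto", "exact",
                                                "monte_carlo"),
                       n_permutations = 9999L, seed = 1L,
                       exact_limit = 50000) {
  mode <- match.arg(mode)
  n1 <- nrow(group1)
  n2 <- nrow(group2)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  all_cv <- rbind(group1[, c("value", "status")],
                  group2[, c("value", "status")])
  s <- gehan_score_matrix(all_cv)
  n <- n1 + n2
  w_for <- function(idx1) sum(s[idx1, setdiff(seq_len(n), idx1)])
  w_obs <- w_for(seq_len(n1))
  n_splits <- choose(n, n1)
  if (mode == "auto") mode <- if (n_splits <= exact_limit) "exact" else
    "monte_carlo"
  if (mode == "exact") {
    if (n_splits > exact_limit) stop("exact enumeration too large")
    w_null <- apply(utils::combn(n, n1), 2L, w_for)
    p <- mean(abs(w_null) >= abs(w_obs))
  } else {
    w_null <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(b) w_for(sample.int(n, n1)), numeric(1))
    })
    p <- (1 + sum(abs(w_null) >= abs(w_obs))) / (n_permutations + 1)
  }
  list(statistic = w_obs, p_value = p, n_used = n, mode = mode)
}

#' Two-stage Benjamini-Hochberg FDR control
#'
#' Stage 1 runs BH at level `q / (1 + q)` and counts its rejections `r1`;
#' the estimated number of true nulls is `m0 = m - r1`. If stage 1 rejects
#' nothing, nothing is rejected; if `m0 = 0`, everything is. Otherwise
#' stage 2 runs BH at level `q * m / m0`, which supplies the rejections and
#' the adjusted q-values.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q target false-discovery rate.
#' @return list with `rejected` (logical), `q_values`, `m0`.
#' @export
two_stage_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  bh_reject <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    ok <- which(p[o] <= thr)
    rej <- rep(FALSE, m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  r1 <- sum(bh_reject(p_values, q / (1 + q)))
  m0 <- m - r1
  q_values <- pmin(1, stats::p.adjust(p_values, "BH") * max(m0, 0) / m)
  if (r1 == 0L) {
    rejected <- rep(FALSE, m)
  } else if (m0 == 0L) {
    rejected <- rep(TRUE, m)
  } else {
    rejected <- bh_reject(p_values, q * m / m0)
  }
  list(rejected = rejected, q_values = q_values, m0 = m0)
}

#' Censored-ratio differential response screen across features
#'
#' For every feature, builds the per-dog censored log-ratios of post to
#' baseline within each of two diet arms and runs the two-sided Gehan
#' test between them, then applies two-stage Benjamini-Hochberg
#' correction over the features.
#'
#' @param abund feature x sample matrix (detection-limit-censored relative
#'   abundances).
#' @param metadata sample metadata as produced by [simulate_study()].
#' @param diets the two diet arms to contrast.
#' @param q target FDR for the two-stage BH correction.
#' @param n_permutations,seed Gehan Monte Carlo controls.
#' @return data.frame: feature, statistic, p_value, q_value, rejected,
#'   n_used, n_excluded.
#' @export
gehan_screen <- function(abund, metadata, diets = c("HPLC", "LPHC"),
                         q = 0.05, n_permutations = 999L, seed = 1L) {
  diet_col <- if ("intervention_diet" %in% names(metadata)) {
    "intervention_diet"
  } else "diet"
  grab <- function(diet, tp) {
    md <- metadata[metadata[[diet_col]] == diet & metadata$timepoint == tp, ]
    md <- md[order(md$dog_id), ]
    abund[, md$sample_id, drop = FALSE]
  }
  rows <- lapply(rownames(abund), function(f) {
    blocks <- lapply(diets, function(d) {
      list(baseline = grab(d, "baseline")[f, ], post = grab(d, "post")[f, ])
    })
    # per-feature pseudo-count over all analyzed samples of both arms
    vals <- unlist(blocks)
    if (all(vals == 0)) return(NULL)
    pseudo <- min(vals[vals > 0]) / 10
    cvs <- lapply(blocks, function(b) {
      censored_log_ratios(b$baseline, b$post, pseudo = pseudo)
    })
    if (nrow(cvs[[1]]) == 0L || nrow(cvs[[2]]) == 0L) return(NULL)
    gt <- gehan_test(cvs[[1]], cvs[[2]], n_permutations = n_permutations,
                     seed = seed)
    data.frame(feature = f, statistic = gt$statistic, p_value = gt$p_value,
               n_used = gt$n_used,
               n_excluded = attr(cvs[[1]], "n_excluded") +
                 attr(cvs[[2]], "n_excluded"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  fdr <- two_stage_bh(res$p_value, q)
  res$q_value <- fdr$q_values
  res$rejected <- fdr$rejected
  res[order(res$p_value), ]
}

#' Prevalence-change tests across diet groups
#'
#' Per taxon, cross-tabulates detected/undetected status against diet
#' group and evaluates a two-sided Fisher's exact test, Bonferroni-
#' corrected over taxa. `mode = "pairwise"` (default) tests every pair of
#' diets as a 2x2 table (correction also multiplies by the number of
#' pairs); `mode = "joint"` tests one 2xg table per taxon.
#'
#' @param presence taxon x sample logical matrix (TRUE = detected).
#' @param groups per-sample diet labels.
#' @param alpha significance level applied to corrected p-values.
#' @param mode `"pairwise"` or `"joint"`.
#' @return data.frame: taxon, comparison, p_value, p_bonferroni,
#'   significant, plus the per-group detected counts.
#' @export
prevalence_test <- function(presence, groups, alpha = 0.05,
                            mode = c("pairwise", "joint")) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need >= 2 diet groups")
  if (any(table(groups) == 0L)) stop("empty group")
  comparisons <- if (mode == "joint") list(lv) else
    utils::combn(lv, 2L, simplify = FALSE)
  rows <- list()
  for (taxon in rownames(presence)) {
    det <- presence[taxon, ]
    for (cmp in comparisons) {
      sel <- groups %in% cmp
      tab <- table(factor(det[sel], levels = c(TRUE, FALSE)),
                   factor(groups[sel], levels = cmp))
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, comparison = paste(cmp, collapse = " vs "),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  n_tests <- nrow(presence) * length(comparisons)
  res$p_bonferroni <- pmin(1, res$p_value * n_tests)
  res$significant <- res$p_bonferroni < alpha
  res[order(res$p_value), ]
}
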