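#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG state without disturbing the caller's
# stream. All stochastic entry points funnel through this so that a seed
# argument fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Per-feature pseudo-counts for log transforms and ratios
#'
#' Each feature (row) receives one tenth of its lowest non-zero value; a
#' feature with no non-zero value falls back to one tenth of the global
#' minimum non-zero value of the matrix, with a warning. This is the
#' detection-limit convention used throughout the package: the smallest
#' observed value of a feature proxies its per-feature detection floor.
#'
#' @param x nonnegative numeric matrix, features in rows.
#' @param policy `"feature_min"` (default) or `"fixed:<value>"` for a single
#'   global pseudo-count, e.g. `"fixed:1e-6"`.
#' @return numeric vector of pseudo-counts, one per row of `x`.
#' @export
pseudo_counts <- function(x, policy = "feature_min") {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundances are not allowed")
  if (startsWith(policy, "fixed:")) {
    val <- as.numeric(sub("^fixed:", "", policy))
    if (!is.finite(val) || val <= 0) stop("invalid fixed pseudo-count: ", policy)
    return(rep(val, nrow(x)))
  }
  if (policy != "feature_min") stop("unknown pseudo-count policy: ", policy)
  pos <- x > 0
  if (!any(pos)) stop("matrix has no non-zero entries; cannot derive pseudo-counts")
  global <- min(x[pos]) / 10
  ps <- apply(x, 1L, function(r) {
    nz <- r[r > 0]
    if (length(nz) == 0L) NA_real_ else min(nz) / 10
  })
  if (anyNA(ps)) {
    warning(sum(is.na(ps)), " all-zero feature(s); pseudo-count fell back to global minimum/10")
    ps[is.na(ps)] <- global
  }
  ps
}

# Close columns of a nonnegative matrix to sum 1 (all-zero columns stay zero).
close_columns <- function(x) {
  cs <- colSums(x)
  cs[cs == 0] <- 1
  sweep(x, 2L, cs, "/")
}

stopifnot_matrix <- function(x, what = "abundance matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have feature rownames and sample colnames")
  }
  invisible(x)
}
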