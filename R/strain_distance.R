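#' Coverage gate for strain-level comparisons
#'
#' Keeps samples with enough coverage over the genome: mean depth at least
#' `min_depth` (vertical) and covered fraction at least `min_breadth`
#' (horizontal).
#'
#' @param coverage data.frame with `sample_id`, `mean_depth`, `breadth`.
#' @param min_depth vertical coverage threshold (default 5x).
#' @param min_breadth horizontal coverage threshold (default 80%).
#' @return character vector of eligible sample ids.
#' @export
filter_coverage <- function(coverage, min_depth = 5, min_breadth = 0.8) {
  coverage$sample_id[coverage$mean_depth >= min_depth &
                       coverage$breadth >= min_breadth]
}

#' Normalized Manhattan distance between SNP allele-frequency profiles
#'
#' Over the positions observed (non-missing) in both samples, the mean
#' absolute difference of allele frequencies: identical profiles score 0,
#' completely distinct profiles (all 0 vs all 1) score 1.
#'
#' @param f_a,f_b numeric vectors of allele frequencies in \[0, 1\], NA =
#'   position not observed in that sample.
#' @param min_shared smallest number of shared positions below which the
#'   pair is declared incomparable (error).
#' @return distance in \[0, 1\].
#' @export
snp_distance <- function(f_a, f_b, min_shared = 1L) {
  if (length(f_a) != length(f_b)) stop("profiles must align by position")
  ok <- !is.na(f_a) & !is.na(f_b)
  if (sum(ok) < max(1L, min_shared)) {
    stop("incomparable pair: only ", sum(ok), " shared position(s)")
  }
  mean(abs(f_a[ok] - f_b[ok]))
}

#' Strain-level ordination from SNP allele frequencies
#'
#' Applies the coverage gate, computes all-pairs normalized Manhattan SNP
#' distances (pairs with too few shared positions are recorded as missing
#' and the sample with most missing pairs is dropped until the matrix is
#' complete), runs [pcoa()], and annotates every pair as same-host or
#' cross-host.
#'
#' @param freqs position x sample matrix of allele frequencies (NA =
#'   missing).
#' @param hosts named per-sample host labels.
#' @param coverage optional coverage data.frame for [filter_coverage()].
#' @param min_depth,min_breadth coverage gate.
#' @param min_shared minimum shared positions per pair (default 50).
#' @param k PCoA axes.
#' @return list with `coordinates`, `eigenvalues`, `distances` (matrix),
#'   `pairs` (data.frame with `same_host` flag), `samples_used`.
#' @export
strain_pcoa <- function(freqs, hosts, coverage = NULL, min_depth = 5,
                        min_breadth = 0.8, min_shared = 50L, k = 2L) {
  keep <- colnames(freqs)
  if (!is.null(coverage)) {
    keep <- intersect(keep, filter_coverage(coverage, min_depth, min_breadth))
  }
  if (length(keep) < 3L) stop("need >= 3 eligible samples")
  f <- freqs[, keep, drop = FALSE]
  n <- ncol(f)
  D <- matrix(0, n, n, dimnames = list(keep, keep))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- tryCatch(
      snp_distance(f[, i], f[, j], min_shared = min_shared),
      error = function(e) NA_real_)
  }
  while (anyNA(D) && nrow(D) > 3L) {
    worst <- which.max(rowSums(is.na(D)))
    message("dropping sample ", rownames(D)[worst],
            " (incomparable with ", sum(is.na(D[worst, ])), " others)")
    D <- D[-worst, -worst, drop = FALSE]
  }
  if (anyNA(D)) stop("distance matrix incomplete after dropping samples")
  ord <- pcoa(D, k = min(k, nrow(D)))
  ids <- rownames(D)
  pr <- utils::combn(ids, 2L)
  pairs <- data.frame(
    sample_a = pr[1, ], sample_b = pr[2, ],
    distance = D[cbind(pr[1, ], pr[2, ])],
    same_host = hosts[pr[1, ]] == hosts[pr[2, ]],
    stringsAsFactors = FALSE
  )
  list(coordinates = ord$coordinates, eigenvalues = ord$eigenvalues,
       distances = D, pairs = pairs, samples_used = ids)
}

#' Read allele frequencies from TSV
#'
#' Position rows, sample columns, empty cells are missing observations.
#' (VCF ingestion is out of scope; a converter would map each biallelic
#' record's alternate-allele frequency per sample into this layout,
#' collapsing multiallelic sites to the major allele.)
#'
#' @param path file path.
#' @return position x sample numeric matrix with NAs for missing cells.
#' @export
read_allele_freqs_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("frequencies must be in [0, 1]")
  m
}
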