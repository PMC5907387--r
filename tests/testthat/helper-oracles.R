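# Shared fixtures and independent oracles. Every oracle here re-derives its
# quantity from first principles (explicit case tables, exhaustive
# enumeration, direct arithmetic) without touching the package's own code
# path for that quantity.

make_cv <- function(values, statuses = "observed") {
  structure(data.frame(value = values,
                       status = rep_len(statuses, length(values)),
                       stringsAsFactors = FALSE),
            class = c("censored_values", "data.frame"))
}

rand_cv <- function(n, cens_frac = 0.3, shift = 0) {
  v <- rnorm(n) + shift
  s <- sample(c("observed", "left", "right"), n, replace = TRUE,
              prob = c(1 - cens_frac, cens_frac / 2, cens_frac / 2))
  make_cv(v, s)
}

# Pairwise Gehan score by explicit case analysis (independent of the
# package's bound construction).
oracle_score <- function(va, sa, vb, sb) {
  definitely_greater <- function(v1, s1, v2, s2) {
    # v1 surely exceeds v2: v1's lower bound above v2's upper bound
    lo1 <- switch(s1, observed = v1, right = v1, left = -Inf)
    hi2 <- switch(s2, observed = v2, left = v2, right = Inf)
    lo1 > hi2
  }
  if (definitely_greater(va, sa, vb, sb)) return(1L)
  if (definitely_greater(vb, sb, va, sa)) return(-1L)
  0L
}

# Exhaustive-permutation Gehan p-value: every split of the pooled values
# into the two group sizes, W computed pair by pair with oracle_score.
oracle_gehan_exact <- function(g1, g2) {
  pool <- rbind(g1, g2)
  n <- nrow(pool)
  n1 <- nrow(g1)
  w_of <- function(i1) {
    i2 <- setdiff(seq_len(n), i1)
    w <- 0L
    for (a in i1) for (b in i2) {
      w <- w + oracle_score(pool$value[a], pool$status[a],
                            pool$value[b], pool$status[b])
    }
    w
  }
  w_obs <- w_of(seq_len(n1))
  w_all <- apply(utils::combn(n, n1), 2L, w_of)
  list(statistic = w_obs, p_value = mean(abs(w_all) >= abs(w_obs)))
}

# Monte Carlo permutation Mann-Whitney on raw values via the rank-sum
# statistic (two-sided, add-one estimator).
oracle_perm_mannwhitney <- function(x, y, B = 4999L) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  mu <- n1 * (length(pool) + 1) / 2
  t_obs <- abs(sum(r[seq_len(n1)]) - mu)
  t_null <- replicate(B, abs(sum(sample(r, n1)) - mu))
  (1 + sum(t_null >= t_obs - 1e-9)) / (B + 1)
}

# PERMANOVA pseudo-F recomputed from scratch from the distance matrix.
oracle_permanova_f <- function(D, labels) {
  n <- length(labels)
  groups <- unique(labels)
  k <- length(groups)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
      ss_w <- ss_w + s / length(idx)
    }
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}

# Exhaustive two-group PERMANOVA p-value over all label assignments.
oracle_permanova_exact <- function(D, labels) {
  n <- length(labels)
  g <- unique(labels)
  n1 <- sum(labels == g[1])
  f_obs <- oracle_permanova_f(D, labels)
  f_all <- apply(utils::combn(n, n1), 2L, function(i1) {
    lab <- rep(g[2], n)
    lab[i1] <- g[1]
    oracle_permanova_f(D, lab)
  })
  mean(f_all >= f_obs - 1e-12)
}

toy_taxonomy <- function() {
  taxonomy_tree(data.frame(
    id = c("root", "F1", "G1", "G2", "S1", "S2", "S3"),
    parent = c("root", "root", "F1", "F1", "G1", "G1", "G2"),
    name = c("root", "Fam1", "Gen1", "Gen2", "Sp1", "Sp2", "Sp3"),
    rank = c("no rank", "family", "genus", "genus",
             "species", "species", "species"),
    stringsAsFactors = FALSE))
}

# Small study used by several test files; cached per session.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(study_config(n_dogs = 32, n_taxa = 48,
                                            seed = 2024L))
    }
    cache
  }
})
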