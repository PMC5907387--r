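test_that("rank aggregation sums by taxon and pools unassigned mass", {
  abund <- rbind(s1 = c(0.3, 0.4), s2 = c(0.2, 0.1), s3 = c(0.5, 0.5))
  colnames(abund) <- c("A", "B")
  lin <- data.frame(feature = c("s1", "s2", "s3"),
                    genus = c("G1", "G1", NA),
                    phylum = c("P1", "P1", "P2"))
  g <- aggregate_rank(abund, lin, "genus")
  expect_equal(g["G1", ], c(A = 0.5, B = 0.5))
  expect_equal(g["unassigned", ], c(A = 0.5, B = 0.5))
  # all-unassigned at a rank collapses to a single unit row
  lin2 <- data.frame(feature = rownames(abund), family = NA_character_)
  f <- aggregate_rank(close_columns(abund), lin2, "family")
  expect_equal(nrow(f), 1L)
  expect_equal(unname(f[1, ]), c(1, 1))
  # hand-summed three-genus toy table
  lin3 <- data.frame(feature = rownames(abund),
                     genus = c("Ga", "Gb", "Gc"))
  g3 <- aggregate_rank(abund, lin3, "genus")
  expect_equal(g3[c("Ga", "Gb", "Gc"), "A"],
               c(Ga = 0.3, Gb = 0.2, Gc = 0.5))
  expect_error(aggregate_rank(abund, lin, "kingdom"), "unknown rank")
})

test_that("log transform applies per-feature detection-floor pseudo-counts", {
  m <- rbind(f1 = c(0, 0.001, 0.01), f2 = c(0.2, 0.2, 0.2))
  colnames(m) <- c("a", "b", "c")
  lt <- log_transform(m)
  expect_equal(unname(lt["f1", ]),
               c(log10(1e-4), log10(0.0011), log10(0.0101)))
  expect_equal(diff(range(lt["f2", ])), 0)
  fixed <- log_transform(m, "fixed:1e-6")
  expect_equal(unname(fixed["f1", 1]), log10(1e-6))
  allzero <- rbind(f1 = c(0, 0), f2 = c(0.1, 0.2))
  expect_warning(log_transform(allzero), "all-zero")
})

test_that("distances match hand arithmetic and an independent implementation", {
  x <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(distance_matrix(x, "bray_curtis")["a", "b"], 1)
  expect_equal(distance_matrix(x, "weighted_jaccard")["a", "b"], 1)
  y <- cbind(a = c(2, 2), b = c(1, 3))
  expect_equal(distance_matrix(y, "bray_curtis")["a", "b"], 0.25)
  expect_equal(distance_matrix(y, "weighted_jaccard")["a", "b"], 0.4)
  expect_equal(distance_matrix(y, "manhattan")["a", "b"], 2)
  same <- cbind(a = c(1, 2), b = c(1, 2))
  for (m in c("bray_curtis", "weighted_jaccard", "manhattan")) {
    expect_equal(distance_matrix(same, m)["a", "b"], 0)
  }
  expect_error(distance_matrix(cbind(a = -1, b = 1), "bray_curtis"),
               "nonnegative")
  skip_if_not_installed("vegan")
  set.seed(1)
  r <- matrix(runif(60), 6, 10, dimnames = list(letters[1:6], LETTERS[1:10]))
  ours <- distance_matrix(r, "bray_curtis")
  theirs <- as.matrix(vegan::vegdist(t(r), method = "bray"))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("distance invariants hold on random nonnegative profiles", {
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(rexp(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    for (m in c("bray_curtis", "weighted_jaccard")) {
      d <- distance_matrix(x, m)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0 & d <= 1))
    }
  }
})

test_that("PCoA reproduces Euclidean geometry and flags degeneracy", {
  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(pcoa(zero, 2)$coordinates == 0))
  # collinear triple: one positive eigenvalue, the second exactly zero
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  e <- pcoa(D3, 2)$eigenvalues
  expect_gt(e[1], 0)
  expect_lt(abs(e[2]), 1e-10)
  set.seed(3)
  pts <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(letters[1:8], letters[1:8])
  o <- pcoa(D, 7)
  expect_lt(max(abs(as.matrix(dist(o$coordinates)) - D)), 1e-8)
  expect_true(all(o$eigenvalues > -1e-10))
  # axis sign convention: the largest-magnitude loading is positive
  for (j in seq_len(ncol(o$coordinates))) {
    expect_gt(o$coordinates[which.max(abs(o$coordinates[, j])), j], 0)
  }
  expect_error(pcoa(D, 9), "exceeds")
  skip_if_not_installed("vegan")
  cm <- cmdscale(D, k = 2)
  expect_equal(abs(o$coordinates[, 1:2]), abs(cm), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PERMANOVA matches the independent F and exhaustive enumeration", {
  set.seed(11)
  x <- matrix(rexp(40), 8, 5, dimnames = list(NULL, paste0("s", 1:5)))
  x[, 4:5] <- x[, 4:5] * 3
  D <- distance_matrix(x, "bray_curtis")
  labels <- c("a", "a", "a", "b", "b")
  pm <- permanova(D, labels, mode = "exact")
  expect_equal(pm$pseudo_F, oracle_permanova_f(D, labels))
  expect_equal(pm$p_value, oracle_permanova_exact(D, labels))
  skip_if_not_installed("vegan")
  f_vegan <- vegan::adonis2(as.dist(D) ~ g,
                            data = data.frame(g = labels),
                            permutations = 99)$F[1]
  expect_equal(pm$pseudo_F, f_vegan, tolerance = 1e-10)
})

test_that("perfectly separated groups drive within-group variance to zero", {
  # two groups of mutually identical points at unit cross-distance
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  labels <- rep(c("a", "b"), each = 3)
  pm <- permanova(D, labels, mode = "exact")
  expect_true(is.infinite(pm$pseudo_F))
  # only the two arrangements reproducing the perfect split tie F = Inf
  expect_equal(pm$p_value, 2 / choose(6, 3))
  pm_mc <- permanova(D, labels, n_permutations = 199, seed = 1)
  expect_lte(pm_mc$p_value, 0.15)
  expect_error(permanova(D, c("a", rep("b", 5))), "2 samples")
})

test_that("paired shifts are zero for unchanged dogs and rank the arms", {
  st <- small_study()
  genus <- aggregate_rank(st$abundance, st$lineages, "genus")
  sh <- paired_shift(genus, st$metadata)
  expect_equal(nrow(sh), st$config$n_dogs)
  expect_true(all(sh$shift >= 0))
  # identical baseline/post -> shift exactly 0
  dup <- genus
  for (d in unique(st$metadata$dog_id)) {
    dup[, paste0(d, "_post")] <- dup[, paste0(d, "_baseline")]
  }
  sh0 <- paired_shift(dup, st$metadata)
  expect_true(all(sh0$shift == 0))
  # planted design: HPLC shifts dominate LPHC; OW dominates LN within HPLC
  cmp <- compare_shifts(sh, list(diet = "HPLC"))
  expect_lt(cmp$p.value, 0.05)
  expect_gt(cmp$medians[["focal"]], cmp$medians[["rest"]])
  med <- tapply(sh$shift, interaction(sh$diet, sh$condition), median)
  expect_gt(med[["HPLC.OW"]], med[["HPLC.LN"]])
})

test_that("dogs missing a timepoint are excluded with a message", {
  st <- small_study()
  genus <- aggregate_rank(st$abundance, st$lineages, "genus")
  drop <- colnames(genus)[1]   # a baseline sample
  expect_message(
    sh <- paired_shift(genus[, setdiff(colnames(genus), drop)],
                       st$metadata),
    "missing a timepoint")
  expect_equal(nrow(sh), st$config$n_dogs - 1L)
})

test_that("taxon-ratio tests handle signal, identity and degenerate ties", {
  st <- small_study()
  phylum <- aggregate_rank(st$abundance, st$lineages, "phylum")
  dietlab <- st$metadata$diet[match(colnames(phylum),
                                    st$metadata$sample_id)]
  fb <- ratio_test(phylum, "Firmicutes", "Bacteroidetes", dietlab)
  expect_lt(fb$test$p.value, 0.05)
  hp <- tapply(fb$ratios, dietlab, median)
  expect_gt(hp[["HPLC"]], hp[["LPHC"]])   # planted HPLC Firmicutes shift
  expect_equal(nrow(fb$pairwise), 3L)
  # numerator == denominator -> unit ratios, p = 1
  id <- ratio_test(phylum, "Firmicutes", "Firmicutes", dietlab)
  expect_true(all(id$ratios == 1))
  expect_equal(id$test$p.value, 1)
  # all-tied two-group case degenerates to p = 1
  m <- matrix(c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1), 2, 6,
              dimnames = list(c("n", "d"), paste0("s", 1:6)))
  tied <- ratio_test(m, "n", "d", rep(c("x", "y"), each = 3))
  expect_equal(tied$test$p.value, 1)
  expect_error(ratio_test(phylum, character(0), "Firmicutes", dietlab),
               "non-empty")
})

test_that("leave-out robustness enumerates subsets and flags single drivers", {
  st <- small_study()
  genus <- aggregate_rank(st$abundance, st$lineages, "genus",
                          keep_unassigned = FALSE)
  focal <- list(diet = "HPLC", condition = "OW")
  # g = 4, max_k = 3 -> 4 + 6 + 4 = 14 subsets
  g4 <- close_columns(genus[1:4, , drop = FALSE])
  r4 <- suppressWarnings(leave_out_robustness(g4, st$metadata, focal,
                                              max_k = 3))
  expect_equal(nrow(r4$results), 14L)
  expect_equal(table(r4$results$k), table(rep(1:3, c(4, 6, 4))),
               ignore_attr = TRUE)
  # closure is restored after every removal
  sub <- close_columns(g4[-1, , drop = FALSE])
  expect_true(all(abs(colSums(sub) - 1) < 1e-9))
  # effect spread over several genera survives all removals at k <= 2
  rr <- suppressWarnings(leave_out_robustness(genus, st$metadata, focal,
                                              max_k = 2))
  expect_true(rr$all_significant)
  # effect carried by one genus alone collapses when that genus is removed
  sc <- study_config(n_dogs = 32, n_taxa = 48,
                     effect_map = list(Turicibacter = c(HPLC = 3)),
                     ow_response_multiplier = 2, noise_sd = 0.15,
                     dog_effect_sd = 0.3, effect_sd = 0.2, seed = 77L)
  st1 <- simulate_study(sc)
  g1 <- aggregate_rank(st1$abundance, st1$lineages, "genus",
                       keep_unassigned = FALSE)
  r1 <- suppressWarnings(leave_out_robustness(g1, st1$metadata, focal,
                                              max_k = 1))
  expect_false(r1$all_significant)
  worst <- r1$results$removed[which.max(r1$results$p_value)]
  expect_equal(worst, "Turicibacter")
  expect_error(leave_out_robustness(g4[1:3, ], st$metadata, focal,
                                    max_k = 3), "too few")
})
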