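test_that("censored log-ratios follow the detection-limit rules", {
  cv <- censored_log_ratios(baseline = c(0.01, 0, 0, 0.1),
                            post = c(0.1, 0.01, 0, 0),
                            pseudo = 1e-12)
  expect_equal(nrow(cv), 3L)
  expect_equal(cv$value[1], 1, tolerance = 1e-6)   # log10(0.1/0.01)
  expect_equal(cv$status, c("observed", "right", "left"))
  expect_equal(attr(cv, "n_excluded"), 1L)         # the both-zero pair
  # default pseudo-count: lowest non-zero detection / 10
  cv2 <- censored_log_ratios(c(0.01, 0), c(0.1, 0.05))
  expect_equal(cv2$value[1], log10(0.101 / 0.011))
  # an explicit detection limit censors sub-limit (not just zero) values
  cv3 <- censored_log_ratios(c(1e-6, 0.01), c(0.01, 0.02),
                             detection_limit = 2e-5)
  expect_equal(cv3$status[1], "right")
  expect_error(censored_log_ratios(c(-0.1), c(0.1)), "negative")
})

test_that("gehan scores match the explicit case table and are antisymmetric", {
  expect_equal(gehan_score(make_cv(1), make_cv(2)), -1L)
  expect_equal(gehan_score(make_cv(0.5, "left"), make_cv(2)), -1L)
  expect_equal(gehan_score(make_cv(0.5, "left"), make_cv(3, "right")), -1L)
  expect_equal(gehan_score(make_cv(2), make_cv(2, "right")), 0L)  # touching
  # exhaustive 9-combination antisymmetry with ordered and tied values
  statuses <- c("observed", "left", "right")
  for (sa in statuses) for (sb in statuses) {
    for (vals in list(c(1, 2), c(2, 1), c(1.5, 1.5))) {
      a <- make_cv(vals[1], sa)
      b <- make_cv(vals[2], sb)
      expect_equal(gehan_score(a, b), -gehan_score(b, a))
      expect_equal(gehan_score(a, b),
                   oracle_score(vals[1], sa, vals[2], sb))
    }
  }
})

test_that("exact Gehan p-values equal exhaustive enumeration", {
  g1 <- make_cv(c(1, 2))
  g2 <- make_cv(c(3, 4))
  gt <- gehan_test(g1, g2, mode = "exact")
  expect_equal(gt$statistic, -4L)
  expect_equal(gt$p_value, 1 / 3)
  # identical multisets: W = 0 and every split ties -> p = 1
  sym <- gehan_test(make_cv(c(1, 2), c("observed", "left")),
                    make_cv(c(1, 2), c("observed", "left")),
                    mode = "exact")
  expect_equal(sym$statistic, 0L)
  expect_equal(sym$p_value, 1)
  expect_error(gehan_test(make_cv(numeric(0)), g2), "non-empty")
})

test_that("Monte Carlo mode agrees with exact mode within binomial error", {
  set.seed(5)
  g1 <- rand_cv(6, cens_frac = 0.4)
  g2 <- rand_cv(6, cens_frac = 0.4, shift = 0.5)
  ex <- gehan_test(g1, g2, mode = "exact")
  B <- 100000L
  mc <- gehan_test(g1, g2, mode = "monte_carlo", n_permutations = B,
                   seed = 9L)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / B)
  expect_lt(abs(mc$p_value - ex$p_value), 4 * se + 2 / B)
})

test_that("rejection rate grows with the planted location shift", {
  set.seed(31)
  rate <- vapply(c(0, 0.5, 1, 2), function(delta) {
    rej <- replicate(300, {
      g1 <- rand_cv(20, cens_frac = 0.3)
      g2 <- rand_cv(20, cens_frac = 0.3, shift = delta)
      gehan_test(g1, g2, mode = "monte_carlo", n_permutations = 199L,
                 seed = sample.int(1e6, 1))$p_value <= 0.05
    })
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.05))   # non-decreasing up to noise
  expect_lt(rate[1], 0.12)
  expect_gt(rate[4], 0.9)
})

test_that("two-stage BH reproduces hand-computed rejection sets", {
  r <- two_stage_bh(rep(0.001, 10), q = 0.05)
  expect_true(all(r$rejected))
  # worked 4-value example: stage-1 level 0.05/1.05 rejects one, so the
  # stage-2 level is 0.05 * 4/3 and still rejects exactly that one
  r4 <- two_stage_bh(c(0.001, 0.9, 0.95, 1.0), q = 0.05)
  expect_equal(r4$rejected, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r4$m0, 3L)
  r1 <- two_stage_bh(0.04, q = 0.05)
  expect_true(r1$rejected)
  expect_error(two_stage_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # stage 1 rejecting nothing means nothing is rejected
  flat <- two_stage_bh(c(0.4, 0.6, 0.8), q = 0.05)
  expect_false(any(flat$rejected))
  expect_equal(flat$q_values, p.adjust(c(0.4, 0.6, 0.8), "BH"))
})

test_that("prevalence tests match hypergeometric tails and find planted flips", {
  pres <- rbind(flip = rep(c(TRUE, FALSE), each = 10))
  grp <- rep(c("HPLC", "LPHC"), each = 10)
  r <- prevalence_test(pres, grp)
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  null <- prevalence_test(rbind(t = rep(c(TRUE, FALSE), 10)), grp)
  expect_equal(null$p_value, 1)
  # planted presence flip among noise taxa survives Bonferroni
  set.seed(8)
  noise <- matrix(runif(20 * 30) < 0.5, 20, 30,
                  dimnames = list(sprintf("n%02d", 1:20), NULL))
  pres2 <- rbind(planted = rep(c(TRUE, FALSE), each = 15), noise)
  grp2 <- rep(c("LPHC", "HPLC"), each = 15)
  r2 <- prevalence_test(pres2, grp2)
  expect_true(r2$significant[r2$taxon == "planted"])
  expect_false(any(r2$significant[r2$taxon != "planted"]))
  # joint 2x3 mode runs one test per taxon
  grp3 <- rep(c("Base", "HPLC", "LPHC"), each = 10)
  pres3 <- rbind(x = c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 10)))
  r3 <- prevalence_test(pres3, grp3, mode = "joint")
  expect_equal(nrow(r3), 1L)
  expect_lt(r3$p_value, 0.001)
  expect_error(prevalence_test(pres, rep("x", 20)), "2 diet groups")
})

test_that("gehan screen ranks planted responders first", {
  st <- small_study()
  scr <- gehan_screen(st$abundance, st$metadata, n_permutations = 199L,
                      seed = 3L)
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  expect_true(all(scr$q_value >= 0 & scr$q_value <= 1))
  planted <- rownames(st$truth$effects)[
    st$truth$effects[, "HPLC"] != 0 | st$truth$effects[, "LPHC"] != 0]
  top10 <- scr$feature[1:10]
  expect_gte(sum(top10 %in% planted), 8)
  expect_gt(sum(scr$rejected), 0)
})

test_that("log base only rescales censored values, never rank results", {
  set.seed(12)
  base <- runif(16, 0, 0.1) * rbinom(16, 1, 0.8)
  post <- runif(16, 0, 0.1) * rbinom(16, 1, 0.8)
  keep <- !(base == 0 & post == 0)
  cv10 <- censored_log_ratios(base, post)
  cv2 <- cv10
  cv2$value <- cv10$value / log10(2)   # change of base
  i <- seq_len(sum(keep)) <= sum(keep) / 2
  t10 <- gehan_test(cv10[i, ], cv10[!i, ], mode = "exact")
  t2 <- gehan_test(cv2[i, ], cv2[!i, ], mode = "exact")
  expect_equal(t10$statistic, t2$statistic)
  expect_equal(t10$p_value, t2$p_value)
})
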