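test_that("q-values are ranked cumulative complements of posterior probs", {
  expect_equal(q_values(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(q_values(c(0.99, 0.98)), c(0.01, 0.015))
  # locus with post_prob 0 collects the mean complement over all loci
  pp <- c(0.9, 0.5, 0)
  q <- q_values(pp)
  expect_equal(q[3], mean(1 - pp))
  # non-decreasing down the ranking, order-independent
  set.seed(3)
  pp2 <- runif(40)
  q2 <- q_values(pp2)
  expect_true(all(diff(q2[order(pp2, decreasing = TRUE)]) >= -1e-12))
  sh <- sample(40)
  expect_equal(q_values(pp2[sh]), q2[sh])
})

test_that("verdicts are a pure function of effect sign and threshold", {
  expect_equal(scan_verdict(c(1, -1, 1, -1), c(0.99, 0.99, 0.5, 0.5)),
               c("diversifying", "balancing", "neutral", "neutral"))
  expect_equal(scan_verdict(2, 0.95), "neutral")   # strict threshold
})

test_that("scan returns calibrated structures on a neutral fixture", {
  set.seed(61)
  des <- sim_design(n_plots = 6, n_loci = 25, sample_size_range = c(12, 20),
                    seed = 61)
  m <- gen_markers(des, gen_community(des))
  cfg <- scan_config(out_iterations = 150, thinning = 4, pilot_runs = 4,
                     pilot_length = 150, burn_in = 600, seed = 8)
  sc <- scan_outliers(m, cfg)
  r <- sc$results
  expect_true(all(r$post_prob >= 0 & r$post_prob <= 1))
  # exact-1 posterior probabilities are capped before q-values
  expect_true(all(r$post_prob <= 1 - 1 / cfg$out_iterations))
  expect_true(all(r$fdr >= 0 & r$fdr <= 1))
  expect_true(all(r$verdict %in% c("diversifying", "balancing", "neutral")))
  # adapted acceptance rates end near the 25-45% target band
  expect_true(all(sc$acceptance[c("q", "qbar", "beta")] > 0.1 &
                  sc$acceptance[c("q", "qbar", "beta")] < 0.7))
  # monomorphic loci never enter: the filter removes them upstream
  fr <- locus_frequencies(m)
  expect_true(all(sc$results$locus_id %in% filter_loci(fr)$retained))
})

test_that("a planted frequency gradient is flagged and chain halves agree", {
  set.seed(67)
  des <- sim_design(n_plots = 14, n_loci = 42, n_outlier_loci = 2,
                    sample_size_range = c(17, 53), seed = 67)
  m <- gen_markers(des, gen_community(des))
  truth <- attr(m, "truth")
  cfg <- scan_config(out_iterations = 300, thinning = 5, pilot_runs = 5,
                     pilot_length = 200, burn_in = 1500, seed = 8)
  sc <- scan_outliers(m, cfg)
  r <- sc$results
  planted <- r$locus_id %in% truth$outlier_loci
  expect_true(all(r$post_prob[planted] > 0.95))
  expect_true(all(r$alpha[planted] > 0))
  expect_true(all(r$verdict[planted] == "diversifying"))
  # the planted loci outrank every neutral locus
  expect_true(min(r$post_prob[planted]) >= max(r$post_prob[!planted]))

  # posterior inclusion probabilities from the two chain halves agree
  half <- nrow(sc$incl_samples) %/% 2
  pp1 <- colMeans(sc$incl_samples[seq_len(half), , drop = FALSE])
  pp2 <- colMeans(sc$incl_samples[(half + 1):nrow(sc$incl_samples), ,
                                  drop = FALSE])
  expect_lt(max(abs(pp1 - pp2)), 0.2)
})

test_that("detectability increases with the planted gradient range", {
  set.seed(71)
  pp_by_range <- vapply(list(c(0.35, 0.65), c(0.05, 0.95)), function(rng) {
    des <- sim_design(n_plots = 14, n_loci = 30, n_outlier_loci = 2,
                      outlier_range = rng, sample_size_range = c(17, 53),
                      seed = 71)
    m <- gen_markers(des, gen_community(des))
    cfg <- scan_config(out_iterations = 200, thinning = 5, pilot_runs = 4,
                       pilot_length = 150, burn_in = 1000, seed = 8)
    r <- scan_outliers(m, cfg)$results
    mean(r$post_prob[r$locus_id %in% attr(m, "truth")$outlier_loci])
  }, numeric(1))
  expect_lt(pp_by_range[1], pp_by_range[2])
  expect_gt(pp_by_range[2], 0.95)
})

test_that("scan rejects degenerate inputs", {
  m <- tiny_markers()
  expect_error(scan_outliers(subset_markers(m, plot = "P1"),
                             scan_config(fast = TRUE)), "at least two plots")
  expect_error(scan_outliers(m, scan_config(fast = TRUE), loci = character(0)),
               "no retained loci")
})
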