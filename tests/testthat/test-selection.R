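test_that("Bonferroni thresholds match the staged-testing arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 5, "one"), 0.01)
  expect_equal(bonferroni_threshold(0.05, 1, "one"), 0.05)
  expect_equal(round(bonferroni_threshold(0.05, 6, "two"), 3), 0.004)
  expect_error(bonferroni_threshold(0.05, 0), "count")
  expect_error(bonferroni_threshold(1.5, 5), "alpha")
})

make_scan <- function(pp, alpha = rep(1, length(pp)),
                      fdr = q_values(pp)) {
  data.frame(locus_id = sprintf("L%02d", seq_along(pp)), alpha = alpha,
             post_prob = pp, fdr = fdr, stringsAsFactors = FALSE)
}
make_ctests <- function(ids, p) {
  data.frame(locus_id = ids, p_value = p, stringsAsFactors = FALSE)
}

test_that("seven distinct survivors reduce to the five highest posteriors", {
  pp <- c(0.999, 0.998, 0.997, 0.996, 0.995, 0.994, 0.993)
  scan <- make_scan(pp)
  ct <- make_ctests(scan$locus_id, rep(0.02, 7))
  dec <- select_candidates(scan, ct)
  expect_equal(sum(dec$selected_topk), 5)
  expect_equal(dec$locus_id[dec$selected_topk], scan$locus_id[1:5])
  expect_equal(attr(dec, "m"), 5L)
  expect_equal(attr(dec, "threshold"), 0.01)
  # p = 0.02 passes the uncorrected stage but not the corrected one
  expect_false(any(dec$significant_after_bonferroni))
})

test_that("ties at the fifth posterior enlarge the Bonferroni family", {
  pp <- c(0.999, 0.998, 0.997, 0.996, 0.995, 0.995)
  scan <- make_scan(pp)
  ct <- make_ctests(scan$locus_id, rep(0.005, 6))
  dec <- select_candidates(scan, ct)
  expect_equal(sum(dec$selected_topk), 6)
  expect_equal(attr(dec, "m"), 6L)
  expect_equal(attr(dec, "threshold"), 0.05 / 6)
  expect_true(all(dec$significant_after_bonferroni))
})

test_that("fewer survivors than k keeps them all with a reduced family", {
  scan <- make_scan(c(0.99, 0.97, 0.2))
  ct <- make_ctests(scan$locus_id, c(0.004, 0.04, 0.001))
  dec <- select_candidates(scan, ct)
  expect_equal(sum(dec$selected_topk), 2)
  expect_equal(attr(dec, "m"), 2L)
  expect_equal(dec$significant_after_bonferroni,
               c(TRUE, FALSE, FALSE))  # 0.004 < 0.025, 0.04 > 0.025
})

test_that("loci failing the scan stage never reach later stages", {
  scan <- make_scan(c(0.5, 0.4), alpha = c(1, -1))
  ct <- make_ctests(scan$locus_id, c(0.001, 0.001))
  dec <- select_candidates(scan, ct)
  expect_false(any(dec$passed_scan))
  expect_false(any(dec$selected_topk))
  expect_equal(attr(dec, "m"), 0L)
  expect_true(is.na(attr(dec, "threshold")))
  # negative alpha blocks the scan stage even at high posterior
  scan2 <- make_scan(c(0.99), alpha = -2)
  dec2 <- select_candidates(scan2, make_ctests("L01", 0.001))
  expect_false(dec2$passed_scan)
})

test_that("decisions are deterministic and monotone in the C p-values", {
  set.seed(83)
  pp <- round(runif(12, 0.9, 1), 4)
  scan <- make_scan(pp)
  p0 <- runif(12, 0.001, 0.2)
  dec1 <- select_candidates(scan, make_ctests(scan$locus_id, p0))
  dec1b <- select_candidates(scan, make_ctests(scan$locus_id, p0))
  expect_identical(dec1, dec1b)
  # shrinking the surviving loci's p-values never removes one from the
  # selected set (the survivor set itself is held fixed)
  p1 <- ifelse(dec1$passed_C, p0 / 2, p0)
  dec2 <- select_candidates(scan, make_ctests(scan$locus_id, p1))
  expect_true(all(dec1$locus_id[dec1$selected_topk] %in%
                  dec2$locus_id[dec2$selected_topk]))
  # stage implications hold on arbitrary inputs
  expect_true(all(!dec1$selected_topk | dec1$passed_C))
  expect_true(all(!dec1$significant_after_bonferroni | dec1$selected_topk))
})
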