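test_that("delta reproduces its defining cases", {
  # complete differentiation: each plot's variant absent from the other
  expect_equal(delta_from_counts(rbind(c(10, 0), c(0, 10)))$delta, 1)
  # identical distributions
  expect_equal(delta_from_counts(rbind(c(6, 4), c(6, 4)))$delta, 0)
  # hand-computed half-L1 case
  d <- delta_from_counts(rbind(c(8, 2), c(4, 6)) * 5)
  expect_equal(d$D_j, c(0.4, 0.4))
  expect_equal(d$delta, 0.4)
  expect_error(delta_from_counts(rbind(c(0, 0), c(1, 1))), "zero individuals")
  expect_error(delta_from_counts(matrix(1, 1, 2)), "two plots")
})

test_that("delta matches the brute-force complement-distance oracle", {
  set.seed(37)
  # exhaustive 2x2 tables, counts 0..3, non-empty plots
  for (a in 0:3) for (b in 0:3) for (c in 0:3) for (d in 0:3) {
    if (a + b == 0 || c + d == 0) next
    cnt <- rbind(c(a, b), c(c, d))
    expect_equal(delta_from_counts(cnt)$delta, brute_delta_counts(cnt),
                 tolerance = 1e-12)
  }
  # random 3x3 tables
  for (rep in 1:100) {
    cnt <- matrix(sample(0:4, 9, replace = TRUE), 3, 3)
    if (any(rowSums(cnt) == 0)) next
    v <- delta_from_counts(cnt)$delta
    expect_equal(v, brute_delta_counts(cnt), tolerance = 1e-12)
    expect_true(v >= -1e-12 && v <= 1 + 1e-12)
  }
})

test_that("delta is invariant under relabeling and plot merging rules", {
  set.seed(41)
  for (rep in 1:30) {
    cnt <- matrix(sample(1:6, 6, replace = TRUE), 3, 2)
    d0 <- delta_from_counts(cnt)$delta
    expect_equal(delta_from_counts(cnt[, 2:1])$delta, d0, tolerance = 1e-12)
    expect_equal(delta_from_counts(cnt[c(2, 3, 1), ])$delta, d0,
                 tolerance = 1e-12)
  }
  # merging two plots with identical frequency distributions never
  # decreases delta: each half-plot's complement is diluted by the other
  # half, so the merged plot is at least as distinct from its complement
  for (rep in 1:30) {
    base <- sample(1:5, 3, replace = TRUE)
    other <- sample(1:5, 3, replace = TRUE)
    split3 <- rbind(base, base * 2, other)
    merged <- rbind(base * 3, other)
    expect_gte(delta_from_counts(merged)$delta,
               delta_from_counts(split3)$delta - 1e-12)
  }
})

test_that("marker-mode delta averages per-locus values over retained loci", {
  m <- tiny_markers()
  d <- delta_stat(m)
  per <- vapply(m$locus_ids, function(l) {
    x <- m$calls[, l]; ok <- !is.na(x)
    delta_from_counts(unclass(table(m$plot[ok], factor(x[ok], levels = 0:1))))$delta
  }, numeric(1))
  expect_equal(d$delta, mean(per))
  expect_equal(d$per_locus, per)
})

test_that("reassignment test behaves at the boundaries and the criterion", {
  # identical plots -> delta 0, p ~ 1
  v <- rep(c("a", "b"), 20)
  p <- rep(c("P1", "P2"), each = 20)
  dt <- differentiation_test(v, p, n_perm = 499, seed = 2)
  expect_equal(dt$delta, 0)
  expect_true(dt$p_value > 0.9)
  expect_false(dt$significant)
  expect_equal(dt$criterion, 0.05 / 12)

  # strong differentiation -> minimal add-one p, significant at 0.004
  v2 <- rep(c("a", "b"), each = 25)
  p2 <- rep(c("P1", "P2"), each = 25)
  dt2 <- differentiation_test(v2, p2, n_perm = 999, seed = 2)
  expect_equal(dt2$delta, 1)
  expect_equal(dt2$p_value, 1 / 1000)
  expect_true(dt2$significant)

  expect_warning(differentiation_test(v2, p2, n_perm = 99, seed = 1),
                 "cannot resolve")
})

test_that("reassignment p-values are roughly uniform under exchangeability", {
  set.seed(53)
  pvals <- replicate(120, {
    v <- sample(c("a", "b", "c"), 36, replace = TRUE)
    p <- rep(c("P1", "P2", "P3"), each = 12)
    differentiation_test(v, p, n_perm = 199, m = 1)$p_value
  })
  # level control at a few nominal points (tolerant binomial bands)
  expect_lt(mean(pvals <= 0.05), 0.13)
  expect_gt(mean(pvals <= 0.5), 0.32)
})
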