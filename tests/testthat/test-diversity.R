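test_that("hill numbers reproduce hand-computed profile values", {
  for (a in c(0, 0.5, 1, 2, 7, Inf))
    expect_equal(hill_number(rep(0.25, 4), a), 4)
  for (a in c(0, 1, 2, Inf))
    expect_equal(hill_number(1, a), 1)
  expect_equal(hill_number(c(0.7, 0.3), 2), 1 / 0.58, tolerance = 1e-12)
  expect_equal(hill_number(c(0.7, 0.3), Inf), 1 / 0.7, tolerance = 1e-12)
  expect_equal(hill_number(c(0.5, 0.5), 1), 2)
  # zero-frequency variants don't count toward richness
  expect_equal(hill_number(c(0.5, 0.5, 0), 0), 2)
  expect_error(hill_number(c(0.5, 0.4), 2), "sum to 1")
  expect_error(hill_number(c(1.2, -0.2), 2), "negative")
})

test_that("hill numbers agree with the Renyi-entropy oracle", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:25) {
    p <- rand_freqs(sample(2:12, 1))
    for (a in c(0, 1, 2)) {
      oracle <- exp(as.numeric(vegan::renyi(p, scales = a)))
      expect_equal(hill_number(p, a), oracle, tolerance = 1e-8)
    }
  }
})

test_that("profiles are monotone in order and replication-invariant", {
  set.seed(23)
  orders <- c(0, 0.5, 1, 1.5, 2, 4, Inf)
  for (rep in 1:200) {
    p <- rand_freqs(sample(2:10, 1))
    v <- vapply(orders, function(a) hill_number(p, a), numeric(1))
    expect_true(all(diff(v) <= 1e-10))
    expect_true(all(v >= 1 - 1e-12))
    # duplicating every variant's count leaves nu_a unchanged
    counts <- sample(1:20, length(p), replace = TRUE)
    p1 <- counts / sum(counts)
    p2 <- (2 * counts) / sum(2 * counts)
    a <- sample(orders, 1)
    expect_equal(hill_number(p2, a), hill_number(p1, a), tolerance = 1e-10)
  }
})

test_that("species profiles evaluate plot abundance distributions", {
  ab <- abundance_table(rbind(P1 = c(A = 10, B = 10, C = 10),
                              P2 = c(A = 70, B = 20, C = 10)))
  expect_equal(unname(species_profile(ab, "P1")), c(3, 3, 3))
  p2 <- species_profile(ab, "P2")
  expect_equal(unname(p2), c(3, 1 / 0.54, 1 / 0.7), tolerance = 1e-10)
  expect_error(species_profile(ab, "P9"), "unknown plot")
})

test_that("locus diversity supports both bias-correction modes", {
  fr <- data.frame(locus_id = "L1", n = 10L, f_present = 0.7,
                   f_absent = 0.3, defined = TRUE)
  expect_equal(locus_diversity(fr, "none")$v_g2, 1 / 0.58, tolerance = 1e-12)
  expect_equal(locus_diversity(fr, "literal_factor")$v_g2,
               (1 / 0.58) * 10 / 9, tolerance = 1e-10)
  expect_equal(locus_diversity(fr, "unbiased_simpson")$v_g2,
               1 / ((10 * 0.58 - 1) / 9), tolerance = 1e-10)

  fr2 <- transform(fr, f_present = 0.5, f_absent = 0.5)
  expect_equal(locus_diversity(fr2, "none")$v_g2, 2)
  fr3 <- transform(fr, f_present = 1, f_absent = 0)
  expect_equal(locus_diversity(fr3, "none")$v_g2, 1)

  fr$n <- 1L
  expect_error(locus_diversity(fr, "literal_factor"), "n >= 2")
})

test_that("nu_2 via hill_number matches the raw locus-diversity path", {
  set.seed(5)
  for (f in runif(20)) {
    fr <- data.frame(locus_id = "L", n = 50L, f_present = f,
                     f_absent = 1 - f, defined = TRUE)
    expect_equal(locus_diversity(fr, "none")$v_g2,
                 hill_number(c(f, 1 - f)[c(f, 1 - f) > 0], 2),
                 tolerance = 1e-10)
  }
})

test_that("nu_mean,2 is the arithmetic locus average and stays bracketed", {
  ld <- data.frame(v_g2 = c(1.0, 2.0))
  expect_equal(mean_locus_diversity(ld), 1.5)
  expect_equal(mean_locus_diversity(data.frame(v_g2 = c(1.2, 1.5, 1.8))), 1.5)
  expect_equal(mean_locus_diversity(data.frame(v_g2 = rep(1.37, 9))), 1.37)
  set.seed(3)
  v <- 1 + runif(30)
  m <- mean_locus_diversity(data.frame(v_g2 = v))
  expect_true(m >= min(v) && m <= max(v))
  expect_error(mean_locus_diversity(data.frame(v_g2 = numeric())), "no defined")
})

test_that("diversity table carries a correct across-populations mean row", {
  set.seed(9)
  des <- sim_design(n_plots = 5, n_loci = 30, sample_size_range = c(10, 15),
                    seed = 9)
  com <- gen_community(des)
  m <- gen_markers(des, com)
  div <- diversity_table(com$abundance, m)
  expect_equal(nrow(div), 5)
  mr <- attr(div, "mean_row")
  expect_equal(unname(mr["nu_sp_0"]), mean(div$nu_sp_0))
  expect_equal(unname(mr["nu_mean_2"]), mean(div$nu_mean_2, na.rm = TRUE))
  expect_true(all(div$nu_mean_2 >= 1, na.rm = TRUE))
})
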