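test_that("generated communities respect the study-design constraints", {
  des <- sim_design(seed = 101)
  com <- gen_community(des)
  ab <- unclass(com$abundance)
  expect_equal(nrow(ab), 14)
  richness <- rowSums(ab > 0)
  expect_true(all(richness >= 4 & richness <= 9))
  expect_true(all(ab[, des$focal_species] > 0))
  expect_true(all(com$census$N >= 1))
  expect_error(sim_design(richness_range = c(4, 20), n_species_pool = 10,
                          seed = 1), "pool")
  expect_error(sim_design(n_plots = 14), "seed")
})

test_that("the same seed reproduces communities and markers exactly", {
  des <- sim_design(n_plots = 6, n_loci = 30, sample_size_range = c(8, 15),
                    n_outlier_loci = 2, seed = 202)
  c1 <- gen_community(des); c2 <- gen_community(des)
  expect_identical(unclass(c1$abundance), unclass(c2$abundance))
  expect_identical(c1$census, c2$census)
  m1 <- gen_markers(des, c1); m2 <- gen_markers(des, c2)
  expect_identical(m1$calls, m2$calls)
  expect_identical(attr(m1, "truth")$allele_freq,
                   attr(m2, "truth")$allele_freq)
})

test_that("realized background F_ST tracks the nominal level", {
  fst_hat <- vapply(1:50, function(s) {
    des <- sim_design(n_plots = 10, n_loci = 40, sample_size_range = c(5, 8),
                      background_fst = 0.05, seed = 5000 + s)
    Q <- attr(gen_markers(des, gen_community(des)), "truth")$allele_freq
    # Weir-style moment estimate from the latent plot allele frequencies
    mean(apply(Q, 2, function(q) var(q) / (mean(q) * (1 - mean(q)))))
  }, numeric(1))
  expect_lt(abs(mean(fst_hat) - 0.05), 0.02)
})

test_that("planted structure has the advertised marginal properties", {
  des <- sim_design(n_plots = 14, n_loci = 60, n_outlier_loci = 2,
                    sample_size_range = c(17, 53), seed = 303)
  m <- gen_markers(des, gen_community(des))
  tr <- attr(m, "truth")
  # gradient loci span >= 0.6 in per-plot allele frequency
  rng <- apply(tr$allele_freq[, tr$outlier_loci, drop = FALSE], 2,
               function(q) diff(range(q)))
  expect_true(all(rng >= 0.6))
  # most neutral pooled band frequencies fall inside the filter window
  fr <- locus_frequencies(m)
  neutral <- !(fr$locus_id %in% tr$outlier_loci)
  expect_gt(mean(fr$f_present[neutral] >= 0.05 &
                 fr$f_present[neutral] <= 0.95), 0.8)
})

test_that("zero coupling leaves locus frequencies independent of diversity", {
  cors <- vapply(1:50, function(s) {
    des <- sim_design(n_plots = 10, n_loci = 8, n_coupled_loci = 4,
                      coupling = 0, sample_size_range = c(5, 8),
                      seed = 7000 + s)
    m <- gen_markers(des, gen_community(des))
    tr <- attr(m, "truth")
    mean(apply(tr$allele_freq[, tr$coupled_loci, drop = FALSE], 2,
               function(q) cor(q, tr$nu_sp2)))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("strong coupling plants a monotone diversity-frequency link", {
  des <- sim_design(n_plots = 14, n_loci = 20, n_coupled_loci = 3,
                    coupling = 1, sample_size_range = c(10, 20), seed = 404)
  m <- gen_markers(des, gen_community(des))
  tr <- attr(m, "truth")
  for (l in tr$coupled_loci) {
    expect_equal(cor(tr$allele_freq[, l], tr$nu_sp2, method = "spearman"), 1)
  }
})
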