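#' Run the full community-genetics analysis pipeline
#'
#' Chains every stage on either a synthetic design or user-supplied data:
#' locus filtering, plot-level diversity summaries (species profiles and
#' nu_mean,2), the Bayesian outlier scan, covariation tests between species
#' diversity and the genetic variables at the putative outlier loci, the
#' staged candidate selection with Bonferroni correction, and the
#' differentiation test delta on the species composition.  Optionally writes
#' the report bundle (TSV tables, JSON records and a run manifest) to
#' `out_dir`.
#'
#' @param design a [sim_design()]; when supplied, inputs are generated and
#'   the truth manifest is written alongside the reports.
#' @param markers,abundance,census alternatively, a [marker_matrix()], an
#'   [abundance_table()] and (optionally) a census data.frame
#'   (plot, species, N).
#' @param n_perm permutations for every permutation test.
#' @param scan_cfg a [scan_config()].
#' @param correction_mode bias-correction mode for nu_g,2.
#' @param k top-posterior-probability count for the selection stage.
#' @param alpha family-wise significance level.
#' @param m_delta hypothesis count of the delta test's Bonferroni family.
#' @param seed base seed when no design is given (a design's own seed is
#'   used otherwise); stage seeds are derived from it.
#' @param out_dir optional directory for the report bundle.
#' @return object of class `community_pipeline`: `diversity` (table),
#'   `scan`, `ctests`, `ctests_mean`, `ctests_census`, `decisions`,
#'   `delta`, `retained`, `manifest`, and `truth` when synthetic.
#' @export
run_pipeline <- function(design = NULL, markers = NULL, abundance = NULL,
                         census = NULL, n_perm = 5000,
                         scan_cfg = scan_config(),
                         correction_mode = "literal_factor",
                         k = 5, alpha = 0.05, m_delta = 6,
                         seed = 1L, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL
  if (!is.null(design)) {
    community <- gen_community(design)
    abundance <- community$abundance
    census <- community$census
    markers <- gen_markers(design, community)
    truth <- attr(markers, "truth")
    seed <- design$seed
  }
  if (is.null(markers) || is.null(abundance))
    stop("either a design or both markers and abundance are required")
  seed <- as.integer(seed) %% 2000000000L

  # stage 1: frequencies + filter
  freqs <- locus_frequencies(markers)
  filt <- filter_loci(freqs)
  if (length(filt$retained) == 0)
    stop("locus filter retained nothing; pipeline refuses to run")

  # stage 2: diversity summaries
  div <- diversity_table(abundance, markers, retained = filt$retained,
                         mode = correction_mode)
  t_div <- proc.time()[["elapsed"]]

  # stage 3: outlier scan
  scan_cfg$seed <- seed + 1001L
  scan <- scan_outliers(markers, scan_cfg, loci = filt$retained)
  t_scan <- proc.time()[["elapsed"]]

  # stage 4: covariation tests at the putative diversifying loci
  plots_m <- sort(unique(markers$plot))
  div_m <- div[match(plots_m, div$plot), ]
  survivors <- scan$results$locus_id[scan$results$verdict == "diversifying" &
                                     scan$results$fdr < 0.05]
  perplot <- lapply(plots_m, function(pl) locus_frequencies(markers, plot = pl))
  names(perplot) <- plots_m
  set.seed(seed + 2002L)
  ctests <- .covary_loci(survivors, perplot, div_m, n_perm, correction_mode)
  ctests_mean <- .covary_mean(div_m, n_perm)
  ctests_census <- NULL
  if (!is.null(census)) {
    Nvec <- census$N[match(plots_m, census$plot)]
    ctests_census <- .covary_census(Nvec, survivors, perplot, div_m, n_perm,
                                    correction_mode)
  }
  t_cov <- proc.time()[["elapsed"]]

  # stage 5: staged candidate selection
  decisions <- select_candidates(scan$results, ctests, k = k, alpha = alpha)

  # stage 6: differentiation among plots (species composition)
  ab <- unclass(abundance)
  ind_sp <- rep(colnames(ab), times = colSums(ab))
  ind_plot <- unlist(lapply(seq_len(ncol(ab)), function(s)
    rep(rownames(ab), times = ab[, s])), use.names = FALSE)
  delta <- differentiation_test(ind_sp, ind_plot, n_perm = n_perm,
                                seed = seed + 3003L, m = m_delta,
                                alpha = alpha)
  t_end <- proc.time()[["elapsed"]]

  manifest <- list(
    package_version = as.character(utils::packageVersion("commdiv")),
    r_version = R.version.string,
    seed = seed,
    stage_seeds = list(scan = seed + 1001L, covariation = seed + 2002L,
                       delta = seed + 3003L),
    n_perm = n_perm, alpha = alpha, k = k, m_delta = m_delta,
    correction_mode = correction_mode,
    filter = list(lower = filt$lower, upper = filt$upper,
                  retained = length(filt$retained),
                  excluded = nrow(filt$excluded)),
    scan_config = unclass(scan_cfg),
    selection = list(m = attr(decisions, "m"),
                     threshold = attr(decisions, "threshold")),
    timings = list(diversity = t_div - t0, scan = t_scan - t_div,
                   covariation = t_cov - t_scan, total = t_end - t0))

  res <- structure(list(diversity = div, scan = scan, ctests = ctests,
                        ctests_mean = ctests_mean,
                        ctests_census = ctests_census,
                        decisions = decisions, delta = delta,
                        retained = filt$retained, filter = filt,
                        freqs = freqs, manifest = manifest, truth = truth,
                        abundance = abundance, census = census),
                   class = "community_pipeline")
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

# per-plot genetic variables for one locus over aligned plots
.locus_vars <- function(locus, perplot, mode) {
  f_vr <- vapply(perplot, function(fr) fr$f_absent[fr$locus_id == locus],
                 numeric(1))
  v_g2 <- vapply(perplot, function(fr) {
    row <- fr[fr$locus_id == locus, ]
    if (!row$defined || row$n < 2) return(NA_real_)
    locus_diversity(row, mode = mode)$v_g2
  }, numeric(1))
  list(f_vr = f_vr, v_g2 = v_g2)
}

.ctest_row <- function(locus, a, var, x, y, n_perm) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NULL)
  ct <- covariation_test(x[ok], y[ok], n_perm = n_perm)
  data.frame(locus_id = locus, order = a, variable = var, C = ct$C,
             p_value = ct$p_value, n_plots = sum(ok), n_perm = ct$n_perm,
             exact = ct$exact, stringsAsFactors = FALSE)
}

.covary_loci <- function(loci, perplot, div_m, n_perm, mode) {
  rows <- list()
  orders <- c("0", "2", "inf")
  for (locus in loci) {
    lv <- .locus_vars(locus, perplot, mode)
    for (a in orders) {
      x <- div_m[[paste0("nu_sp_", a)]]
      rows[[length(rows) + 1]] <- .ctest_row(locus, a, "f_vr", x, lv$f_vr, n_perm)
      rows[[length(rows) + 1]] <- .ctest_row(locus, a, "v_g2", x, lv$v_g2, n_perm)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(), order = character(),
                      variable = character(), C = numeric(),
                      p_value = numeric(), n_plots = integer(),
                      n_perm = integer(), exact = logical(),
                      stringsAsFactors = FALSE)
  out
}

.covary_mean <- function(div_m, n_perm) {
  if (!"nu_mean_2" %in% names(div_m)) return(NULL)
  rows <- list()
  for (a in c("0", "2", "inf")) {
    rows[[length(rows) + 1]] <-
      .ctest_row("mean", a, "nu_mean_2", div_m[[paste0("nu_sp_", a)]],
                 div_m$nu_mean_2, n_perm)
  }
  do.call(rbind, rows)
}

.covary_census <- function(Nvec, loci, perplot, div_m, n_perm, mode) {
  rows <- list()
  rows[[length(rows) + 1]] <- .ctest_row("N", "2", "nu_sp_2", Nvec,
                                         div_m$nu_sp_2, n_perm)
  if ("nu_mean_2" %in% names(div_m))
    rows[[length(rows) + 1]] <- .ctest_row("N", "2", "nu_mean_2", Nvec,
                                           div_m$nu_mean_2, n_perm)
  for (locus in loci) {
    lv <- .locus_vars(locus, perplot, mode)
    rows[[length(rows) + 1]] <- .ctest_row(locus, "2", "N_x_v_g2", Nvec,
                                           lv$v_g2, n_perm)
    rows[[length(rows) + 1]] <- .ctest_row(locus, "2", "N_x_f_vr", Nvec,
                                           lv$f_vr, n_perm)
  }
  do.call(rbind, rows)
}

# report formatting: 2 decimals for diversities and C, 3 for alpha and
# thresholds, scientific notation below 1e-3 for p-values
.fmt_p <- function(p) ifelse(is.na(p), "NA",
                             ifelse(p < 1e-3, sprintf("%.2e", p),
                                    sprintf("%.3f", p)))
.fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
.fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

#' Write the pipeline report bundle
#'
#' Emits the analogues of the study's report tables: the per-plot diversity
#' table with its `across all populations` mean row, the outlier-candidate
#' table, the per-locus and per-species covariation tables, the census
#' covariation table, the selection decision ledger, the delta record and a
#' run manifest (JSON).  Raw full-precision values live in the JSON outputs;
#' the TSVs are rounded for reading.
#'
#' @param res a `community_pipeline` object.
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  div <- as.data.frame(res$diversity)
  tab2 <- data.frame(plot = c(div$plot, "across all populations"),
                     lapply(div[-1], function(col)
                       .fmt2(c(col, mean(col, na.rm = TRUE)))),
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab2, file.path(out_dir, "table2_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- res$scan$results
  tab3 <- data.frame(locus = sc$locus_id, alpha = .fmt3(sc$alpha),
                     posterior_probability = .fmt3(sc$post_prob),
                     FDR = .fmt3(sc$fdr), verdict = sc$verdict,
                     stringsAsFactors = FALSE)
  utils::write.table(tab3, file.path(out_dir, "table3_outliers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$ctests) > 0) {
    ct <- res$ctests
    tab4 <- data.frame(order = ct$order, locus = ct$locus_id,
                       variable = ct$variable, C = .fmt2(ct$C),
                       P = .fmt_p(ct$p_value), stringsAsFactors = FALSE)
  } else tab4 <- data.frame(order = character(), locus = character(),
                            variable = character(), C = character(),
                            P = character())
  utils::write.table(tab4, file.path(out_dir, "table4_covariation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$ctests_mean)) {
    cm <- res$ctests_mean
    tab5 <- data.frame(order = cm$order, C = .fmt2(cm$C),
                       P = .fmt_p(cm$p_value), stringsAsFactors = FALSE)
    utils::write.table(tab5, file.path(out_dir, "table5_mean_covariation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$ctests_census))
    utils::write.table(res$ctests_census,
                       file.path(out_dir, "census_covariation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$decisions),
                     file.path(out_dir, "selection_decisions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(delta = res$delta$delta,
                            c_j = as.list(res$delta$c_j),
                            D_j = as.list(res$delta$D_j),
                            p_value = res$delta$p_value,
                            n_perm = res$delta$n_perm,
                            criterion = res$delta$criterion,
                            significant = res$delta$significant),
                       file.path(out_dir, "delta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$truth)) {
    tr <- res$truth
    jsonlite::write_json(list(seed = tr$seed,
                              outlier_loci = tr$outlier_loci,
                              coupled_loci = tr$coupled_loci,
                              fis = tr$fis,
                              sample_sizes = as.list(tr$sample_sizes),
                              allele_freq = tr$allele_freq),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.community_pipeline <- function(x, ...) {
  cat("Community diversity / genetic-structure pipeline\n")
  cat(sprintf("  loci retained: %d of %d\n", length(x$retained),
              nrow(x$freqs)))
  sc <- x$scan$results
  cat(sprintf("  outlier scan: %d diversifying, %d balancing of %d loci\n",
              sum(sc$verdict == "diversifying"),
              sum(sc$verdict == "balancing"), nrow(sc)))
  cat(sprintf("  covariation tests: %d at candidate loci\n", nrow(x$ctests)))
  cat(sprintf("  selected top-%d: %d; significant after Bonferroni: %d\n",
              attr(x$decisions, "k"), sum(x$decisions$selected_topk),
              sum(x$decisions$significant_after_bonferroni)))
  cat(sprintf("  delta = %.3f, P(Z>=delta) = %.4g (%s)\n", x$delta$delta,
              x$delta$p_value,
              if (x$delta$significant) "significant" else "not significant"))
  invisible(x)
}
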