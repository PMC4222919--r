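#' Configuration for the outlier scan chain
#'
#' Defaults follow the published chain settings: 5,000 retained samples,
#' thinning 10, 20 pilot runs of 5,000 iterations (used to adapt proposal
#' scales toward 25-45% acceptance), 50,000 additional burn-in, prior odds
#' 10 for the neutral model, and a uniform prior on the within-population
#' inbreeding coefficient F_is over \[0, 1\].  `fast = TRUE` shortens every
#' chain component tenfold, the profile used by the test suite.
#'
#' @param out_iterations retained posterior sample count.
#' @param thinning thinning interval.
#' @param pilot_runs,pilot_length number and length of pilot runs.
#' @param burn_in additional burn-in iterations.
#' @param prior_odds_neutral prior odds P(neutral)/P(selected) per locus.
#' @param fis_bounds bounds of the uniform prior on F_is.
#' @param seed optional RNG seed for the chain.
#' @param fast logical; use the tenfold-shorter test profile.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(out_iterations = 5000, thinning = 10,
                        pilot_runs = 20, pilot_length = 5000,
                        burn_in = 50000, prior_odds_neutral = 10,
                        fis_bounds = c(0, 1), seed = NULL, fast = FALSE) {
  if (fast) {
    out_iterations <- max(1L, out_iterations %/% 10L)
    pilot_length <- max(1L, pilot_length %/% 10L)
    burn_in <- max(1L, burn_in %/% 10L)
  }
  cfg <- list(out_iterations = as.integer(out_iterations),
              thinning = as.integer(thinning),
              pilot_runs = as.integer(pilot_runs),
              pilot_length = as.integer(pilot_length),
              burn_in = as.integer(burn_in),
              prior_odds_neutral = prior_odds_neutral,
              fis_bounds = fis_bounds, seed = seed, fast = fast)
  stopifnot(cfg$out_iterations > 0, cfg$thinning > 0, cfg$pilot_runs >= 0,
            cfg$pilot_length > 0, cfg$burn_in >= 0,
            cfg$prior_odds_neutral > 0,
            length(fis_bounds) == 2, fis_bounds[1] >= 0, fis_bounds[2] <= 1,
            fis_bounds[1] < fis_bounds[2])
  class(cfg) <- "scan_config"
  cfg
}

#' Bayesian F_ST outlier scan for dominant binary loci
#'
#' Reimplements the multinomial-Dirichlet outlier model for dominant data:
#' plot allele frequencies at locus i follow a beta distribution around the
#' ancestral frequency with concentration (1 - F_ST)/F_ST, where
#' logit(F_ST_ij) = alpha_i + beta_j; the band-absence phenotype count in a
#' plot is binomial with probability q^2 + F_is q(1 - q).  A reversible-jump
#' MCMC toggles each locus-specific component alpha_i between 0 (neutral)
#' and free (prior N(0, 1)) with the configured prior odds; beta_j has a
#' N(-2, 1.8) prior and F_is a uniform prior per population.  The scan
#' reports the posterior mean of alpha (model-averaged), the posterior
#' inclusion probability, a q-value per locus and a verdict:
#' `diversifying` (alpha > 0, posterior probability > 0.95), `balancing`
#' (alpha < 0, > 0.95) or `neutral`.
#'
#' Posterior probabilities of exactly 1 are capped at
#' 1 - 1/(retained samples) before q-values are computed, so sampling error
#' is never hidden behind a q-value of exactly zero.
#'
#' @param m a [marker_matrix()] for one species over >= 2 plots.
#' @param cfg a [scan_config()].
#' @param loci locus ids to scan (pre-filtered; defaults to the 0.05/0.95
#'   frequency filter on the pooled individuals).
#' @return object of class `outlier_scan` with elements `results`
#'   (data.frame: locus_id, alpha, post_prob, fdr, verdict), `acceptance`,
#'   `scales`, `config`, `plots`, and the retained `alpha_samples` /
#'   `incl_samples` matrices.
#' @export
scan_outliers <- function(m, cfg = scan_config(), loci = NULL) {
  if (is.null(loci)) loci <- filter_loci(locus_frequencies(m))$retained
  if (length(loci) == 0) stop("no retained loci to scan")
  plots <- sort(unique(m$plot))
  if (length(plots) < 2) stop("the scan needs at least two plots")
  X <- m$calls[, loci, drop = FALSE]
  pf <- factor(m$plot, levels = plots)
  A <- rowsum(+(!is.na(X) & X == 0), pf)            # band-absence counts
  Nn <- rowsum(+(!is.na(X)), pf)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fit <- scan_mcmc_cpp(A, Nn, cfg$out_iterations, cfg$thinning,
                       cfg$pilot_runs, cfg$pilot_length, cfg$burn_in,
                       cfg$prior_odds_neutral, cfg$fis_bounds[1],
                       cfg$fis_bounds[2], 1.0, -2.0, 1.8)
  if (any(fit$acceptance[c("q", "qbar", "beta")] < 0.1 |
          fit$acceptance[c("q", "qbar", "beta")] > 0.7, na.rm = TRUE))
    warning("acceptance rates outside the adapted band after all pilot runs: ",
            paste(sprintf("%s=%.2f", names(fit$acceptance), fit$acceptance),
                  collapse = ", "))
  pp <- colMeans(fit$incl_samples)
  pp <- pmin(pp, 1 - 1 / cfg$out_iterations)
  a_mean <- colMeans(fit$alpha_samples)
  res <- data.frame(locus_id = loci, alpha = a_mean, post_prob = pp,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$fdr <- q_values(res$post_prob)
  res$verdict <- scan_verdict(res$alpha, res$post_prob)
  structure(list(results = res, acceptance = fit$acceptance,
                 scales = fit$scales, pilot_rates = fit$pilot_rates,
                 config = cfg, plots = plots,
                 alpha_samples = fit$alpha_samples,
                 incl_samples = fit$incl_samples),
            class = "outlier_scan")
}

#' q-values from posterior inclusion probabilities
#'
#' Loci are ranked by posterior probability (descending); the q-value of a
#' locus is the mean of (1 - posterior probability) over all loci at or
#' above its rank — the expected proportion of false positives among the
#' markers declared outliers down to that rank.
#'
#' @param post_prob posterior inclusion probabilities.
#' @return q-values in the input order; non-decreasing as posterior
#'   probability decreases.
#' @export
q_values <- function(post_prob) {
  ord <- order(post_prob, decreasing = TRUE)
  q_sorted <- cumsum(1 - post_prob[ord]) / seq_along(ord)
  q <- numeric(length(post_prob))
  q[ord] <- q_sorted
  q
}

#' Verdict mapping for scanned loci
#'
#' A pure function of the sign of alpha and the posterior-probability
#' threshold.
#'
#' @param alpha posterior mean locus effects.
#' @param post_prob posterior inclusion probabilities.
#' @param threshold posterior-probability threshold (default 0.95).
#' @return character vector: `"diversifying"`, `"balancing"` or `"neutral"`.
#' @export
scan_verdict <- function(alpha, post_prob, threshold = 0.95) {
  ifelse(post_prob > threshold & alpha > 0, "diversifying",
         ifelse(post_prob > threshold & alpha < 0, "balancing", "neutral"))
}

#' @export
print.outlier_scan <- function(x, ...) {
  r <- x$results
  cat(sprintf("Outlier scan: %d loci x %d plots, %d retained samples\n",
              nrow(r), length(x$plots), x$config$out_iterations))
  cat(sprintf("  diversifying: %d, balancing: %d (post_prob > 0.95)\n",
              sum(r$verdict == "diversifying"), sum(r$verdict == "balancing")))
  cat("  acceptance:",
      paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.outlier_scan <- function(object, fdr_max = 0.05, post_min = 0.95, ...) {
  r <- object$results
  out <- r[r$fdr < fdr_max & r$post_prob > post_min, , drop = FALSE]
  out <- out[order(out$post_prob, decreasing = TRUE), ]
  cat(sprintf("Candidate loci (FDR < %g, posterior probability > %g):\n",
              fdr_max, post_min))
  if (nrow(out) == 0) cat("  none\n") else
    print.data.frame(out, row.names = FALSE, digits = 3)
  invisible(out)
}

#' @export
plot.outlier_scan <- function(x, post_min = 0.95, ...) {
  r <- x$results
  graphics::plot(r$post_prob, r$alpha, xlab = "posterior probability",
                 ylab = "locus effect alpha",
                 pch = ifelse(r$verdict == "neutral", 1, 19), ...)
  graphics::abline(v = post_min, lty = 2)
  invisible(x)
}

#' @export
coef.outlier_scan <- function(object, ...) {
  stats::setNames(object$results$alpha, object$results$locus_id)
}
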