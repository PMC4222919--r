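#' Bonferroni-corrected per-test level
#'
#' One-sided families use alpha/m (0.05 over m = 5 comparisons gives 0.01);
#' the two-sided usage for the delta test uses alpha/(2 m) (0.05 over m = 6
#' hypotheses gives ~0.004).
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of comparisons (hypotheses), m >= 1.
#' @param sided `"one"` or `"two"`.
#' @return corrected per-test level.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a count >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (sided == "one") alpha / m else alpha / (2 * m)
}

#' Staged candidate-locus selection
#'
#' Implements the staged procedure tying the outlier scan and the
#' covariation tests together:
#' 1. scan stage: keep loci with FDR (q-value) < 0.05, posterior
#'    probability > 0.95 and alpha > 0 (putative differential selection);
#' 2. covariation stage: of these, keep loci with at least one covariation
#'    test significant at the uncorrected level (p < `alpha`);
#' 3. rank survivors by posterior probability and keep the `k` highest
#'    (default 5); ties at rank k are all kept and m is enlarged to the
#'    number kept;
#' 4. Bonferroni stage: the selected loci's covariation p-values face the
#'    corrected one-sided level `alpha / m`; a locus is flagged when any of
#'    its tests passes it.
#'
#' @param scan data.frame with columns `locus_id`, `alpha`, `post_prob`,
#'   `fdr` (e.g. the `results` of [scan_outliers()]).
#' @param ctests data.frame of per-locus covariation tests with columns
#'   `locus_id`, `p_value` (and typically `order`, `variable`, `C`).
#' @param k number of top posterior probabilities to select (default 5).
#' @param alpha family-wise level (default 0.05).
#' @param fdr_max,post_min scan-stage thresholds (defaults 0.05 / 0.95).
#' @return data.frame of class `candidate_decisions`, one row per scanned
#'   locus with logical stage columns `passed_scan`, `passed_C`,
#'   `selected_topk`, `significant_after_bonferroni` and `min_p` (smallest
#'   covariation p).  Attributes `m` (effective family size) and
#'   `threshold` (corrected level; NA when no locus reaches stage 3).
#' @export
select_candidates <- function(scan, ctests, k = 5, alpha = 0.05,
                              fdr_max = 0.05, post_min = 0.95) {
  stopifnot(all(c("locus_id", "alpha", "post_prob", "fdr") %in% names(scan)))
  passed_scan <- scan$fdr < fdr_max & scan$post_prob > post_min & scan$alpha > 0
  minp <- vapply(scan$locus_id, function(id) {
    p <- ctests$p_value[ctests$locus_id == id]
    if (length(p) == 0) NA_real_ else min(p)
  }, numeric(1))
  passed_C <- passed_scan & !is.na(minp) & minp < alpha
  sel <- rep(FALSE, nrow(scan))
  m_eff <- 0L
  thr <- NA_real_
  surv <- which(passed_C)
  if (length(surv) > 0) {
    pp <- scan$post_prob[surv]
    if (length(surv) <= k) {
      sel[surv] <- TRUE
    } else {
      cut <- sort(pp, decreasing = TRUE)[k]
      sel[surv[pp >= cut]] <- TRUE   # ties at rank k all kept
    }
    m_eff <- sum(sel)
    thr <- bonferroni_threshold(alpha, m_eff, sided = "one")
  }
  sig <- sel & !is.na(minp) & minp < ifelse(is.na(thr), 0, thr)
  out <- data.frame(locus_id = scan$locus_id, alpha = scan$alpha,
                    post_prob = scan$post_prob, fdr = scan$fdr,
                    min_p = minp, passed_scan = passed_scan,
                    passed_C = passed_C, selected_topk = sel,
                    significant_after_bonferroni = sig,
                    stringsAsFactors = FALSE)
  attr(out, "m") <- m_eff
  attr(out, "threshold") <- thr
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  class(out) <- c("candidate_decisions", "data.frame")
  out
}

#' @export
print.candidate_decisions <- function(x, ...) {
  cat(sprintf("Candidate selection: %d scanned, %d passed scan, %d passed C,",
              nrow(x), sum(x$passed_scan), sum(x$passed_C)))
  cat(sprintf(" %d selected (m = %d), %d significant after Bonferroni\n",
              sum(x$selected_topk), attr(x, "m"),
              sum(x$significant_after_bonferroni)))
  if (any(x$selected_topk)) {
    print.data.frame(as.data.frame(x)[x$selected_topk, ], row.names = FALSE,
                     digits = 3)
  }
  invisible(x)
}
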