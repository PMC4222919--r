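#' Hill number (effective number of variants) of order a
#'
#' The diversity profile nu_a of a frequency distribution p:
#' \deqn{\nu_a = \left(\sum_i p_i^a\right)^{1/(1-a)}}
#' with the limits nu_0 = number of variants with positive frequency
#' (richness), nu_1 = exp(Shannon entropy), nu_2 = 1 / sum p_i^2 (Simpson
#' effective number) and nu_Inf = 1 / max p_i (number of prevalent variants).
#' nu_a is non-increasing in a and equals the number of variants k exactly
#' when p is uniform.
#'
#' Zero-frequency variants are dropped before evaluation (0^a = 0 for a > 0;
#' they do not count toward richness at a = 0).  The order a = 1 is handled
#' by the entropy limit rather than the numerically unstable general formula
#' (switch within |a - 1| < 1e-9).
#'
#' @param p nonnegative frequencies summing to 1 (tolerance 1e-6).
#' @param a diversity order, a >= 0 or `Inf`.
#' @return the effective number of variants, a scalar >= 1.
#' @export
hill_number <- function(p, a) {
  if (any(is.na(p))) stop("p contains NA")
  if (any(p < 0)) stop("negative frequencies in p")
  if (abs(sum(p) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  if (length(a) != 1 || is.na(a) || a < 0) stop("a must be a single order >= 0")
  p <- p[p > 0]
  if (a == 0) return(length(p))
  if (is.infinite(a)) return(1 / max(p))
  if (abs(a - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^a)^(1 / (1 - a))
}

#' Species diversity profile of a plot
#'
#' Normalizes the plot's species counts and evaluates the Hill numbers at the
#' requested orders: by default richness (a = 0), Simpson effective number
#' (a = 2) and the number of prevalent species (a = Inf).
#'
#' @param t an [abundance_table()].
#' @param plot plot code (row of `t`).
#' @param orders diversity orders to evaluate.
#' @return named numeric vector of nu_sp values, one per order.
#' @export
species_profile <- function(t, plot, orders = c(0, 2, Inf)) {
  if (!plot %in% rownames(t)) stop("unknown plot: ", plot)
  counts <- unclass(t)[plot, ]
  if (sum(counts) == 0) stop("plot ", plot, " has no individuals")
  p <- counts / sum(counts)
  v <- vapply(orders, function(a) hill_number(p, a), numeric(1))
  names(v) <- paste0("nu_sp_", ifelse(is.infinite(orders), "inf", orders))
  v
}

#' Per-locus genetic diversity nu_g,2
#'
#' The effective number of the two band-phenotype variants at each dominant
#' locus, nu_g,2 = 1 / (f1^2 + f2^2), optionally bias-corrected for sample
#' size:
#' * `"literal_factor"` (default): multiplies the raw value by n/(n-1).
#' * `"unbiased_simpson"`: the classical unbiased concentration estimator,
#'   1 / ((n * (f1^2 + f2^2) - 1) / (n - 1)).
#' * `"none"`: no correction.
#'
#' @param freqs a `locus_freqs` data.frame from [locus_frequencies()].
#' @param mode bias-correction mode.
#' @return `freqs` with an added `v_g2` column (NA for undefined loci);
#'   class `locus_diversity`.
#' @export
locus_diversity <- function(freqs,
                            mode = c("literal_factor", "unbiased_simpson", "none")) {
  mode <- match.arg(mode)
  S <- freqs$f_present^2 + freqs$f_absent^2
  raw <- 1 / S
  n <- freqs$n
  if (mode != "none" && any(freqs$defined & n < 2))
    stop("bias correction requires n >= 2 at every defined locus")
  v <- switch(mode,
              none = raw,
              literal_factor = raw * n / (n - 1),
              unbiased_simpson = 1 / ((n * S - 1) / (n - 1)))
  freqs$v_g2 <- ifelse(freqs$defined, v, NA_real_)
  attr(freqs, "correction_mode") <- mode
  class(freqs) <- unique(c("locus_diversity", class(freqs)))
  freqs
}

#' Mean genetic diversity per locus, nu_mean,2
#'
#' Unweighted arithmetic mean of nu_g,2 over the (retained, defined) loci of
#' one species in one unit.
#'
#' @param ld a `locus_diversity` data.frame from [locus_diversity()].
#' @return scalar mean.
#' @export
mean_locus_diversity <- function(ld) {
  v <- ld$v_g2[!is.na(ld$v_g2)]
  if (length(v) == 0) stop("no defined loci to average")
  mean(v)
}

#' Plot-level diversity summary table
#'
#' Builds the per-plot summary: species diversity profile (nu_sp,0, nu_sp,2,
#' nu_sp,Inf) and, when a marker matrix is supplied, the mean per-locus
#' genetic diversity nu_mean,2 of its species computed from plot-level locus
#' frequencies over the retained loci.  A final `across all populations` row
#' holds the arithmetic column means.
#'
#' @param t an [abundance_table()].
#' @param m optional [marker_matrix()] (one species).
#' @param retained optional locus ids to use (defaults to the 0.05/0.95
#'   filter applied to the species-pooled frequencies).
#' @param mode bias-correction mode passed to [locus_diversity()].
#' @return data.frame with one row per plot plus the mean row; attribute
#'   `mean_row` holds the means.
#' @export
diversity_table <- function(t, m = NULL, retained = NULL,
                            mode = "literal_factor") {
  plots <- rownames(t)
  prof <- t(vapply(plots, function(pl) species_profile(t, pl), numeric(3)))
  out <- data.frame(plot = plots, prof, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  if (!is.null(m)) {
    if (is.null(retained)) {
      retained <- filter_loci(locus_frequencies(m))$retained
    }
    if (length(retained) == 0) stop("no retained loci for nu_mean,2")
    vm <- rep(NA_real_, length(plots))
    for (k in seq_along(plots)) {
      if (!plots[k] %in% m$plot) next
      fr <- locus_frequencies(m, plot = plots[k])
      fr <- fr[fr$locus_id %in% retained & fr$defined & fr$n >= 2, , drop = FALSE]
      if (nrow(fr) == 0) next
      vm[k] <- mean_locus_diversity(locus_diversity(fr, mode = mode))
    }
    out$nu_mean_2 <- vm
  }
  mean_row <- colMeans(out[, -1, drop = FALSE], na.rm = TRUE)
  attr(out, "mean_row") <- mean_row
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' @export
print.diversity_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  cat("across all populations:",
      paste(sprintf("%s = %.3f", names(attr(x, "mean_row")),
                    attr(x, "mean_row")), collapse = ", "), "\n")
  invisible(x)
}
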