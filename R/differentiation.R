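#' Differentiation delta from a plot-by-variant count table
#'
#' For each plot j, D_j is the d0 (half-L1) distance between plot j's variant
#' frequency distribution and the pooled distribution of all remaining plots
#' (its complement); delta is the size-weighted mean
#' \deqn{\delta = \sum_j c_j D_j, \qquad c_j = n_j / \sum_k n_k.}
#' delta = 0 iff all plot distributions are identical; delta = 1 iff every
#' plot's variants are absent from its complement.
#'
#' @param counts nonnegative matrix, plots in rows, variants in columns;
#'   every plot must be non-empty.
#' @return list with `delta`, `c_j`, `D_j`.
#' @export
delta_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least two plots")
  n_j <- rowSums(counts)
  if (any(n_j == 0)) stop("plot(s) with zero individuals: ",
                          paste(which(n_j == 0), collapse = ", "))
  N <- sum(n_j)
  tot <- colSums(counts)
  p <- counts / n_j
  comp <- sweep(-counts, 2, tot, "+") / (N - n_j)  # pooled complement freqs
  D_j <- 0.5 * rowSums(abs(p - comp))
  c_j <- n_j / N
  list(delta = sum(c_j * D_j), c_j = c_j, D_j = D_j)
}

#' Differentiation parameter delta
#'
#' Two modes:
#' * default (species composition): `units` is a vector of variant labels
#'   (e.g. the species identity of each tree) with a parallel `plot` vector —
#'   one categorical trait.
#' * [marker_matrix()]: delta is computed per locus on the two band
#'   phenotypes (missing calls excluded locus-wise) and averaged, unweighted,
#'   over the selected loci.
#'
#' @param units variant labels per individual, or a [marker_matrix()].
#' @param plot plot label per individual (default mode only).
#' @param loci optional locus ids (marker mode; default all).
#' @return list with `delta`, `c_j`, `D_j` (marker mode: per-locus delta in
#'   `per_locus`, `c_j`/`D_j` averaged over loci for reporting).
#' @export
delta_stat <- function(units, plot = NULL, loci = NULL) {
  if (inherits(units, "marker_matrix")) {
    m <- units
    if (is.null(loci)) loci <- m$locus_ids
    X <- m$calls[, loci, drop = FALSE]
    plots <- sort(unique(m$plot))
    per <- numeric(length(loci))
    Dacc <- matrix(0, length(plots), length(loci))
    cacc <- matrix(0, length(plots), length(loci))
    for (k in seq_along(loci)) {
      x <- X[, k]
      ok <- !is.na(x)
      cnt <- table(factor(m$plot[ok], levels = plots),
                   factor(x[ok], levels = c(0, 1)))
      d <- delta_from_counts(unclass(cnt))
      per[k] <- d$delta
      Dacc[, k] <- d$D_j
      cacc[, k] <- d$c_j
    }
    list(delta = mean(per), per_locus = stats::setNames(per, loci),
         c_j = stats::setNames(rowMeans(cacc), plots),
         D_j = stats::setNames(rowMeans(Dacc), plots))
  } else {
    if (is.null(plot)) stop("plot labels required")
    cnt <- table(plot, units)
    d <- delta_from_counts(unclass(cnt))
    d$c_j <- stats::setNames(d$c_j, rownames(cnt))
    d$D_j <- stats::setNames(d$D_j, rownames(cnt))
    d
  }
}

#' Permutation test for delta by random reassignment
#'
#' Individuals are randomly reassigned to plots preserving the observed plot
#' sizes exactly; the upper-tail p-value P(Z >= delta_obs) uses the add-one
#' convention (1 + b)/(1 + B).  Significance is declared against the
#' two-sided Bonferroni-corrected criterion alpha/(2 m) — with the defaults
#' alpha = 0.05, m = 6 this is 0.05/12 ~ 0.004, i.e. the observed delta must
#' exceed 99.6% of reassignment deltas.
#'
#' @inheritParams delta_stat
#' @param n_perm number of reassignments (default 5000; a warning is issued
#'   when too small to resolve the criterion).
#' @param seed optional RNG seed.
#' @param m number of hypotheses in the Bonferroni family (default 6).
#' @param alpha family-wise level (default 0.05).
#' @return object of class `differentiation_test`: `delta`, `c_j`, `D_j`,
#'   `p_value`, `n_perm`, `criterion` (the corrected level), `significant`,
#'   `m`, `alpha`.
#' @export
differentiation_test <- function(units, plot = NULL, loci = NULL,
                                 n_perm = 5000, seed = NULL, m = 6,
                                 alpha = 0.05) {
  crit <- bonferroni_threshold(alpha, m, sided = "two")
  if (1 / (n_perm + 1) > crit)
    warning(sprintf("n_perm = %d cannot resolve the criterion %.4g", n_perm, crit))
  if (!is.null(seed)) set.seed(seed)
  obs <- delta_stat(units, plot, loci)
  if (inherits(units, "marker_matrix")) {
    mm <- units
    if (is.null(loci)) loci <- mm$locus_ids
    X <- mm$calls[, loci, drop = FALSE]
    plots <- sort(unique(mm$plot))
    pf <- factor(mm$plot, levels = plots)
    deltas <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pp <- pf[sample.int(length(pf))]
      per <- vapply(seq_len(ncol(X)), function(k) {
        x <- X[, k]; ok <- !is.na(x)
        delta_from_counts(unclass(table(pp[ok], factor(x[ok], levels = c(0, 1)))))$delta
      }, numeric(1))
      deltas[b] <- mean(per)
    }
  } else {
    plots <- sort(unique(plot))
    vlev <- sort(unique(units))
    deltas <- perm_delta_stats(
      as.integer(factor(units, levels = vlev)) - 1L,
      as.integer(factor(plot, levels = plots)) - 1L,
      length(plots), length(vlev), as.integer(n_perm))
  }
  p <- (1 + sum(deltas >= obs$delta - 1e-12)) / (1 + n_perm)
  structure(list(delta = obs$delta, c_j = obs$c_j, D_j = obs$D_j,
                 per_locus = obs$per_locus, p_value = p, n_perm = n_perm,
                 criterion = crit, significant = p < crit, m = m,
                 alpha = alpha),
            class = "differentiation_test")
}

#' @export
print.differentiation_test <- function(x, ...) {
  cat(sprintf("Differentiation among %d plots: delta = %.4f\n",
              length(x$c_j), x$delta))
  cat(sprintf("  P(Z >= delta) = %.4g  (%d reassignments)\n",
              x$p_value, x$n_perm))
  cat(sprintf("  criterion (two-sided Bonferroni, m = %d): %.4g -> %s\n",
              x$m, x$criterion,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
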