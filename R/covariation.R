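#' Covariation statistic C between two plot-level variables
#'
#' A bounded measure of monotone (not necessarily linear) co-movement:
#' \deqn{C = \frac{\sum_{i<j} (x_i - x_j)(y_i - y_j)}
#'                {\sum_{i<j} |x_i - x_j|\,|y_i - y_j|}}
#' C = 1 for an entirely positive (co-monotone) covariation, C = -1 for a
#' strictly negative one.  Tied pairs contribute 0 to both sums.  When the
#' denominator is zero (either variable constant) C is undefined and
#' `NA_real_` is returned.
#'
#' @param x,y numeric vectors aligned on the same plots, length >= 2.
#' @return C in \[-1, 1\], or `NA_real_` when undefined.
#' @export
covariation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned on the same plots")
  if (length(x) < 2) stop("need at least two plots")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  up <- upper.tri(dx)
  den <- sum(abs(dx[up]) * abs(dy[up]))
  if (den == 0) return(NA_real_)
  sum(dx[up] * dy[up]) / den
}

# all permutations of 1..n (n small); column-bound recursion
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' One-sided permutation test for the covariation C
#'
#' Permutes `y` across plots.  When the number of orderings `factorial(n)`
#' does not exceed `n_perm`, all orderings are enumerated and the exact
#' p-value `#\{C_perm >= C_obs\} / n!` is reported (plain convention; the
#' identity ordering is included so p > 0).  Otherwise `n_perm` random
#' permutations are drawn and the add-one convention
#' `(1 + #\{C_perm >= C_obs\}) / (1 + n_perm)` avoids p = 0.  Permuted data
#' with undefined C cannot be ranked and are excluded from both numerator
#' and denominator; their count is reported.
#'
#' @param x,y numeric vectors aligned on the same plots.
#' @param n_perm number of permutations (default 5000).
#' @param seed optional RNG seed for the sampled mode.
#' @param alternative `"greater"` (default, tests positive covariation) or
#'   `"less"`.
#' @param labels optional character pair naming x and y for printing.
#' @param exact `NULL` (auto: enumerate when `factorial(n) <= n_perm`),
#'   `TRUE` to force enumeration, or `FALSE` to force sampling.
#' @return object of class `covariation_test`: list with `C`, `p_value`,
#'   `n_perm` (effective count), `exact`, `n_undefined`, `alternative`,
#'   `status` (`"ok"` or `"undefined"`; no test is run when the observed C
#'   is undefined).
#' @export
covariation_test <- function(x, y, n_perm = 5000, seed = NULL,
                             alternative = c("greater", "less"),
                             labels = c("x", "y"), exact = NULL) {
  alternative <- match.arg(alternative)
  C_obs <- covariation(x, y)
  res <- list(C = C_obs, p_value = NA_real_, n_perm = 0L, exact = FALSE,
              n_undefined = 0L, alternative = alternative, labels = labels,
              n = length(x), status = "ok")
  class(res) <- "covariation_test"
  if (is.na(C_obs)) {
    res$status <- "undefined"
    return(res)
  }
  n <- length(x)
  tol <- 1e-12
  if (is.null(exact)) exact <- factorial(n) <= n_perm
  if (exact && factorial(n) > 362880)
    stop("exhaustive enumeration limited to 9 plots")
  if (exact) {
    P <- .all_perms(n)
    Cp <- vapply(seq_len(nrow(P)), function(r) covariation(x, y[P[r, ]]),
                 numeric(1))
    def <- !is.na(Cp)
    hits <- if (alternative == "greater") Cp[def] >= C_obs - tol
            else Cp[def] <= C_obs + tol
    res$p_value <- sum(hits) / sum(def)
    res$n_perm <- sum(def)
    res$n_undefined <- sum(!def)
    res$exact <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    Cp <- perm_C_stats(as.numeric(x), as.numeric(y), as.integer(n_perm))
    def <- is.finite(Cp)
    hits <- if (alternative == "greater") Cp[def] >= C_obs - tol
            else Cp[def] <= C_obs + tol
    res$p_value <- (1 + sum(hits)) / (1 + sum(def))
    res$n_perm <- sum(def)
    res$n_undefined <- sum(!def)
  }
  res
}

#' @export
print.covariation_test <- function(x, ...) {
  cat("Covariation permutation test:", x$labels[1], "x", x$labels[2], "\n")
  if (x$status == "undefined") {
    cat("  C undefined (zero denominator); no test performed\n")
    return(invisible(x))
  }
  cat(sprintf("  C = %+.4f over %d plots\n", x$C, x$n))
  cat(sprintf("  P(Z %s C) = %.4g  (%s, %d permutations%s)\n",
              if (x$alternative == "greater") ">=" else "<=",
              x$p_value, if (x$exact) "exhaustive" else "sampled",
              x$n_perm,
              if (x$n_undefined > 0)
                sprintf(", %d undefined excluded", x$n_undefined) else ""))
  invisible(x)
}
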