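# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each statistic from its definition with
# explicit loops, sharing no code with the package internals.

# covariation: literal double loop over unordered pairs
brute_C <- function(x, y) {
  num <- 0; den <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + (x[i] - x[j]) * (y[i] - y[j])
      den <- den + abs(x[i] - x[j]) * abs(y[i] - y[j])
    }
  }
  if (den == 0) NA_real_ else num / den
}

# differentiation: literal complement-distance definition on individuals
brute_delta <- function(variant, plot) {
  plots <- unique(plot)
  variants <- unique(variant)
  N <- length(variant)
  delta <- 0
  for (pl in plots) {
    inside <- variant[plot == pl]
    outside <- variant[plot != pl]
    D <- 0
    for (v in variants) {
      pj <- sum(inside == v) / length(inside)
      pc <- sum(outside == v) / length(outside)
      D <- D + abs(pj - pc)
    }
    delta <- delta + (length(inside) / N) * 0.5 * D
  }
  delta
}

brute_delta_counts <- function(counts) {
  v <- c(); p <- c()
  for (j in seq_len(nrow(counts))) for (k in seq_len(ncol(counts))) {
    v <- c(v, rep(k, counts[j, k])); p <- c(p, rep(j, counts[j, k]))
  }
  brute_delta(v, p)
}

# small deterministic marker fixture: 2 plots x 4 individuals x 3 loci
tiny_markers <- function() {
  calls <- rbind(c(1, 0, 1),
                 c(0, 0, 1),
                 c(1, 1, NA),
                 c(0, 1, 1))
  marker_matrix(calls,
                species = rep("SpA", 4),
                plot = c("P1", "P1", "P2", "P2"),
                individual_id = paste0("i", 1:4),
                locus_ids = c("La", "Lb", "Lc"))
}

# random frequency distribution over k variants
rand_freqs <- function(k) {
  w <- rexp(k)
  w / sum(w)
}
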