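#' Design for a synthetic tree-community study
#'
#' Defaults emulate the sampled study design: 14 plots of 0.25 ha, 4-9 tree
#' species per plot drawn from a pool of 12, per-plot genotype samples of
#' 17-53 individuals of one focal species, 240 polymorphic dominant loci,
#' island-model background differentiation F_ST = 0.05, and an optional
#' minority of loci under differential selection (per-plot frequency
#' gradients) and/or coupled to plot species diversity.
#'
#' @param n_plots number of plots.
#' @param n_species_pool size of the species pool (>= richness_range\[2\]).
#' @param richness_range min/max species per plot.
#' @param plot_total_range min/max trees per plot.
#' @param focal_species label of the genotyped species (always present in
#'   every plot it is genotyped in).
#' @param n_loci dominant loci for the focal species.
#' @param sample_size_range min/max genotyped individuals per plot.
#' @param background_fst island-model F_ST of neutral loci, in (0, 1).
#' @param fis within-population inbreeding coefficient used to mask
#'   genotypes into dominant band phenotypes.
#' @param n_outlier_loci loci planted under differential selection.
#' @param outlier_range per-plot allele-frequency gradient endpoints of
#'   planted outlier loci.
#' @param coupling strength (0-1) of the monotone link between plot species
#'   diversity (nu_sp,2) and the recessive-variant frequency at coupled loci.
#' @param n_coupled_loci loci carrying the diversity coupling.
#' @param missing_rate per-call missing probability.
#' @param census_fraction expected fraction of focal trees meeting the
#'   census size criterion (DBH >= 7 cm).
#' @param seed RNG seed (mandatory; every draw derives from it).
#' @return object of class `sim_design`.
#' @export
sim_design <- function(n_plots = 14, n_species_pool = 12,
                       richness_range = c(4, 9),
                       plot_total_range = c(60, 200),
                       focal_species = "FocalSp",
                       n_loci = 240, sample_size_range = c(17, 53),
                       background_fst = 0.05, fis = 0.1,
                       n_outlier_loci = 0, outlier_range = c(0.05, 0.95),
                       coupling = 0, n_coupled_loci = 0,
                       missing_rate = 0, census_fraction = 0.4,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_plots >= 2, background_fst > 0, background_fst < 1,
            coupling >= 0, coupling <= 1, fis >= 0, fis <= 1,
            missing_rate >= 0, missing_rate < 1,
            n_outlier_loci + n_coupled_loci <= n_loci)
  if (richness_range[2] > n_species_pool)
    stop("richness_range exceeds the species pool")
  structure(list(n_plots = n_plots, n_species_pool = n_species_pool,
                 richness_range = richness_range,
                 plot_total_range = plot_total_range,
                 focal_species = focal_species, n_loci = n_loci,
                 sample_size_range = sample_size_range,
                 background_fst = background_fst, fis = fis,
                 n_outlier_loci = n_outlier_loci,
                 outlier_range = outlier_range,
                 coupling = coupling, n_coupled_loci = n_coupled_loci,
                 missing_rate = missing_rate,
                 census_fraction = census_fraction, seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a synthetic community (abundances + census counts)
#'
#' Per plot, species richness is drawn uniformly within the design range,
#' the focal species is always included, the other species are a random
#' subset of the pool, and abundances follow a Dirichlet-multinomial.  The
#' census table gives the number of focal individuals meeting the size
#' criterion (binomial thinning of the focal abundance, at least 1).
#'
#' @param d a [sim_design()].
#' @return list with `abundance` (an [abundance_table()]) and `census`
#'   (data.frame plot, species, N).
#' @export
gen_community <- function(d) {
  set.seed(d$seed)
  plots <- sprintf("P%02d", seq_len(d$n_plots))
  pool <- c(d$focal_species,
            sprintf("Sp%02d", seq_len(d$n_species_pool - 1)))
  counts <- matrix(0L, d$n_plots, length(pool),
                   dimnames = list(plots, pool))
  for (j in seq_len(d$n_plots)) {
    r <- sample(seq(d$richness_range[1], d$richness_range[2]), 1)
    present <- c(d$focal_species, sample(pool[-1], r - 1))
    total <- sample(seq(d$plot_total_range[1], d$plot_total_range[2]), 1)
    w <- stats::rgamma(r, shape = 1)          # Dirichlet(1) weights
    n <- stats::rmultinom(1, total, w / sum(w))[, 1]
    # guarantee every listed species occurs at least once
    n[n == 0] <- 1L
    counts[j, present] <- as.integer(n)
  }
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  ab <- abundance_table(counts)
  census <- data.frame(plot = plots, species = d$focal_species,
                       N = pmax(1L, stats::rbinom(d$n_plots,
                                                  unclass(ab)[, d$focal_species],
                                                  d$census_fraction)),
                       stringsAsFactors = FALSE)
  list(abundance = ab, census = census)
}

# map v to [lo, hi] by rank, equally spaced; constant input maps to midpoint
.rank_map <- function(v, lo, hi) {
  if (diff(range(v)) == 0) return(rep((lo + hi) / 2, length(v)))
  lo + (rank(v, ties.method = "average") - 1) / (length(v) - 1) * (hi - lo)
}

#' Generate a binary marker matrix for the focal species
#'
#' Neutral loci: ancestral recessive-allele frequencies ~ Uniform(0.1, 0.9);
#' plot allele frequencies ~ Beta with concentration (1 - F_ST)/F_ST (island
#' model).  Planted outlier loci get a per-plot allele-frequency gradient
#' spanning `outlier_range` in plot order.  Coupled loci are
#' differential-selection loci whose per-plot recessive-allele frequency
#' follows the plot diversity ranking: the ranks of nu_sp,2 are spaced
#' equally over `outlier_range` and blended with a neutral draw,
#' q_j = coupling * rank_map(nu_sp,2_j) + (1 - coupling) * Beta draw, so
#' coupling = 0 reduces to neutrality and coupling = 1 is a deterministic
#' monotone function of plot diversity.  Band phenotypes are produced by
#' dominant masking: P(absence) = q^2 + F_is q(1 - q).  Both the allele
#' frequencies and the absence probabilities are recorded in the `truth`
#' attribute so truth-recovery tests can target either convention.
#'
#' @param d a [sim_design()].
#' @param community output of [gen_community()] for the same design.
#' @return a [marker_matrix()] with attribute `truth` (list: seed,
#'   allele_freq, absence_prob, outlier_loci, coupled_loci, fis,
#'   sample_sizes).
#' @export
gen_markers <- function(d, community) {
  set.seed(d$seed + 1L)
  ab <- community$abundance
  plots <- rownames(ab)
  J <- length(plots)
  nusp2 <- vapply(plots, function(pl) species_profile(ab, pl)[["nu_sp_2"]],
                  numeric(1))
  n_j <- sample(seq(d$sample_size_range[1], d$sample_size_range[2]), J,
                replace = TRUE)
  L <- d$n_loci
  loci <- sprintf("L%03d", seq_len(L))
  types <- rep("neutral", L)
  special <- sample(L, d$n_outlier_loci + d$n_coupled_loci)
  out_idx <- special[seq_len(d$n_outlier_loci)]
  cpl_idx <- setdiff(special, out_idx)
  types[out_idx] <- "outlier"
  types[cpl_idx] <- "coupled"
  theta <- (1 - d$background_fst) / d$background_fst
  Q <- matrix(0, J, L, dimnames = list(plots, loci))
  for (i in seq_len(L)) {
    qbar <- stats::runif(1, 0.1, 0.9)
    qn <- stats::rbeta(J, theta * qbar, theta * (1 - qbar))
    Q[, i] <- switch(types[i],
      neutral = qn,
      outlier = seq(d$outlier_range[1], d$outlier_range[2], length.out = J),
      coupled = d$coupling * .rank_map(nusp2, d$outlier_range[1],
                                       d$outlier_range[2]) +
                (1 - d$coupling) * qn)
  }
  Q <- pmin(pmax(Q, 1e-3), 1 - 1e-3)
  G <- Q^2 + d$fis * Q * (1 - Q)                 # band-absence probability
  calls <- matrix(NA_integer_, sum(n_j), L)
  plot_of <- rep(plots, n_j)
  for (j in seq_len(J)) {
    rows <- which(plot_of == plots[j])
    calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * L, 1, rep(1 - G[j, ], each = length(rows))),
      length(rows), L)
  }
  if (d$missing_rate > 0) {
    mis <- stats::runif(length(calls)) < d$missing_rate
    calls[mis] <- NA_integer_
  }
  m <- marker_matrix(calls, rep(d$focal_species, nrow(calls)), plot_of,
                     sprintf("%s_%04d", d$focal_species, seq_len(nrow(calls))),
                     loci)
  attr(m, "truth") <- list(seed = d$seed, allele_freq = Q, absence_prob = G,
                           outlier_loci = loci[out_idx],
                           coupled_loci = loci[cpl_idx],
                           fis = d$fis, sample_sizes = stats::setNames(n_j, plots),
                           nu_sp2 = nusp2)
  m
}
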