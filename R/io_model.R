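#' Construct a binary marker matrix
#'
#' A `marker_matrix` holds dominant binary (AFLP-type) genotype calls: one row
#' per genotyped individual, one column per locus, entries 1 (band present,
#' dominant variant '1'), 0 (band absent, only recessive variants, variant
#' '2'), or `NA` for a failed call.  Every individual carries exactly one
#' species label and one plot label.
#'
#' @param calls numeric matrix of 0/1/`NA` calls, individuals in rows.
#' @param species character vector, species label per individual.
#' @param plot character vector, plot code per individual.
#' @param individual_id unique individual identifiers; defaults to rownames.
#' @param locus_ids unique locus identifiers; defaults to colnames.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, species, plot,
                          individual_id = rownames(calls),
                          locus_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(individual_id)) individual_id <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(calls)))
  individual_id <- as.character(individual_id)
  species <- as.character(species)
  plot <- as.character(plot)
  locus_ids <- as.character(locus_ids)
  if (length(species) != nrow(calls) || length(plot) != nrow(calls) ||
      length(individual_id) != nrow(calls))
    stop("species, plot and individual_id must have one entry per row of calls")
  if (length(locus_ids) != ncol(calls))
    stop("locus_ids length must equal the number of call columns")
  if (anyDuplicated(individual_id))
    stop("duplicate individual ids: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  bad <- which(!(is.na(calls) | calls == 0 | calls == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf("non-binary call value '%s' at individual '%s', locus '%s'",
                 format(calls[b[1], b[2]]), individual_id[b[1]], locus_ids[b[2]]))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(individual_id, locus_ids)
  structure(list(calls = calls, individual_id = individual_id,
                 species = species, plot = plot, locus_ids = locus_ids),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Binary marker matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "loci\n")
  cat("  species:", paste(sprintf("%s (n=%d)", names(table(x$species)),
                                  as.integer(table(x$species))), collapse = ", "), "\n")
  cat("  plots:  ", length(unique(x$plot)), "\n")
  nmis <- sum(is.na(x$calls))
  if (nmis > 0) cat("  missing calls:", nmis, "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$calls)

#' Subset a marker matrix by species and/or plot
#'
#' @param m a [marker_matrix()].
#' @param species,plot optional labels to keep (`NULL` keeps all).
#' @return a `marker_matrix` restricted to the selected individuals.
#' @export
subset_markers <- function(m, species = NULL, plot = NULL) {
  keep <- rep(TRUE, length(m$individual_id))
  if (!is.null(species)) keep <- keep & m$species %in% species
  if (!is.null(plot)) keep <- keep & m$plot %in% plot
  if (!any(keep)) stop("subset selects no individuals")
  marker_matrix(m$calls[keep, , drop = FALSE], m$species[keep], m$plot[keep],
                m$individual_id[keep], m$locus_ids)
}

.sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a binary marker matrix from TSV/CSV
#'
#' Expected layout: header row with columns `individual_id`, `species`,
#' `plot`, then one column per locus; calls coded 0/1 and missing as `NA`.
#' Missing entries are preserved as missing, never coerced to 0.
#'
#' @param path file to read.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sep_for(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                         check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "plot")
  if (!all(need %in% names(d)))
    stop("header must name columns: ", paste(need, collapse = ", "))
  loci <- setdiff(names(d), need)
  if (length(loci) == 0) stop("no locus columns found in ", path)
  calls <- as.matrix(d[, loci, drop = FALSE])
  bad <- which(!(is.na(calls) | calls == "0" | calls == "1"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf("non-binary call value '%s' at row %d (individual '%s'), locus '%s'",
                 calls[b[1], b[2]], b[1], d$individual_id[b[1]], loci[b[2]]))
  }
  storage.mode(calls) <- "integer"
  marker_matrix(calls, d$species, d$plot, d$individual_id, loci)
}

#' Write a binary marker matrix to TSV/CSV
#'
#' @param m a [marker_matrix()].
#' @param path destination file.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, sep = NULL) {
  sep <- .sep_for(path, sep)
  d <- data.frame(individual_id = m$individual_id, species = m$species,
                  plot = m$plot, check.names = FALSE,
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(m$calls, check.names = FALSE))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a plot-by-species abundance table
#'
#' @param counts nonnegative integer matrix, plots in rows, species in
#'   columns; dimnames give plot codes and species ids.
#' @return an object of class `abundance_table` (a counts matrix).
#' @export
abundance_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("plot codes required as rownames")
  if (is.null(colnames(counts))) stop("species ids required as colnames")
  if (anyDuplicated(colnames(counts))) stop("species ids must be unique")
  if (anyDuplicated(rownames(counts))) stop("plot codes must be unique")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0))
    stop("every retained plot needs at least one positive count; empty: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, class = c("abundance_table", "matrix"))
}

#' Read / write a plot-by-species abundance table
#'
#' File layout: first column `plot`, remaining columns one per species,
#' integer counts.
#'
#' @param path file to read or write.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return [read_abundance_table()] returns an [abundance_table()];
#'   [write_abundance_table()] returns `path` invisibly.
#' @export
read_abundance_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sep_for(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(d)[1] != "plot") stop("first column must be 'plot'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$plot
  abundance_table(m)
}

#' @rdname read_abundance_table
#' @param t an [abundance_table()].
#' @export
write_abundance_table <- function(t, path, sep = NULL) {
  sep <- .sep_for(path, sep)
  d <- data.frame(plot = rownames(t), check.names = FALSE,
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(unclass(t), check.names = FALSE))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a census table of per-plot species counts
#'
#' Columns `plot`, `species`, `N`; `N` counts the individuals of that species
#' in the plot meeting the census size criterion (e.g. DBH >= 7 cm).
#'
#' @inheritParams read_abundance_table
#' @return data.frame with columns plot, species, N.
#' @export
read_census_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sep_for(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("plot", "species", "N") %in% names(d)))
    stop("census table needs columns plot, species, N")
  if (any(d$N < 0) || any(d$N != round(d$N)))
    stop("census counts must be nonnegative integers")
  d
}

#' Per-locus variant frequencies
#'
#' For each locus, counts the individuals with non-missing calls (`n`) and
#' returns the relative frequency of the dominant variant '1' (band present,
#' `f_present`) and of the recessive variant '2' (band absent, `f_absent`).
#' By default frequencies are phenotype (band) frequencies — the two
#' "genetic variants" of a dominant locus — with no transform to allele
#' frequencies.  `scale = "allele"` instead applies the Hardy-Weinberg
#' square-root estimate (recessive allele frequency `sqrt(f_absent)`),
#' which assumes random mating and is off by default.
#'
#' @param m a [marker_matrix()].
#' @param species,plot optional subset selectors (see [subset_markers()]).
#' @param scale `"phenotype"` (default) or `"allele"`.
#' @return data.frame of class `locus_freqs` with columns `locus_id`, `n`,
#'   `f_present`, `f_absent`, `defined`.  Loci with all calls missing in the
#'   subset have `defined = FALSE` and `NA` frequencies.
#' @export
locus_frequencies <- function(m, species = NULL, plot = NULL,
                              scale = c("phenotype", "allele")) {
  scale <- match.arg(scale)
  if (!is.null(species) || !is.null(plot)) m <- subset_markers(m, species, plot)
  n <- colSums(!is.na(m$calls))
  pres <- colSums(m$calls == 1, na.rm = TRUE)
  f1 <- ifelse(n > 0, pres / n, NA_real_)
  if (scale == "allele") f1 <- 1 - sqrt(1 - f1)
  out <- data.frame(locus_id = m$locus_ids, n = as.integer(n),
                    f_present = f1, f_absent = 1 - f1,
                    defined = n > 0, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("locus_freqs", "data.frame")
  out
}

#' Frequency-based locus filter
#'
#' Excludes loci whose variant frequency is below `lower` or above `upper`
#' (defaults 0.05 / 0.95); loci exactly at a boundary are retained.  Loci
#' undefined in the subset (all calls missing) are excluded and logged.
#'
#' @param freqs a `locus_freqs` data.frame from [locus_frequencies()].
#' @param lower,upper retention bounds on the variant-'1' frequency,
#'   `0 <= lower < upper <= 1`.
#' @return list of class `locus_filter` with elements `retained` (locus ids),
#'   `excluded` (data.frame locus_id, f_present, reason), `lower`, `upper`.
#' @export
filter_loci <- function(freqs, lower = 0.05, upper = 0.95) {
  stopifnot(lower >= 0, upper <= 1, lower < upper)
  keep <- freqs$defined & freqs$f_present >= lower & freqs$f_present <= upper
  reason <- rep(NA_character_, nrow(freqs))
  reason[!freqs$defined] <- "all calls missing"
  reason[freqs$defined & freqs$f_present < lower] <- sprintf("f < %g", lower)
  reason[freqs$defined & freqs$f_present > upper] <- sprintf("f > %g", upper)
  if (!any(keep))
    warning("no locus passes the frequency filter; downstream stages will refuse to run")
  structure(list(retained = freqs$locus_id[keep],
                 excluded = data.frame(locus_id = freqs$locus_id[!keep],
                                       f_present = freqs$f_present[!keep],
                                       reason = reason[!keep],
                                       stringsAsFactors = FALSE),
                 lower = lower, upper = upper),
            class = "locus_filter")
}

#' @export
print.locus_filter <- function(x, ...) {
  cat(sprintf("Locus filter [%g, %g]: %d retained, %d excluded\n",
              x$lower, x$upper, length(x$retained), nrow(x$excluded)))
  invisible(x)
}

#' Study plot-level diversity summary
#'
#' The published per-plot summary of the 14-plot Chihuahua-spruce community
#' study bundled with the package: species richness, Simpson effective number
#' and prevalent-species number per plot, and the mean per-locus genetic
#' diversity of the four genotyped tree species (NA where a species was not
#' sampled in a plot).
#'
#' @return data.frame with one row per plot.
#' @export
study_diversity_table <- function() {
  path <- system.file("extdata", "study_plot_diversity.tsv",
                      package = "commdiv", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
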