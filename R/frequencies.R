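#' Allele counts and frequencies with chromosome-aware denominators
#'
#' Counts every observed allele call at a locus and divides by the number of
#' observed chromosomes: `2N` for autosomes, `2 x females + males` for X
#' (sexes pooled, the convention for X-STR reference data), and
#' `males x copy_count` for Y markers. Null calls contribute to neither
#' numerator nor denominator.
#'
#' @param gt A `genotype_table`.
#' @param locus Locus name (must be in the table's catalogue).
#' @return A `"frequency_table"`: data.frame with columns `locus`, `allele`,
#'   `count`, `frequency`; attributes `denominator` and `locus`.
#' @examples
#' \dontrun{freq <- compute_allele_frequencies(gt, "D8S1132")}
#' @export
compute_allele_frequencies <- function(gt, locus) {
  stopifnot(inherits(gt, "genotype_table"))
  catalogue_row(gt$catalogue, locus)  # existence check
  calls <- gt$long[gt$long$locus == locus, , drop = FALSE]
  if (!nrow(calls)) stop("no observed calls at locus ", locus)
  tab <- table(calls$allele)
  denom <- sum(tab)
  out <- data.frame(locus = locus, allele = names(tab),
                    count = as.integer(tab),
                    frequency = as.integer(tab) / denom,
                    stringsAsFactors = FALSE)
  out <- out[order_alleles(out$allele), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  attr(out, "locus") <- locus
  class(out) <- c("frequency_table", "data.frame")
  out
}

# numeric designations sort numerically, everything else lexicographically after
order_alleles <- function(a) {
  num <- suppressWarnings(as.numeric(a))
  order(is.na(num), num, a)
}

#' Frequency tables for every locus of a genotype table
#' @param gt A `genotype_table`.
#' @param loci Optional subset of locus names.
#' @return Named list of `frequency_table`s.
#' @export
allele_frequency_tables <- function(gt, loci = NULL) {
  if (is.null(loci)) loci <- loci_of(gt)
  out <- lapply(loci, function(l) compute_allele_frequencies(gt, l))
  names(out) <- loci
  out
}

#' Frequency vector of a frequency table
#' @param freq A `frequency_table`.
#' @return Numeric vector of allele frequencies.
#' @export
frequencies_of <- function(freq) {
  stopifnot(inherits(freq, "frequency_table"))
  freq$frequency
}

#' Write stacked frequency tables as CSV
#'
#' Long CSV with columns `locus, allele, count, frequency, denominator`;
#' frequencies are reported rounded to 4 decimals but kept exact internally.
#'
#' @param freqs List of `frequency_table`s.
#' @param path Output path.
#' @export
write_frequency_tables <- function(freqs, path) {
  rows <- lapply(freqs, function(f) {
    data.frame(locus = f$locus, allele = f$allele, count = f$count,
               frequency = round(f$frequency, 4),
               denominator = attr(f, "denominator"), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble Y-chromosome haplotypes
#'
#' Builds the per-male ordered allele tuple across the requested Y loci.
#' Multi-copy ("a/b") loci contribute their unordered pair, sorted, as one
#' tuple element. Males missing a call at any requested locus are dropped
#' with a warning; haplotypes are counted by exact tuple equality.
#'
#' @param gt A `genotype_table`.
#' @param loci Character vector of Y locus names (default: all Y loci).
#' @return A `"y_haplotype_set"`: list with `haplotypes` (data.frame
#'   `haplotype`, `count`), `k` distinct haplotypes, `N` males counted,
#'   `loci`.
#' @export
assemble_y_haplotypes <- function(gt, loci = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(loci)) loci <- loci_of(gt, chrom_class = "Y")
  if (!length(loci)) stop("no Y loci requested")
  males <- gt$samples$sample[gt$samples$sex == "M"]
  if (!length(males)) stop("no male samples in table")
  tuples <- character(0)
  kept <- character(0)
  for (s in males) {
    parts <- character(length(loci))
    ok <- TRUE
    for (j in seq_along(loci)) {
      cell <- gt$data[[loci[j]]][gt$data$sample == s]
      calls <- split_call(cell)
      if (!length(calls)) { ok <- FALSE; break }
      parts[j] <- paste(sort(calls), collapse = "+")
    }
    if (ok) {
      tuples <- c(tuples, paste(parts, collapse = " || "))
      kept <- c(kept, s)
    }
  }
  dropped <- setdiff(males, kept)
  if (length(dropped)) {
    warning("dropped ", length(dropped), " male(s) with missing Y calls: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(tuples)) stop("no complete Y haplotypes")
  tab <- table(tuples)
  out <- list(haplotypes = data.frame(haplotype = names(tab),
                                      count = as.integer(tab),
                                      stringsAsFactors = FALSE),
              k = length(tab), N = length(tuples), loci = loci)
  class(out) <- "y_haplotype_set"
  out
}

#' @export
print.y_haplotype_set <- function(x, ...) {
  cat(sprintf("<y_haplotype_set> N = %d males, k = %d haplotypes (%d loci)\n",
              x$N, x$k, length(x$loci)))
  invisible(x)
}

#' Test male/female allele-frequency homogeneity at an X locus
#'
#' Exact (or Monte-Carlo, for larger tables) contingency test of the sex x
#' allele count table. The caller pools male and female X frequencies when
#' the test is non-significant; pooling is the default downstream and this
#' check never gates it.
#'
#' @param gt A `genotype_table`.
#' @param locus X-locus name.
#' @param B Monte-Carlo replicates when the table is too large for the exact
#'   network algorithm.
#' @param seed Seed for the Monte-Carlo path.
#' @return List with `p_value`, `method`, and the sex-by-allele `table`.
#' @export
pool_sex_frequencies_check <- function(gt, locus, B = 10000, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  calls <- gt$long[gt$long$locus == locus, , drop = FALSE]
  if (!nrow(calls)) stop("no observed calls at locus ", locus)
  if (length(unique(calls$sex)) < 2L) stop("both sexes required for homogeneity check")
  tab <- table(calls$sex, calls$allele)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) {
    return(list(p_value = 1, method = "degenerate", table = tab))
  }
  small <- ncol(tab) <= 5L
  if (!is.null(seed)) set.seed(seed)
  ft <- if (small) {
    stats::fisher.test(tab, workspace = 2e7)
  } else {
    stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
  }
  list(p_value = ft$p.value,
       method = if (small) "fisher_exact" else "fisher_monte_carlo",
       table = tab)
}
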