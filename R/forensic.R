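#' Unbiased gene diversity
#'
#' `GD = n (1 - sum p_i^2) / (n - 1)` with `n` the number of observed
#' chromosomes (or haplotypes); the small-sample-corrected expected
#' heterozygosity. Equals 0 for a monomorphic locus and exactly 1 when all
#' `n` observations are distinct.
#'
#' @param p Frequency vector (summing to 1) or a `frequency_table`.
#' @param n Number of observations; taken from the table's denominator when
#'   `p` is a `frequency_table`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
gene_diversity <- function(p, n = NULL) {
  if (inherits(p, "frequency_table")) {
    if (is.null(n)) n <- attr(p, "denominator")
    p <- p$frequency
  }
  check_freqs(p)
  if (is.null(n) || n < 2) stop("gene diversity needs n >= 2 observations")
  n / (n - 1) * (1 - sum(p^2))
}

check_freqs <- function(p, tol = 1e-9) {
  if (any(p < -tol)) stop("negative frequency")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum p_i^2 - (sum p_i^2)^2 + sum p_i^4`, the classic linkage
#' informativeness measure; algebraically equal to the double-sum form
#' `1 - sum p_i^2 - sum_{i != j} p_i^2 p_j^2`.
#'
#' @param p Frequency vector or `frequency_table`.
#' @return Numeric scalar in `[0, 1)`.
#' @export
pic <- function(p) {
  if (inherits(p, "frequency_table")) p <- p$frequency
  check_freqs(p)
  a2 <- sum(p^2)
  1 - a2 - a2^2 + sum(p^4)
}

#' Match probability and power of discrimination
#'
#' `MP = sum f_g^2` over the observed genotype frequencies (the probability
#' that two individuals drawn with replacement from the sample match), and
#' `PD = 1 - MP`. Uses observed -- not Hardy-Weinberg-expected -- genotype
#' frequencies, the convention of the standard forensic summary tools.
#'
#' @param genotypes Character vector of genotype keys (one per individual),
#'   or a table/named numeric vector of genotype counts.
#' @return List with `MP` and `PD`.
#' @export
match_probability <- function(genotypes) {
  counts <- if (is.table(genotypes) || is.numeric(genotypes)) {
    as.numeric(genotypes)
  } else {
    if (!length(genotypes)) stop("empty locus: no genotypes")
    as.numeric(table(genotypes))
  }
  if (!length(counts) || sum(counts) == 0) stop("empty locus: no genotypes")
  f <- counts / sum(counts)
  mp <- sum(f^2)
  list(MP = mp, PD = 1 - mp)
}

#' Power of exclusion and typical paternity index
#'
#' From the observed heterozygote proportion `h` (with homozygote proportion
#' `H = 1 - h`): `PE = h^2 (1 - 2 h H^2)` and `TPI = 1 / (2H)`. A fully
#' heterozygous locus has `PE = 1` and an infinite TPI.
#'
#' @param h Observed heterozygosity in `[0, 1]`.
#' @return List with `PE` and `TPI` (`Inf` when `H = 0`).
#' @export
pe_tpi <- function(h) {
  stopifnot(h >= 0, h <= 1)
  H <- 1 - h
  list(PE = h^2 * (1 - 2 * h * H^2),
       TPI = if (H == 0) Inf else 1 / (2 * H))
}

#' Per-locus forensic parameter bundle
#'
#' Computes the autosomal-style statistics for one locus of a genotype
#' table: observed heterozygosity, unbiased gene diversity (Hexp/GD), PIC,
#' match probability, powers of discrimination and exclusion, and the
#' typical paternity index.
#'
#' @param gt A `genotype_table`.
#' @param locus Locus name (diploid data expected: autosomal, or X females).
#' @param females_only For X loci, restrict to females (default `TRUE` for
#'   X since males are hemizygous).
#' @return List of class `"locus_stats"`.
#' @export
locus_stats <- function(gt, locus, females_only = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  row <- catalogue_row(gt$catalogue, locus)
  if (is.null(females_only)) females_only <- row$chrom_class == "X"
  df <- gt$data
  if (females_only && row$chrom_class == "X") df <- df[df$sex == "F", , drop = FALSE]
  cells <- df[[locus]]
  calls <- lapply(cells, split_call)
  calls <- calls[lengths(calls) == 2L]
  if (!length(calls)) stop("no diploid genotypes at locus ", locus)
  geno <- vapply(calls, function(x) paste(sort(x), collapse = "/"), character(1))
  het <- vapply(calls, function(x) x[1] != x[2], logical(1))
  h <- mean(het)
  alleles <- unlist(calls)
  tabs <- table(alleles)
  pfreq <- as.numeric(tabs) / sum(tabs)
  n <- sum(tabs)
  mp <- match_probability(geno)
  pe <- pe_tpi(h)
  out <- list(locus = locus, n_genotypes = length(geno), n_alleles_obs = n,
              k_alleles = length(tabs),
              Hobs = h, Hexp = gene_diversity(pfreq, n), GD = gene_diversity(pfreq, n),
              PIC = pic(pfreq), MP = mp$MP, PD = mp$PD, PE = pe$PE, TPI = pe$TPI)
  class(out) <- "locus_stats"
  out
}

#' SNP-locus statistics
#'
#' Same parameter set as STR loci restricted to a biallelic marker; `DP` is
#' the SNP literature's synonym of `PD`. More than two observed alleles at a
#' SNP locus is a validation error.
#'
#' @inheritParams locus_stats
#' @return `"locus_stats"` list with an additional `DP` field.
#' @export
snp_stats <- function(gt, locus) {
  st <- locus_stats(gt, locus)
  if (st$k_alleles > 2L) {
    stop("SNP locus ", locus, " shows ", st$k_alleles, " alleles (max 2 allowed)")
  }
  st$DP <- st$PD
  st
}

#' Combine per-locus statistics over an independent panel
#'
#' Panel-wide products accumulated in log space so that combined match
#' probabilities on the 1e-70 scale survive: `CMP = prod MP_l`,
#' `CPD = 1 - CMP`, `CPE = 1 - prod (1 - PE_l)`, `CPI = prod TPI_l`.
#'
#' @param stats Either a list of `locus_stats` or a data.frame with columns
#'   `MP`, `PE`, `TPI`.
#' @return List of class `"panel_stats"` with log10-scale accumulators
#'   (`log10_CMP`, `log10_CPE_complement`, `log10_CPI`), plain values where
#'   representable, and rendered `"1-x"`-style strings.
#' @export
combine_panel <- function(stats) {
  df <- if (is.data.frame(stats)) stats else {
    do.call(rbind, lapply(stats, function(s) {
      data.frame(MP = s$MP, PE = s$PE, TPI = s$TPI)
    }))
  }
  if (!nrow(df)) stop("combine_panel needs at least one locus")
  log10_cmp <- sum(log10(df$MP))
  log10_cpe_c <- sum(log10(1 - df$PE))      # complement of CPE
  log10_cpi <- sum(log10(df$TPI))
  out <- list(
    n_loci = nrow(df),
    log10_CMP = log10_cmp,
    log10_CPE_complement = log10_cpe_c,
    log10_CPI = log10_cpi,
    CMP = 10^log10_cmp,
    CPD = 1 - 10^log10_cmp,
    CPE = 1 - 10^log10_cpe_c,
    CPI = 10^log10_cpi,
    CPD_rendered = render_one_minus(log10_cmp),
    CPE_rendered = render_one_minus(log10_cpe_c),
    CPE_percent = complement_percent(log10_cpe_c),
    CPI_rendered = render_pow10(log10_cpi))
  class(out) <- "panel_stats"
  out
}

# "1-2.411e-73"-style rendering from a log10 complement
render_one_minus <- function(log10_x, digits = 4) {
  paste0("1-", render_pow10(log10_x, digits))
}

render_pow10 <- function(log10_x, digits = 4) {
  e <- floor(log10_x)
  m <- 10^(log10_x - e)
  sprintf("%.*fe%+d", digits - 1, m, as.integer(e))
}

# percentage like 99.999999988 from log10 of the complement
complement_percent <- function(log10_complement, digits = 9) {
  round(100 * (1 - 10^log10_complement), digits)
}

#' @export
print.panel_stats <- function(x, ...) {
  cat(sprintf("<panel_stats> %d loci\n  CPD = %s\n  CPE = %s (%.9f%%)\n  CPI = %s\n",
              x$n_loci, x$CPD_rendered, x$CPE_rendered, x$CPE_percent, x$CPI_rendered))
  invisible(x)
}

#' X-chromosomal mean exclusion chances
#'
#' The four standard X-STR mean exclusion chances, each the probability of
#' excluding a random non-relative under its pedigree scenario, computed in
#' allele-frequency power sums (`a_k = sum p_i^k`):
#' \itemize{
#'   \item Kishida and Desmarais (standard mother-daughter-alleged-father
#'     trio; the X is obligately paternal in a daughter):
#'     `1 - a2 - a2^2 + a4`, identical to the PIC -- the two published
#'     derivations are algebraically equivalent.
#'   \item Desmarais Duo (daughter-alleged father, mother untyped):
#'     `1 - 2 a2 + a3`.
#'   \item Krüger (deficiency configuration: the alleged father is
#'     unavailable and his mother -- the paternal grandmother, a diploid
#'     excludee -- is typed): `1 - 2(a2 + a2^2 - a4) + a3 + 3(a2 a3 - a5)`.
#' }
#' Each closed form agrees with exhaustive enumeration over founder
#' genotypes weighted by frequency (see the package tests).
#'
#' @param p Frequency vector or `frequency_table` (pooled X frequencies).
#' @return List of class `"x_mec"` with `MEC_Kruger`, `MEC_Kishida`,
#'   `MEC_Desmarais`, `MEC_Desmarais_Duo`.
#' @export
mec_suite <- function(p) {
  if (inherits(p, "frequency_table")) p <- p$frequency
  check_freqs(p)
  a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4); a5 <- sum(p^5)
  trio <- 1 - a2 - a2^2 + a4
  out <- list(MEC_Kruger = 1 - 2 * (a2 + a2^2 - a4) + a3 + 3 * (a2 * a3 - a5),
              MEC_Kishida = trio,
              MEC_Desmarais = trio,
              MEC_Desmarais_Duo = 1 - 2 * a2 + a3)
  class(out) <- "x_mec"
  out
}

#' X-chromosomal powers of discrimination
#'
#' For pooled X allele frequencies: males are hemizygous, so
#' `PD_M = 1 - sum p_i^2`; females are diploid and, under Hardy-Weinberg
#' proportions, `PD_F = 1 - (2 (sum p_i^2)^2 - sum p_i^4)`.
#'
#' @param p Frequency vector or `frequency_table`.
#' @return List with `PD_M` and `PD_F`.
#' @export
x_discrimination <- function(p) {
  if (inherits(p, "frequency_table")) p <- p$frequency
  check_freqs(p)
  a2 <- sum(p^2); a4 <- sum(p^4)
  list(PD_M = 1 - a2, PD_F = 1 - (2 * a2^2 - a4))
}

#' Y-haplotype diversity and discrimination capacity
#'
#' `HD = N (1 - sum p_i^2) / (N - 1)` over haplotype frequencies,
#' `DC = k / N` (distinct haplotypes per sampled male), and the unique
#' fraction `singletons / k`.
#'
#' @param yh A `y_haplotype_set`, or a numeric vector of haplotype counts.
#' @return List with `HD`, `DC`, `unique_fraction`, `k`, `N`.
#' @export
haplotype_diversity <- function(yh) {
  counts <- if (inherits(yh, "y_haplotype_set")) yh$haplotypes$count else as.numeric(yh)
  N <- sum(counts)
  if (N < 2) stop("haplotype diversity needs N >= 2")
  k <- length(counts)
  p <- counts / N
  list(HD = N / (N - 1) * (1 - sum(p^2)),
       DC = k / N,
       unique_fraction = sum(counts == 1L) / k,
       k = k, N = N)
}
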