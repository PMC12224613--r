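#' Configure a pipeline run
#'
#' @param genotype_path Genotype TSV path.
#' @param coverage_path Coverage TSV path (optional; QC stage skipped with a
#'   message when absent).
#' @param catalogue_path Locus catalogue TSV path.
#' @param out_dir Output directory (created if needed).
#' @param alpha Family-wise significance level (default 0.05).
#' @param mc_steps Monte-Carlo steps for the exact HWE test.
#' @param permutations Permutations for the LD test.
#' @param ld_max_pairs Cap on LD pairs actually tested per chromosome-class
#'   family (the Bonferroni denominator still counts the full family).
#' @param doc_threshold Coverage QC threshold (default 650).
#' @param seed Mandatory run seed (all stochastic stages derive sub-seeds
#'   from it).
#' @param rounding Decimal places in report tables (default 4).
#' @return `"run_config"` list.
#' @export
run_config <- function(genotype_path, catalogue_path, out_dir,
                       coverage_path = NULL, alpha = 0.05, mc_steps = 5000,
                       permutations = 200, ld_max_pairs = 25,
                       doc_threshold = 650, seed, rounding = 4) {
  if (missing(seed) || is.null(seed)) stop("run_config: seed is mandatory")
  out <- list(genotype_path = genotype_path, catalogue_path = catalogue_path,
              coverage_path = coverage_path, out_dir = out_dir, alpha = alpha,
              mc_steps = as.integer(mc_steps),
              permutations = as.integer(permutations),
              ld_max_pairs = ld_max_pairs, doc_threshold = doc_threshold,
              seed = as.integer(seed), rounding = as.integer(rounding))
  class(out) <- "run_config"
  out
}

stage_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full analysis pipeline
#'
#' Executes, in order: allele/haplotype frequencies, forensic parameters
#' (per chromosome class plus combined panel statistics), HWE and LD tests
#' with Bonferroni bookkeeping, sequence-based vs length-based allele
#' accounting, and coverage QC; then writes a manifest that fully
#' determines a reproduction of the run. Any stage failure aborts the run
#' with a stage-named error and removes partial outputs.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list of the in-memory stage results; outputs are
#'   written under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, path) {
    writer(path)
    written <<- c(written, path)
    path
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  res <- list()
  rnd <- cfg$rounding

  # stage 1: load + frequencies -------------------------------------------
  tryCatch({
    stage_msg("stage frequencies")
    catalogue <- read_locus_catalogue(cfg$catalogue_path)
    gt <- read_genotype_table(cfg$genotype_path, catalogue)
    freqs <- allele_frequency_tables(gt)
    emit(function(p) write_frequency_tables(freqs, p),
         file.path(cfg$out_dir, "frequencies.csv"))
    res$gt <- gt; res$freqs <- freqs
  }, error = function(e) fail("frequencies", e))

  gt <- res$gt; freqs <- res$freqs
  cat_ <- gt$catalogue
  a_str <- loci_of(gt, "autosomal", "STR")
  x_str <- loci_of(gt, "X", "STR")
  y_str <- loci_of(gt, "Y", "STR")
  a_snp <- loci_of(gt, "autosomal", "SNP")

  # stage 2: forensic parameters ------------------------------------------
  tryCatch({
    stage_msg("stage forensic_stats")
    astats <- lapply(a_str, function(l) locus_stats(gt, l))
    adf <- do.call(rbind, lapply(astats, function(s) {
      data.frame(locus = s$locus, Hobs = s$Hobs, Hexp = s$Hexp, PIC = s$PIC,
                 MP = s$MP, PD = s$PD, PE = s$PE, TPI = s$TPI)
    }))
    emit(function(p) utils::write.csv(round_df(adf, rnd), p, row.names = FALSE),
         file.path(cfg$out_dir, "astr_stats.csv"))

    xdf <- do.call(rbind, lapply(x_str, function(l) {
      f <- freqs[[l]]
      xd <- x_discrimination(f); mec <- mec_suite(f)
      data.frame(locus = l, GD = gene_diversity(f), PIC = pic(f),
                 PD_M = xd$PD_M, PD_F = xd$PD_F,
                 MEC_Kruger = mec$MEC_Kruger, MEC_Kishida = mec$MEC_Kishida,
                 MEC_Desmarais = mec$MEC_Desmarais,
                 MEC_Desmarais_Duo = mec$MEC_Desmarais_Duo)
    }))
    if (length(x_str)) {
      emit(function(p) utils::write.csv(round_df(xdf, rnd), p, row.names = FALSE),
           file.path(cfg$out_dir, "xstr_stats.csv"))
    }

    ydf <- do.call(rbind, lapply(y_str, function(l) {
      f <- freqs[[l]]
      data.frame(locus = l, k_alleles = nrow(f), GD = gene_diversity(f))
    }))
    yh <- if (length(y_str)) assemble_y_haplotypes(gt, y_str) else NULL
    yhd <- if (!is.null(yh)) haplotype_diversity(yh) else NULL
    if (length(y_str)) {
      emit(function(p) utils::write.csv(round_df(ydf, rnd), p, row.names = FALSE),
           file.path(cfg$out_dir, "ystr_stats.csv"))
    }

    sdf <- do.call(rbind, lapply(a_snp, function(l) {
      s <- snp_stats(gt, l)
      data.frame(locus = l, Hobs = s$Hobs, GD = s$GD, PIC = s$PIC, DP = s$DP,
                 MP = s$MP, PE = s$PE, TPI = s$TPI)
    }))
    if (length(a_snp)) {
      emit(function(p) utils::write.csv(round_df(sdf, rnd), p, row.names = FALSE),
           file.path(cfg$out_dir, "snp_stats.csv"))
    }

    panel <- list(
      A_STR = if (length(a_str)) unclass_panel(combine_panel(astats)),
      A_SNP = if (length(a_snp)) {
        unclass_panel(combine_panel(data.frame(
          MP = sdf$MP, PE = sdf$PE, TPI = sdf$TPI)))
      },
      X_STR = if (length(x_str)) list(
        combined_PD_F_log10_complement = sum(log10(1 - xdf$PD_F)),
        combined_PD_M_log10_complement = sum(log10(1 - xdf$PD_M)),
        combined_MEC_Desmarais_log10_complement = sum(log10(1 - xdf$MEC_Desmarais)),
        combined_MEC_Desmarais_Duo_log10_complement = sum(log10(1 - xdf$MEC_Desmarais_Duo))),
      Y_STR = if (!is.null(yhd)) yhd[c("HD", "DC", "unique_fraction", "k", "N")])
    emit(function(p) jsonlite::write_json(panel, p, auto_unbox = TRUE, digits = NA,
                                          pretty = TRUE, null = "null"),
         file.path(cfg$out_dir, "panel_stats.json"))
    res$astats <- adf
    res$xstats <- xdf
    res$ystats <- ydf
    res$snpstats <- sdf
    res$panel <- panel
    res$yh <- yh
  }, error = function(e) fail("forensic_stats", e))

  # stage 3: HWE / LD -------------------------------------------------------
  tryCatch({
    stage_msg("stage equilibrium")
    diploid_loci <- c(a_str, x_str, a_snp)
    hwe <- hwe_test_panel(gt, diploid_loci, alpha = cfg$alpha,
                          steps = cfg$mc_steps, seed = cfg$seed)
    emit(function(p) utils::write.table(hwe, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE),
         file.path(cfg$out_dir, "hwe.tsv"))
    ld_fams <- Filter(function(x) length(x) >= 2L,
                      list(A_STR = a_str, X_STR = x_str, A_SNP = a_snp))
    ld <- do.call(rbind, lapply(names(ld_fams), function(fam) {
      out <- ld_test_panel(gt, ld_fams[[fam]], alpha = cfg$alpha,
                           permutations = cfg$permutations, seed = cfg$seed,
                           max_pairs = cfg$ld_max_pairs)
      cbind(family = fam, out)
    }))
    emit(function(p) utils::write.table(ld, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE),
         file.path(cfg$out_dir, "ld.tsv"))
    res$hwe <- hwe; res$ld <- ld
  }, error = function(e) fail("equilibrium", e))

  # stage 4: SB vs LB accounting -------------------------------------------
  tryCatch({
    stage_msg("stage sb_lb")
    str_loci <- c(a_str, x_str, y_str)
    comps <- list(); classes <- character(0)
    for (l in str_loci) {
      cells <- unique(gt$long$allele[gt$long$locus == l])
      if (!any(grepl("[", cells, fixed = TRUE))) next  # length-only data
      row <- catalogue_row(cat_, l)
      alleles <- lapply(cells, function(x) parse_bracket(x, locus = row))
      comps[[l]] <- compare_locus(alleles)
      classes <- c(classes, row$chrom_class)
    }
    if (length(comps)) {
      summ <- panel_summary(comps, classes)
      cmp_df <- data.frame(
        locus = vapply(comps, function(x) x$locus, character(1)),
        class = classes,
        n_sb = vapply(comps, function(x) x$n_sb, numeric(1)),
        n_lb = vapply(comps, function(x) x$n_lb, numeric(1)),
        pct_increase = round(vapply(comps, function(x) x$pct_increase, numeric(1)), rnd),
        source_class = vapply(comps, function(x) x$source_class, character(1)))
      emit(function(p) utils::write.csv(cmp_df, p, row.names = FALSE),
           file.path(cfg$out_dir, "sb_lb_comparison.csv"))
      emit(function(p) jsonlite::write_json(
             list(by_class = summ$by_class, overall = summ$overall), p,
             auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"),
           file.path(cfg$out_dir, "sb_lb_panel.json"))
      res$sb_lb <- summ
    }
  }, error = function(e) fail("sb_lb", e))

  # stage 5: coverage QC -----------------------------------------------------
  tryCatch({
    stage_msg("stage coverage_qc")
    if (!is.null(cfg$coverage_path)) {
      cov <- read_coverage_table(cfg$coverage_path)
      qc <- doc_summary(cov, threshold = cfg$doc_threshold)
      emit(function(p) jsonlite::write_json(
             list(panel_mean = qc$panel_mean, max_locus = qc$max_locus,
                  min_locus = qc$min_locus, ratio = qc$ratio,
                  ratio_rounded = qc$ratio_rounded, threshold = qc$threshold,
                  flagged = qc$flagged,
                  per_locus = qc$per_locus), p,
             auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"),
           file.path(cfg$out_dir, "coverage_summary.json"))
      res$coverage <- qc
    } else {
      stage_msg("  no coverage table supplied; QC stage skipped")
    }
  }, error = function(e) fail("coverage_qc", e))

  # manifest ----------------------------------------------------------------
  tryCatch({
    cfg_echo <- unclass(cfg)
    cfg_echo$out_dir <- NULL  # implied by the manifest's own location
    manifest <- list(
      package = "strpanel",
      version = as.character(utils::packageVersion("strpanel")),
      seed = cfg$seed,
      config = cfg_echo,
      stages = c("frequencies", "forensic_stats", "equilibrium", "sb_lb",
                 "coverage_qc"),
      outputs = basename(written),
      checksums = as.list(tools::md5sum(sort(written))))
    names(manifest$checksums) <- basename(sort(written))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }, error = function(e) fail("manifest", e))

  invisible(res)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

unclass_panel <- function(ps) {
  ps$CMP <- NULL; ps$CPD <- NULL  # underflow to 0/1 at panel scale; keep logs
  unclass(ps)
}
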