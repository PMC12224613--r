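#' Default 306-marker panel catalogue
#'
#' A locus catalogue shaped like the four-in-one MPS identity panel the
#' package targets: 66 autosomal STRs, 29 X-STRs, 75 Y-STRs (including the
#' multi-copy DYS385a/b, DYF387S1a/b and DYS527a/b), 132 autosomal SNPs and
#' 3 Y-SNPs. Well-known marker names are used where applicable and the
#' remainder are filled with systematic synthetic names; counts per class
#' are exact.
#'
#' @return A `locus_catalogue` with 305 rows (plus Amelogenin is not a
#'   marker in the statistical sense and is omitted).
#' @export
default_panel_catalogue <- function() {
  astr <- c("CSF1PO", "FGA", "TH01", "TPOX", "vWA", "D1S1656", "D1S1677",
            "D1S1627", "D1GATA113", "D2S441", "D2S1338", "D2S1360", "D2S1776",
            "D3S1358", "D3S1744", "D3S3045", "D3S3053", "D3S4529", "D4S2364",
            "D4S2408", "D5S818", "D5S2800", "D6S474", "D6S477", "D6S1017",
            "D6S1043", "D7S820", "D7S1517", "D7S3048", "D8S1115", "D8S1132",
            "D8S1179", "D9S925", "D9S1122", "D9S2157", "D10S1248", "D10S1435",
            "D10S2325", "D11S2368", "D11S4463", "D12S391", "D13S317",
            "D13S325", "D14S608", "D14S1434", "D15S659", "D16S539", "D17S974",
            "D17S1290", "D17S1301", "D18S51", "D18S853", "D18S1364",
            "D19S253", "D19S433", "D20S470", "D20S482", "D20S1082", "D21S11",
            "D21S1270", "D21S2055", "D22S1045", "D22GATA198B", "Penta D",
            "Penta E", "D12ATA63")
  xstr <- c("DXS101", "DXS6789", "DXS6795", "DXS6800", "DXS6803", "DXS6807",
            "DXS6809", "DXS7132", "DXS7133", "DXS7423", "DXS7424", "DXS8377",
            "DXS8378", "DXS9895", "DXS9902", "DXS981", "DXS10074", "DXS10077",
            "DXS10079", "DXS10101", "DXS10103", "DXS10134", "DXS10135",
            "DXS10146", "DXS10148", "GATA165B12", "GATA172D05", "GATA31E08",
            "HPRTB")
  ystr_multi <- c("DYS385a/b", "DYF387S1a/b", "DYS527a/b")
  ystr <- c("DYS19", "DYS388", "DYS389I", "DYS389II", "DYS390", "DYS391",
            "DYS392", "DYS393", "DYS434", "DYS435", "DYS437", "DYS438",
            "DYS439", "DYS448", "DYS450", "DYS453", "DYS454", "DYS455",
            "DYS456", "DYS458", "DYS460", "DYS472", "DYS476", "DYS481",
            "DYS485", "DYS502", "DYS505", "DYS508", "DYS511", "DYS512",
            "DYS513", "DYS518", "DYS520", "DYS522", "DYS530", "DYS531",
            "DYS533", "DYS538", "DYS541", "DYS549", "DYS552", "DYS556",
            "DYS565", "DYS568", "DYS570", "DYS571", "DYS572", "DYS573",
            "DYS576", "DYS578", "DYS585", "DYS587", "DYS590", "DYS613",
            "DYS616", "DYS626", "DYS627", "DYS630", "DYS632", "DYS635",
            "DYS638", "DYS640", "DYS643", "DYS644", "DYS645", "DYS710",
            "DYS713", "DYS720", "DYS722", "Y-GATA-H4")
  pad <- function(x, n, fmt) {
    if (length(x) >= n) x[seq_len(n)] else c(x, sprintf(fmt, seq_len(n - length(x))))
  }
  astr <- pad(astr, 66, "A-STR-%02d")
  xstr <- pad(xstr, 29, "X-STR-%02d")
  ystr <- pad(ystr, 72, "Y-STR-%02d")
  asnp <- c("rs576261", "rs740910", "rs9956753", "rs1736442", "rs1109037",
            sprintf("rs90%04d", seq_len(127)))
  ysnp <- sprintf("rsY%04d", 1:3)

  motif3 <- c("D18S853", "DXS8377")
  motif5 <- c("Penta D", "Penta E", "DYS587", "DYS644", "DYS645")
  mk <- function(names, cls, copy = 1L, type = "STR") {
    ml <- if (type == "SNP") NA_integer_ else
      ifelse(names %in% motif3, 3L, ifelse(names %in% motif5, 5L, 4L))
    data.frame(name = names, chrom_class = cls, motif_len = ml,
               copy_count = copy, marker_type = type, stringsAsFactors = FALSE)
  }
  validate_locus_catalogue(rbind(
    mk(astr, "autosomal"), mk(xstr, "X"),
    mk(ystr_multi, "Y", copy = 2L), mk(ystr, "Y"),
    mk(asnp, "autosomal", type = "SNP"), mk(ysnp, "Y", type = "SNP")))
}

#' Configure a synthetic population draw
#'
#' Defaults mirror the target study design: 50 males and 50 females,
#' Hardy-Weinberg genotypes, per-locus allele spectra drawn once from a
#' symmetric Dirichlet, sequence-level decoration (repeat-region bracket
#' variants and flanking-region SNPs layered over shared length classes),
#' and heavy-tailed per-locus coverage (log-normal with a between-locus
#' spread of meanlog).
#'
#' @param catalogue A `locus_catalogue`.
#' @param n_males,n_females Sample sizes (default 50/50).
#' @param seed Mandatory global seed; per-locus streams are derived from it
#'   by a stable hash of the locus name, so adding a locus never perturbs
#'   another locus's draws.
#' @param spectra Optional named list: locus -> explicit allele-token
#'   frequency vector (named numeric, summing to 1); overrides generation.
#' @param str_alleles Number of length classes per STR locus.
#' @param dirichlet Symmetric Dirichlet concentration for spectra.
#' @param rr_variants_max Max sequence variants per length class.
#' @param fr_prob Probability that a sequence variant carries a flanking
#'   SNP annotation.
#' @param cov_meanlog,cov_sdlog_locus,cov_sdlog_sample Coverage model:
#'   per-locus meanlog ~ Normal(cov_meanlog, cov_sdlog_locus); per-sample
#'   reads ~ LogNormal(meanlog_locus, cov_sdlog_sample).
#' @return `"sim_config"` list.
#' @export
sim_config <- function(catalogue, n_males = 50L, n_females = 50L, seed,
                       spectra = NULL, str_alleles = 8L, dirichlet = 2,
                       rr_variants_max = 3L, fr_prob = 0.15,
                       cov_meanlog = 8.5, cov_sdlog_locus = 1.0,
                       cov_sdlog_sample = 0.35) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  catalogue <- validate_locus_catalogue(as.data.frame(catalogue))
  if (!is.null(spectra)) {
    bad <- setdiff(names(spectra), catalogue$name)
    if (length(bad)) stop("spectra given for unknown loci: ", paste(bad, collapse = ", "))
    for (nm in names(spectra)) {
      if (abs(sum(spectra[[nm]]) - 1) > 1e-9) stop("spectrum for ", nm, " does not sum to 1")
    }
  }
  out <- list(catalogue = catalogue, n_males = as.integer(n_males),
              n_females = as.integer(n_females), seed = as.integer(seed),
              spectra = spectra, str_alleles = as.integer(str_alleles),
              dirichlet = dirichlet, rr_variants_max = as.integer(rr_variants_max),
              fr_prob = fr_prob, cov_meanlog = cov_meanlog,
              cov_sdlog_locus = cov_sdlog_locus, cov_sdlog_sample = cov_sdlog_sample)
  class(out) <- "sim_config"
  out
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# sequence vocabulary for one STR length class: pure repeat plus optional
# variants with one mutated unit (same total length, different RR blocks),
# optionally decorated with a flanking SNP annotation
make_sb_variants <- function(motif, units, n_var, fr_prob, chrom, pos_base) {
  vars <- character(0)
  pure <- paste0("[", motif, "]", units)
  vars <- c(vars, pure)
  if (n_var > 1L && units >= 3L) {
    mut <- motif
    substr(mut, 1L, 1L) <- setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L))[1]
    for (v in seq_len(n_var - 1L)) {
      a <- 1L + ((v * 2L) %% (units - 2L))
      vars <- c(vars, paste0("[", motif, "]", a, " [", mut, "]1 [", motif, "]",
                             units - a - 1L))
    }
  }
  vars <- unique(vars)
  decorated <- stats::runif(length(vars)) < fr_prob
  vars[decorated] <- paste0(vars[decorated], " ; GRCh38-chr", chrom, ":",
                            pos_base + which(decorated), "-A")
  vars
}

#' Draw a synthetic population
#'
#' Generates Hardy-Weinberg genotypes for every catalogue locus with
#' chromosome-correct ploidy (autosomal and female-X diploid, male-X and Y
#' hemizygous, multi-copy Y loci drawing `copy_count` alleles), a long-form
#' coverage table, and a truth record holding every generating frequency.
#' Fully reproducible: the same config yields byte-identical output.
#'
#' @param cfg A `sim_config`.
#' @return List with `gt` (a `genotype_table`), `coverage` (long
#'   data.frame), `truth` (per-locus list: `tokens`, `freqs`,
#'   `class_of_token`), and `catalogue`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cat_ <- cfg$catalogue
  samples <- c(sprintf("M%03d", seq_len(cfg$n_males)),
               sprintf("F%03d", seq_len(cfg$n_females)))
  sex <- c(rep("M", cfg$n_males), rep("F", cfg$n_females))
  wide <- data.frame(sample = samples, sex = sex, stringsAsFactors = FALSE)
  truth <- list()
  cov_rows <- vector("list", nrow(cat_))

  for (li in seq_len(nrow(cat_))) {
    loc <- cat_[li, ]
    set.seed(derive_seed(cfg$seed, paste0("locus:", loc$name)))
    expl <- cfg$spectra[[loc$name]]
    if (!is.null(expl)) {
      tokens <- names(expl)
      freqs <- as.numeric(expl)
    } else if (loc$marker_type == "SNP") {
      tokens <- sample(c("A", "C", "G", "T"), 2L)
      freqs <- rdirichlet1(2L, cfg$dirichlet)
    } else {
      k <- cfg$str_alleles
      base <- sample(7:14, 1L)
      unit_lengths <- base + seq_len(k) - 1L
      class_freq <- rdirichlet1(k, cfg$dirichlet)
      motif <- sample(c("TCTA", "GATA", "AGAT", "TATC", "CTTT", "AAAG",
                        "TAGA", "GGAA"), 1L)
      if (!is.na(loc$motif_len) && loc$motif_len != 4L) {
        motif <- substr(paste0(motif, motif), 1L, loc$motif_len)
      }
      tokens <- character(0); freqs <- numeric(0)
      for (ci in seq_len(k)) {
        n_var <- sample.int(cfg$rr_variants_max, 1L)
        vars <- make_sb_variants(motif, unit_lengths[ci], n_var, cfg$fr_prob,
                                 chrom = li %% 22 + 1, pos_base = 10000L * li)
        sub <- rdirichlet1(length(vars), 1)
        tokens <- c(tokens, vars)
        freqs <- c(freqs, class_freq[ci] * sub)
      }
    }
    truth[[loc$name]] <- list(tokens = tokens, freqs = freqs)

    n_draws_per <- vapply(sex, function(sx) {
      expected_call_count(loc$chrom_class, loc$copy_count, sx)
    }, integer(1))
    total <- sum(n_draws_per)
    draws <- sample(tokens, total, replace = TRUE, prob = freqs)
    cells <- character(length(samples))
    off <- 0L
    for (si in seq_along(samples)) {
      nd <- n_draws_per[si]
      cells[si] <- if (nd == 0L) "" else {
        paste(draws[off + seq_len(nd)], collapse = "/")
      }
      off <- off + nd
    }
    wide[[loc$name]] <- cells

    meanlog_l <- stats::rnorm(1, cfg$cov_meanlog, cfg$cov_sdlog_locus)
    cov_rows[[li]] <- data.frame(
      locus = loc$name, sample = samples,
      reads = round(stats::rlnorm(length(samples), meanlog_l, cfg$cov_sdlog_sample)),
      stringsAsFactors = FALSE)
  }

  list(gt = genotype_table(wide, cat_),
       coverage = do.call(rbind, cov_rows),
       truth = truth, catalogue = cat_)
}

#' Simulate the full panel study, with the bundled novel alleles planted
#'
#' Draws a 50-male / 50-female population over the default 306-marker
#' catalogue, then injects the bundled novel repeat-region allele catalogue
#' verbatim: each bundled allele occupies exactly its recorded number of
#' chromosome slots at its locus, so downstream frequency tables reproduce
#' the recorded counts exactly. Any chance background collision with an
#' injected string is swept to a distinct background token first.
#'
#' @param seed Global seed.
#' @param inject Plant the bundled novel-allele catalogue (default `TRUE`).
#' @param catalogue Panel catalogue (default `default_panel_catalogue()`).
#' @param ... Passed to `sim_config()`.
#' @return As `simulate_population()`, plus `injected` (the bundled table).
#' @export
simulate_panel_study <- function(seed, inject = TRUE,
                                 catalogue = default_panel_catalogue(), ...) {
  cfg <- sim_config(catalogue, seed = seed, ...)
  sim <- simulate_population(cfg)
  if (!inject) return(sim)
  nv <- novel_allele_catalogue()
  missing_loci <- setdiff(unique(nv$locus), catalogue$name)
  if (length(missing_loci)) {
    stop("catalogue lacks loci needed for injection: ",
         paste(missing_loci, collapse = ", "))
  }
  wide <- sim$gt$data
  for (loc in unique(nv$locus)) {
    rows <- nv[nv$locus == loc, , drop = FALSE]
    calls <- lapply(wide[[loc]], split_call)
    slot_row <- rep(seq_along(calls), lengths(calls))
    slot_pos <- unlist(lapply(lengths(calls), seq_len), use.names = FALSE)
    n_slots <- length(slot_row)
    need <- sum(rows$count)
    if (need > n_slots) stop("not enough chromosome slots at ", loc)
    set.seed(derive_seed(seed, paste0("inject:", loc)))
    ord <- sample.int(n_slots)
    take <- ord[seq_len(need)]
    tok_by_slot <- rep(rows$motif, rows$count)
    for (q in seq_len(need)) {
      calls[[slot_row[take[q]]]][slot_pos[take[q]]] <- tok_by_slot[q]
    }
    # sweep background occurrences of injected strings off untouched slots
    rest <- ord[-seq_len(need)]
    safe <- paste0("[GGCA]", 30 + seq_len(length(rest)))
    for (q in seq_along(rest)) {
      cur <- calls[[slot_row[rest[q]]]][slot_pos[rest[q]]]
      if (cur %in% rows$motif) {
        calls[[slot_row[rest[q]]]][slot_pos[rest[q]]] <- safe[q]
      }
    }
    wide[[loc]] <- vapply(calls, function(x) paste(x, collapse = "/"), character(1))
  }
  sim$gt <- genotype_table(wide, catalogue)
  sim$injected <- nv
  sim
}
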