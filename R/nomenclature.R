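#' Parse a bracketed sequence-based STR allele
#'
#' Sequence-based (SB) alleles from MPS STR typing are written in the ISFG
#' bracket notation: repeated units as `[SEQ]n`, uppercase runs for
#' interruptions inside the repeat region, `N<k>` spacers for stretches that
#' are not part of the counted repeat region, and lowercase runs for
#' flanking-region (FR) sequence. Flanking-region variants (SNPs and indels
#' relative to the reference assembly) may be appended after `;` separators
#' as tokens of the form `GRCh38-chr2:68011829-C` (SNP),
#' `GRCh38-chr21:43227345-insTG` (insertion) or
#' `GRCh38-chr6:41709690-del2` (deletion), optionally prefixed `up@` /
#' `down@` to record the side.
#'
#' @param raw Allele string, e.g. `"[TCTA]13 TCTG [TCTA]1"`.
#' @param locus A `locus_def()` row, a bare motif length, or `NULL`.
#' @return An object of class `"sequence_allele"`: a list with `raw`,
#'   `locus`, `motif_len`, `blocks` (data.frame of tokens with columns
#'   `token_kind`, `seq`, `count`, `spacer_len`) and `flank_variants`
#'   (data.frame with `position`, `build`, `chrom`, `coord`, `kind`,
#'   `observed`, `side`).
#' @examples
#' a <- parse_bracket("[TCTA]13 TCTG [TCTA]1", locus = 4)
#' designation_from_bracket(a)  # 15
#' @export
parse_bracket <- function(raw, locus = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw))) {
    stop("allele string must be a single non-empty character value")
  }
  parts <- strsplit(raw, ";", fixed = TRUE)[[1]]
  motif_part <- trimws(parts[1])
  if (!nzchar(motif_part)) stop("allele string has no repeat-region part: ", sQuote(raw))
  fv <- if (length(parts) > 1L) {
    parse_flank_variants(trimws(parts[-1]))
  } else {
    empty_flank_variants()
  }
  blocks <- tokenize_bracket(motif_part)
  out <- list(raw = raw,
              locus = locus_name(locus),
              motif_len = locus_motif_len(locus),
              blocks = blocks,
              flank_variants = fv)
  class(out) <- "sequence_allele"
  out
}

# One whitespace chunk may hold several adjacent tokens (e.g. a lowercase
# flank run glued to a bracket). Consume greedily; anything unconsumable is
# reported verbatim.
tokenize_bracket <- function(s) {
  chunks <- strsplit(s, "[[:space:]]+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (!length(chunks)) stop("empty repeat-region string")
  kind <- character(0); seq <- character(0); count <- integer(0); spl <- integer(0)
  push <- function(k, sq, ct, sl) {
    kind <<- c(kind, k); seq <<- c(seq, sq); count <<- c(count, ct); spl <<- c(spl, sl)
  }
  for (chunk in chunks) {
    rest <- chunk
    while (nzchar(rest)) {
      if (startsWith(rest, "[")) {
        m <- regmatches(rest, regexec("^\\[([A-Za-z]+)\\]([0-9]+)", rest))[[1]]
        if (!length(m)) stop("malformed bracket token: ", sQuote(chunk))
        if (grepl("[^ACGT]", m[2])) {
          stop("bracket motif must be uppercase A/C/G/T in token: ", sQuote(chunk))
        }
        n <- as.integer(m[3])
        if (n < 1L) stop("bracket repeat count must be >= 1 in token: ", sQuote(chunk))
        push("bracketed", m[2], n, NA_integer_)
        rest <- substring(rest, nchar(m[1]) + 1L)
      } else if (grepl("^N[0-9]+", rest)) {
        m <- regmatches(rest, regexec("^N([0-9]+)", rest))[[1]]
        push("spacer", "", 1L, as.integer(m[2]))
        rest <- substring(rest, nchar(m[1]) + 1L)
      } else if (grepl("^[ACGT]+", rest)) {
        m <- regmatches(rest, regexec("^[ACGT]+", rest))[[1]]
        nxt <- substring(rest, nchar(m) + 1L, nchar(m) + 1L)
        if (nzchar(nxt) && grepl("^[acgt]$", nxt)) {
          stop("mixed-case token: ", sQuote(chunk))
        }
        push("interruption", m, 1L, NA_integer_)
        rest <- substring(rest, nchar(m) + 1L)
      } else if (grepl("^[acgt]+", rest)) {
        m <- regmatches(rest, regexec("^[acgt]+", rest))[[1]]
        nxt <- substring(rest, nchar(m) + 1L, nchar(m) + 1L)
        if (nzchar(nxt) && grepl("^[ACGT]$", nxt)) {
          stop("mixed-case token: ", sQuote(chunk))
        }
        push("flank", m, 1L, NA_integer_)
        rest <- substring(rest, nchar(m) + 1L)
      } else {
        stop("unrecognized characters in token: ", sQuote(chunk))
      }
    }
  }
  data.frame(token_kind = kind, seq = seq, count = count, spacer_len = spl,
             stringsAsFactors = FALSE)
}

parse_flank_variants <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(empty_flank_variants())
  rows <- lapply(tokens, function(tok) {
    side <- NA_character_
    body <- tok
    if (grepl("^(up|down)@", tok)) {
      side <- if (startsWith(tok, "up@")) "upstream" else "downstream"
      body <- sub("^(up|down)@", "", tok)
    }
    m <- regmatches(body,
                    regexec("^([A-Za-z0-9]+)-[Cc]hr([0-9XYMxym]+):[ ]?([0-9]+)-([A-Za-z0-9]+)$",
                            body))[[1]]
    if (!length(m)) stop("malformed flanking-variant token: ", sQuote(tok))
    coord <- as.integer(m[4])
    if (is.na(coord) || coord <= 0L) stop("flanking-variant coordinate must be positive: ", sQuote(tok))
    obs <- m[5]
    kind <- if (grepl("^ins", obs)) "insertion" else if (grepl("^del", obs)) "deletion" else "SNP"
    if (kind == "SNP" && grepl("[^ACGTacgt]", obs)) {
      stop("flanking SNP observed base must be A/C/G/T: ", sQuote(tok))
    }
    data.frame(position = paste0(m[2], "-chr", m[3], ":", m[4]),
               build = m[2], chrom = m[3], coord = coord,
               kind = kind, observed = obs, side = side,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_flank_variants <- function() {
  data.frame(position = character(0), build = character(0), chrom = character(0),
             coord = integer(0), kind = character(0), observed = character(0),
             side = character(0), stringsAsFactors = FALSE)
}

#' Canonical rendering of a parsed allele
#'
#' Tokens are rendered with a single space between them, bracketed blocks as
#' `[SEQ]n`, so that equal alleles have byte-equal canonical strings. Flank
#' variants, if any, are appended after `" ; "` sorted by genomic position.
#'
#' @param allele A `sequence_allele`.
#' @param flanks Include flanking-variant tokens (default `TRUE`).
#' @return A character scalar.
#' @export
render_bracket <- function(allele, flanks = TRUE) {
  stopifnot(inherits(allele, "sequence_allele"))
  b <- allele$blocks
  toks <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    toks[i] <- switch(b$token_kind[i],
      bracketed = paste0("[", b$seq[i], "]", b$count[i]),
      interruption = b$seq[i],
      flank = b$seq[i],
      spacer = paste0("N", b$spacer_len[i]))
  }
  out <- paste(toks, collapse = " ")
  fv <- allele$flank_variants
  if (flanks && nrow(fv)) {
    fv <- fv[order(fv$position, fv$observed), , drop = FALSE]
    side <- ifelse(is.na(fv$side), "",
                   ifelse(fv$side == "upstream", "up@", "down@"))
    out <- paste(out, ";", paste0(side, fv$position, "-", fv$observed, collapse = " ; "))
  }
  out
}

#' Identity key of a sequence-based allele
#'
#' Two SB alleles are the same allele iff their repeat-region block
#' structure, lowercase flanking sequence and flanking-variant lists all
#' agree; the key is the canonical rendering, so `allele_key()` equality is
#' allele equality.
#'
#' @param allele A `sequence_allele`.
#' @return A character scalar usable as a grouping key.
#' @export
allele_key <- function(allele) render_bracket(allele, flanks = TRUE)

rr_key <- function(allele) {
  b <- allele$blocks
  keep <- b$token_kind != "flank"
  a2 <- allele
  a2$blocks <- b[keep, , drop = FALSE]
  a2$flank_variants <- empty_flank_variants()
  render_bracket(a2, flanks = FALSE)
}

fr_key <- function(allele) {
  b <- allele$blocks
  flank_seq <- paste(b$seq[b$token_kind == "flank"], collapse = "|")
  fv <- allele$flank_variants
  fv_part <- if (nrow(fv)) {
    fv <- fv[order(fv$position, fv$observed), , drop = FALSE]
    paste(fv$position, fv$observed, sep = "-", collapse = ";")
  } else ""
  paste(flank_seq, fv_part, sep = " // ")
}

#' Length designation of a sequence-based STR allele
#'
#' The ISFG length designation counts the repeat-region length `L` in
#' nucleotides -- all bracketed blocks plus uppercase interruption runs;
#' lowercase flanking sequence and `N<k>` spacers are excluded -- and names
#' the allele `floor(L/m)` full units with a `.remainder` suffix when
#' `L mod m > 0`, `m` being the canonical motif length.
#'
#' @param allele A `sequence_allele` parsed with a known motif length, or a
#'   raw string (then `motif_len` must be given).
#' @param motif_len Motif length override when `allele` is a string.
#' @return An object of class `"str_designation"`: list with integer
#'   `units`, `remainder`, and `nt_length`.
#' @examples
#' designation_from_bracket("[CTGT]3 [CTAT]2 CAT [CTAT]8", motif_len = 4)  # 13.3
#' @export
designation_from_bracket <- function(allele, motif_len = NULL) {
  if (is.character(allele)) allele <- parse_bracket(allele, locus = motif_len)
  stopifnot(inherits(allele, "sequence_allele"))
  m <- if (!is.null(motif_len)) as.integer(motif_len) else allele$motif_len
  if (is.na(m) || is.null(m)) stop("motif length unset: cannot designate allele ", sQuote(allele$raw))
  b <- allele$blocks
  L <- sum(ifelse(b$token_kind == "bracketed", nchar(b$seq) * b$count,
           ifelse(b$token_kind == "interruption", nchar(b$seq), 0L)))
  out <- list(units = L %/% m, remainder = L %% m, nt_length = L, motif_len = m)
  class(out) <- "str_designation"
  out
}

#' @export
format.str_designation <- function(x, ...) {
  if (x$remainder == 0L) as.character(x$units) else paste0(x$units, ".", x$remainder)
}

#' @export
print.str_designation <- function(x, ...) {
  cat("STR designation:", format(x), sprintf("(%d nt, motif %d)\n", x$nt_length, x$motif_len))
  invisible(x)
}

#' @export
as.double.str_designation <- function(x, ...) x$units + x$remainder / 10

#' @export
print.sequence_allele <- function(x, ...) {
  cat("<sequence_allele>", render_bracket(x), "\n")
  if (!is.na(x$motif_len)) cat("  designation:", format(designation_from_bracket(x)), "\n")
  invisible(x)
}

#' Collapse sequence-based alleles to length classes
#'
#' Partitions a set of SB alleles of one locus by length designation -- the
#' information a capillary-electrophoresis (length-based, LB) assay would
#' retain. The number of keys is the LB allele count.
#'
#' @param alleles List of `sequence_allele` objects sharing one locus.
#' @return Named list: designation label -> list of member alleles.
#' @export
collapse_to_length <- function(alleles) {
  stopifnot(is.list(alleles), length(alleles) > 0)
  loci <- vapply(alleles, function(a) {
    if (is.null(a$locus) || is.na(a$locus)) "" else a$locus
  }, character(1))
  if (length(unique(loci[nzchar(loci)])) > 1L) {
    stop("collapse_to_length: alleles from mixed loci (contract violation): ",
         paste(unique(loci[nzchar(loci)]), collapse = ", "))
  }
  keys <- vapply(alleles, function(a) format(designation_from_bracket(a)), character(1))
  split(alleles, keys)
}

#' Bundled catalogue of novel repeat-region variant alleles
#'
#' Loads the package's bundled table of novel repeat-region STR variants
#' observed in a 100-individual (50 male, 50 female) Han Chinese population
#' typed on a 306-marker MPS panel: locus, printed designation, bracketed
#' motif, observed count and printed frequency. Each motif is parsed, its
#' designation recomputed by the length rule, and rows whose printed
#' designation disagrees with the rule are flagged rather than silently
#' corrected -- such discordances are a known hazard when comparing
#' nomenclature across MPS platforms and CE.
#'
#' @param path Optional override of the bundled TSV.
#' @return data.frame with columns `locus`, `chrom_class`, `motif_len`,
#'   `copy_count`, `designation` (printed), `motif`, `count`, `frequency`
#'   (printed), plus `computed_designation` and `designation_concordant`.
#' @export
novel_allele_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "novel_rr_alleles.tsv", package = "strpanel")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(designation = "character"))
  df$computed_designation <- vapply(seq_len(nrow(df)), function(i) {
    format(designation_from_bracket(df$motif[i], motif_len = df$motif_len[i]))
  }, character(1))
  df$designation_concordant <- df$computed_designation == df$designation
  df
}
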