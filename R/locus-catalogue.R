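#' Define a single panel marker
#'
#' A locus definition carries the identity and conventions of one marker:
#' its chromosome class (which fixes the ploidy bookkeeping downstream), the
#' canonical repeat-unit length used for STR length designations, and the
#' number of allele copies contributed per chromosome (2 for multi-copy
#' "a/b" Y markers such as DYS385a/b, otherwise 1).
#'
#' @param name Marker identifier, e.g. `"D8S1132"`.
#' @param chrom_class One of `"autosomal"`, `"X"`, `"Y"`.
#' @param motif_len Canonical repeat-unit length in nucleotides (2-5) for
#'   STRs; `NA` for SNPs.
#' @param copy_count Alleles contributed per chromosome (1 or 2).
#' @param marker_type `"STR"` or `"SNP"`.
#' @return A one-row `data.frame` with class `"locus_catalogue"`.
#' @examples
#' locus_def("DYS385a/b", "Y", motif_len = 4, copy_count = 2)
#' @export
locus_def <- function(name,
                      chrom_class = c("autosomal", "X", "Y"),
                      motif_len = NA_integer_,
                      copy_count = 1L,
                      marker_type = c("STR", "SNP")) {
  chrom_class <- match.arg(chrom_class)
  marker_type <- match.arg(marker_type)
  motif_len <- as.integer(motif_len)
  copy_count <- as.integer(copy_count)
  if (marker_type == "STR" && !is.na(motif_len) && !(motif_len %in% 2:5)) {
    stop("motif_len must be in 2..5 for STR locus ", name)
  }
  if (!(copy_count %in% 1:2)) stop("copy_count must be 1 or 2 for locus ", name)
  out <- data.frame(name = as.character(name), chrom_class = chrom_class,
                    motif_len = motif_len, copy_count = copy_count,
                    marker_type = marker_type, stringsAsFactors = FALSE)
  class(out) <- c("locus_catalogue", "data.frame")
  out
}

#' Build a locus catalogue from per-locus definitions
#'
#' @param ... `locus_def()` rows or compatible data.frames.
#' @return A `locus_catalogue` data.frame.
#' @export
locus_catalogue <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  validate_locus_catalogue(out)
}

validate_locus_catalogue <- function(df) {
  needed <- c("name", "chrom_class", "motif_len", "copy_count", "marker_type")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("locus catalogue lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicated locus names in catalogue")
  if (!all(df$chrom_class %in% c("autosomal", "X", "Y"))) {
    stop("chrom_class must be autosomal/X/Y")
  }
  if (!all(df$marker_type %in% c("STR", "SNP"))) stop("marker_type must be STR or SNP")
  bad <- df$marker_type == "STR" & !is.na(df$motif_len) & !(df$motif_len %in% 2:5)
  if (any(bad)) stop("motif_len out of 2..5 at: ", paste(df$name[bad], collapse = ", "))
  if (!all(df$copy_count %in% 1:2)) stop("copy_count must be 1 or 2")
  df$motif_len <- as.integer(df$motif_len)
  df$copy_count <- as.integer(df$copy_count)
  rownames(df) <- NULL
  class(df) <- c("locus_catalogue", "data.frame")
  df
}

#' Read / write a locus catalogue TSV
#'
#' The catalogue dialect is a plain TSV with header
#' `name  chrom_class  motif_len  copy_count  marker_type`.
#'
#' @param path File path.
#' @return `read_locus_catalogue`: a `locus_catalogue`;
#'   `write_locus_catalogue`: `path`, invisibly.
#' @export
read_locus_catalogue <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_locus_catalogue(df)
}

#' @rdname read_locus_catalogue
#' @param catalogue A `locus_catalogue`.
#' @export
write_locus_catalogue <- function(catalogue, path) {
  utils::write.table(as.data.frame(catalogue), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

catalogue_row <- function(catalogue, locus) {
  i <- match(locus, catalogue$name)
  if (is.na(i)) stop("locus not in catalogue: ", locus)
  catalogue[i, , drop = FALSE]
}

locus_motif_len <- function(locus) {
  if (is.null(locus)) return(NA_integer_)
  if (is.numeric(locus)) return(as.integer(locus))
  if (is.data.frame(locus)) return(as.integer(locus$motif_len[1]))
  if (is.list(locus) && !is.null(locus$motif_len)) return(as.integer(locus$motif_len))
  NA_integer_
}

locus_name <- function(locus) {
  if (is.null(locus) || is.numeric(locus)) return(NA_character_)
  if (is.data.frame(locus)) return(as.character(locus$name[1]))
  if (is.list(locus) && !is.null(locus$name)) return(as.character(locus$name))
  NA_character_
}
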