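#' Assemble and validate a genotype table
#'
#' The pipeline's input container: allele calls for samples x loci together
#' with per-sample sex, validated against chromosome-class ploidy rules --
#' autosomal loci carry two calls per sample, X loci two in females and one
#' in males, Y loci `copy_count` calls in males and none in females. Empty
#' cells are null (no call) and are excluded from all downstream
#' denominators.
#'
#' @param df Wide data.frame: columns `sample`, `sex` (`"M"`/`"F"`), then one
#'   column per locus; diploid cells `"A1/A2"` (unordered), hemizygous cells
#'   a single token, multi-copy Y cells `"A1/A2"`, empty cells null.
#' @param catalogue A `locus_catalogue` covering every locus column.
#' @return An object of class `"genotype_table"`: list with `data` (the wide
#'   table), `long` (one row per allele call: `sample`, `sex`, `locus`,
#'   `allele`), `samples`, `catalogue`.
#' @export
genotype_table <- function(df, catalogue) {
  catalogue <- validate_locus_catalogue(as.data.frame(catalogue))
  if (!all(c("sample", "sex") %in% names(df))) {
    stop("genotype table needs 'sample' and 'sex' columns")
  }
  if (anyDuplicated(df$sample)) stop("duplicated sample IDs")
  if (!all(df$sex %in% c("M", "F"))) stop("sex column values must be 'M' or 'F'")
  loci <- setdiff(names(df), c("sample", "sex"))
  unknown <- setdiff(loci, catalogue$name)
  if (length(unknown)) stop("loci absent from catalogue: ", paste(unknown, collapse = ", "))

  problems <- validate_genotype_calls(df, catalogue, loci)
  if (nrow(problems)) {
    stop("genotype table validation failed:\n",
         paste(sprintf("  sample %s, locus %s: %s",
                       problems$sample, problems$locus, problems$reason),
               collapse = "\n"))
  }

  long <- genotype_long(df, loci)
  out <- list(data = df, long = long,
              samples = df[, c("sample", "sex")], catalogue = catalogue)
  class(out) <- "genotype_table"
  out
}

split_call <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  trimws(strsplit(cell, "/", fixed = TRUE)[[1]])
}

expected_call_count <- function(chrom_class, copy_count, sex) {
  switch(chrom_class,
    autosomal = 2L,
    X = if (sex == "F") 2L else 1L,
    Y = if (sex == "M") copy_count else 0L)
}

validate_genotype_calls <- function(df, catalogue, loci) {
  bad <- list()
  for (loc in loci) {
    row <- catalogue_row(catalogue, loc)
    for (i in seq_len(nrow(df))) {
      calls <- split_call(df[[loc]][i])
      n <- length(calls)
      if (n == 0L) {
        if (row$chrom_class == "Y" && df$sex[i] == "F") next
        next  # null call: dropped, never an allele class
      }
      want <- expected_call_count(row$chrom_class, row$copy_count, df$sex[i])
      if (want == 0L) {
        bad[[length(bad) + 1L]] <- data.frame(
          sample = df$sample[i], locus = loc,
          reason = "female sample with Y-chromosome call", stringsAsFactors = FALSE)
      } else if (n != want) {
        bad[[length(bad) + 1L]] <- data.frame(
          sample = df$sample[i], locus = loc,
          reason = sprintf("expected %d allele call(s), found %d", want, n),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(sample = character(0), locus = character(0), reason = character(0))
}

genotype_long <- function(df, loci) {
  recs <- vector("list", length(loci))
  for (j in seq_along(loci)) {
    loc <- loci[j]
    calls <- lapply(df[[loc]], split_call)
    n <- lengths(calls)
    recs[[j]] <- data.frame(sample = rep(df$sample, n), sex = rep(df$sex, n),
                            locus = loc, allele = unlist(calls, use.names = FALSE),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples (%d M / %d F), %d loci\n",
              nrow(x$samples), sum(x$samples$sex == "M"), sum(x$samples$sex == "F"),
              nrow(x$catalogue)))
  invisible(x)
}

#' Locus names of a genotype table, filtered by class/type
#' @param gt A `genotype_table`.
#' @param chrom_class Optional filter (`"autosomal"`, `"X"`, `"Y"`).
#' @param marker_type Optional filter (`"STR"`, `"SNP"`).
#' @return Character vector of locus names present in the table.
#' @export
loci_of <- function(gt, chrom_class = NULL, marker_type = NULL) {
  cat_ <- gt$catalogue
  keep <- rep(TRUE, nrow(cat_))
  if (!is.null(chrom_class)) keep <- keep & cat_$chrom_class %in% chrom_class
  if (!is.null(marker_type)) keep <- keep & cat_$marker_type %in% marker_type
  cat_$name[keep & cat_$name %in% names(gt$data)]
}

#' Drop one sample from a genotype table
#' @param gt A `genotype_table`.
#' @param sample Sample ID to remove.
#' @return A new `genotype_table`.
#' @export
drop_sample <- function(gt, sample) {
  stopifnot(inherits(gt, "genotype_table"))
  genotype_table(gt$data[gt$data$sample != sample, , drop = FALSE], gt$catalogue)
}

#' Read / write the genotype TSV dialect
#'
#' Plain TSV, UTF-8, header row: `sample`, `sex`, then one column per locus;
#' diploid calls `"A1/A2"`, hemizygous calls a single token, empty cell =
#' null. Rows that violate the ploidy/sex rules are rejected with a per-row
#' reason listing.
#'
#' @param path File path.
#' @param catalogue A `locus_catalogue`.
#' @return A `genotype_table` (reader) or `path` invisibly (writer).
#' @export
read_genotype_table <- function(path, catalogue) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  genotype_table(df, catalogue)
}

#' @rdname read_genotype_table
#' @param gt A `genotype_table`.
#' @export
write_genotype_table <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  utils::write.table(gt$data, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
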