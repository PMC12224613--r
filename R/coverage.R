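#' Depth-of-coverage summary and QC flags
#'
#' The depth of coverage (DoC) of a locus is the sum of valid reads at that
#' locus in a sample, averaged over samples. The summary reports per-locus
#' mean DoC, the panel mean, the best- and worst-covered loci, their
#' highest-to-lowest ratio (rounded to an integer for reporting), and the
#' loci whose mean falls below the QC threshold (default 650x).
#'
#' @param cov Long data.frame with columns `locus`, `sample`, `reads`
#'   (valid read counts, non-negative).
#' @param threshold Mean-DoC flagging threshold.
#' @return `"doc_summary"`: list with `per_locus` (data.frame `locus`,
#'   `mean_doc`, `flagged`), `panel_mean`, `max_locus`, `min_locus`,
#'   `ratio`, `ratio_rounded`, `flagged` (locus names), `threshold`.
#' @export
doc_summary <- function(cov, threshold = 650) {
  needed <- c("locus", "sample", "reads")
  if (!all(needed %in% names(cov))) {
    stop("coverage table needs columns: ", paste(needed, collapse = ", "))
  }
  if (!nrow(cov)) stop("empty coverage table")
  if (any(cov$reads < 0)) stop("negative read counts")
  means <- tapply(cov$reads, cov$locus, mean)
  per_locus <- data.frame(locus = names(means), mean_doc = as.numeric(means),
                          flagged = as.numeric(means) < threshold,
                          stringsAsFactors = FALSE)
  per_locus <- per_locus[order(per_locus$locus), , drop = FALSE]
  rownames(per_locus) <- NULL
  mn <- min(per_locus$mean_doc); mx <- max(per_locus$mean_doc)
  if (mn == 0) stop("ratio undefined: a locus has zero mean coverage")
  out <- list(per_locus = per_locus,
              panel_mean = mean(per_locus$mean_doc),
              max_locus = per_locus$locus[which.max(per_locus$mean_doc)],
              min_locus = per_locus$locus[which.min(per_locus$mean_doc)],
              ratio = mx / mn,
              ratio_rounded = as.integer(round(mx / mn)),
              flagged = per_locus$locus[per_locus$flagged],
              threshold = threshold)
  class(out) <- "doc_summary"
  out
}

#' @export
print.doc_summary <- function(x, ...) {
  cat(sprintf(paste0("<doc_summary> %d loci, panel mean %.0fx\n",
                     "  range %.0fx (%s) .. %.0fx (%s), ratio %d\n",
                     "  %d locus/loci below %gx\n"),
              nrow(x$per_locus), x$panel_mean,
              min(x$per_locus$mean_doc), x$min_locus,
              max(x$per_locus$mean_doc), x$max_locus,
              x$ratio_rounded, length(x$flagged), x$threshold))
  invisible(x)
}

#' Read / write the coverage TSV dialect
#'
#' Long-form TSV with header `locus  sample  reads`.
#'
#' @param path File path.
#' @export
read_coverage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "sample", "reads") %in% names(df))) {
    stop("coverage TSV needs columns locus, sample, reads")
  }
  df
}

#' @rdname read_coverage_table
#' @param cov Coverage data.frame.
#' @export
write_coverage_table <- function(cov, path) {
  utils::write.table(cov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
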