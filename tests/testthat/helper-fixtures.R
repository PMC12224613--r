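# Small in-code fixtures shared across test files.

tiny_catalogue <- function() {
  locus_catalogue(
    locus_def("AutoA", "autosomal", 4),
    locus_def("AutoB", "autosomal", 4),
    locus_def("Xloc", "X", 4),
    locus_def("Ysingle", "Y", 4),
    locus_def("Ymulti", "Y", 4, copy_count = 2),
    locus_def("SnpA", "autosomal", NA, marker_type = "SNP"))
}

# deterministic hand-built table: 2 males, 2 females
tiny_gt <- function() {
  df <- data.frame(
    sample = c("m1", "m2", "f1", "f2"),
    sex = c("M", "M", "F", "F"),
    AutoA = c("10/11", "10/10", "11/12", "10/11"),
    AutoB = c("7/8", "7/7", "8/8", "7/8"),
    Xloc = c("14", "15", "14/15", "14/14"),
    Ysingle = c("20", "21", "", ""),
    Ymulti = c("17/18", "17/17", "", ""),
    SnpA = c("A/G", "G/G", "A/A", "A/G"),
    stringsAsFactors = FALSE)
  genotype_table(df, tiny_catalogue())
}

# study-shaped simulation reused by several files (cached per session)
.study_cache <- new.env()
cached_study <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- simulate_panel_study(seed = seed)
  }
  .study_cache[[key]]
}

split_calls_for_test <- function(cell) strpanel:::split_call(cell)

validate_fixture_catalogue <- function(df) strpanel:::validate_locus_catalogue(df)

expect_close <- function(x, y, tol = 1e-12) {
  testthat::expect_true(abs(x - y) <= tol,
                        label = sprintf("|%g - %g| <= %g", x, y, tol))
}
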