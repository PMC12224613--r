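test_that("allele frequencies use chromosome-correct denominators", {
  gt <- tiny_gt()
  fa <- compute_allele_frequencies(gt, "AutoA")
  expect_equal(attr(fa, "denominator"), 8L)           # 2 per diploid sample
  expect_equal(sum(fa$count), 8L)
  expect_equal(sum(fa$frequency), 1, tolerance = 1e-12)
  expect_equal(fa$frequency, fa$count / 8)

  fx <- compute_allele_frequencies(gt, "Xloc")
  expect_equal(attr(fx, "denominator"), 6L)           # 2F x 2 + 2M x 1
  fy <- compute_allele_frequencies(gt, "Ysingle")
  expect_equal(attr(fy, "denominator"), 2L)           # males only
  fym <- compute_allele_frequencies(gt, "Ymulti")
  expect_equal(attr(fym, "denominator"), 4L)          # 2 males x copy_count 2
  expect_equal(fym$count[fym$allele == "17"], 3L)
})

test_that("a monomorphic locus yields a single entry with frequency 1", {
  df <- data.frame(sample = c("a", "b"), sex = c("F", "F"),
                   AutoA = c("12/12", "12/12"), stringsAsFactors = FALSE)
  gt <- genotype_table(df, tiny_catalogue()[1, ])
  f <- compute_allele_frequencies(gt, "AutoA")
  expect_equal(nrow(f), 1L)
  expect_equal(f$frequency, 1)
})

test_that("null calls drop out of numerator and denominator; removal of a sample shrinks the denominator by its ploidy", {
  df <- data.frame(sample = c("a", "b", "c"), sex = c("F", "F", "F"),
                   AutoA = c("12/13", "", "13/13"), stringsAsFactors = FALSE)
  gt <- genotype_table(df, tiny_catalogue()[1, ])
  f <- compute_allele_frequencies(gt, "AutoA")
  expect_equal(attr(f, "denominator"), 4L)
  expect_false("" %in% f$allele)

  gt2 <- drop_sample(gt, "c")
  f2 <- compute_allele_frequencies(gt2, "AutoA")
  expect_equal(attr(f, "denominator") - attr(f2, "denominator"), 2L)
})

test_that("ploidy and sex violations are rejected with sample and locus named", {
  cat6 <- tiny_catalogue()
  bad1 <- data.frame(sample = "s1", sex = "F", Ysingle = "20",
                     stringsAsFactors = FALSE)
  expect_error(genotype_table(bad1, cat6), "female sample with Y-chromosome call")
  bad2 <- data.frame(sample = "s9", sex = "M", AutoA = "12",
                     stringsAsFactors = FALSE)
  expect_error(genotype_table(bad2, cat6), "s9.*AutoA.*expected 2")
  bad3 <- data.frame(sample = "s2", sex = "M", Xloc = "14/15",
                     stringsAsFactors = FALSE)
  expect_error(genotype_table(bad3, cat6), "expected 1")
  expect_error(genotype_table(data.frame(sample = "s", sex = "U",
                                         stringsAsFactors = FALSE), cat6),
               "sex column")
})

test_that("Y haplotype assembly counts exact tuples, sorted within multi-copy loci", {
  cat6 <- tiny_catalogue()
  df <- data.frame(
    sample = sprintf("m%d", 1:4), sex = rep("M", 4),
    Ysingle = c("20", "20", "21", "20"),
    Ymulti = c("17/18", "18/17", "17/17", "18/18"),  # rows 1,2 identical unordered
    stringsAsFactors = FALSE)
  gt <- genotype_table(df, cat6)
  yh <- assemble_y_haplotypes(gt, c("Ysingle", "Ymulti"))
  expect_equal(yh$N, 4L)
  expect_equal(yh$k, 3L)
  expect_equal(sum(yh$haplotypes$count), yh$N)
  expect_equal(max(yh$haplotypes$count), 2L)

  # missing call drops the male with a warning
  df$Ymulti[3] <- ""
  gt2 <- genotype_table(df, cat6)
  expect_warning(yh2 <- assemble_y_haplotypes(gt2, c("Ysingle", "Ymulti")),
                 "dropped 1 male")
  expect_equal(yh2$N, 3L)
})

test_that("haplotype counting agrees with a hash-free pairwise-comparison oracle", {
  study <- cached_study()
  yloci <- loci_of(study$gt, "Y", "STR")[1:6]
  yh <- assemble_y_haplotypes(study$gt, yloci)
  males <- study$gt$data[study$gt$data$sex == "M", ]
  tuples <- lapply(seq_len(nrow(males)), function(i) {
    unlist(lapply(yloci, function(l) sort(split_calls_for_test(males[[l]][i]))))
  })
  # O(N^2) equality partition
  n <- length(tuples)
  assigned <- rep(NA_integer_, n); cls <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    cls <- cls + 1L; assigned[i] <- cls
    if (i < n) for (j in (i + 1L):n) {
      if (is.na(assigned[j]) && identical(tuples[[i]], tuples[[j]])) assigned[j] <- cls
    }
  }
  expect_equal(yh$k, cls)
  expect_equal(sort(yh$haplotypes$count), sort(as.integer(table(assigned))))
})

test_that("male/female X spectra: identical spectra give p ~ 1, disjoint spectra reject", {
  cat1 <- locus_catalogue(locus_def("Xloc", "X", 4))
  same <- data.frame(
    sample = c(sprintf("m%d", 1:10), sprintf("f%d", 1:5)),
    sex = c(rep("M", 10), rep("F", 5)),
    Xloc = c(rep(c("14", "15"), 5), rep("14/15", 5)),
    stringsAsFactors = FALSE)
  gt <- genotype_table(same, cat1)
  expect_gt(pool_sex_frequencies_check(gt, "Xloc")$p_value, 0.9)

  disj <- data.frame(
    sample = c(sprintf("m%d", 1:20), sprintf("f%d", 1:10)),
    sex = c(rep("M", 20), rep("F", 10)),
    Xloc = c(rep("14", 20), rep("15/15", 10)),
    stringsAsFactors = FALSE)
  gt2 <- genotype_table(disj, cat1)
  expect_lt(pool_sex_frequencies_check(gt2, "Xloc")$p_value, 0.01)
})

test_that("Monte-Carlo homogeneity p agrees with full enumeration on a 2x3 table", {
  # direct comparison at the fisher.test level on the same sex-by-allele table
  cat1 <- locus_catalogue(locus_def("Xloc", "X", 4))
  df <- data.frame(
    sample = c(sprintf("m%d", 1:12), sprintf("f%d", 1:8)),
    sex = c(rep("M", 12), rep("F", 8)),
    Xloc = c(rep("14", 6), rep("15", 4), rep("16", 2),
             rep("14/15", 3), rep("15/16", 3), rep("16/16", 2)),
    stringsAsFactors = FALSE)
  gt <- genotype_table(df, cat1)
  chk <- pool_sex_frequencies_check(gt, "Xloc")
  exact_p <- stats::fisher.test(chk$table)$p.value
  set.seed(3)
  mc_p <- stats::fisher.test(chk$table, simulate.p.value = TRUE, B = 20000)$p.value
  se <- sqrt(exact_p * (1 - exact_p) / 20000)
  expect_lt(abs(mc_p - exact_p), 4 * se + 1e-4)
  expect_equal(chk$p_value, exact_p, tolerance = 1e-12)
})

test_that("genotype TSV round-trips through the package readers", {
  gt <- tiny_gt()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  cat_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(gt, tsv)
  write_locus_catalogue(gt$catalogue, cat_tsv)
  gt2 <- read_genotype_table(tsv, read_locus_catalogue(cat_tsv))
  expect_identical(gt2$data, gt$data)
  expect_identical(gt2$long, gt$long)
})
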