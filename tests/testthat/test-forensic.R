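test_that("gene diversity hits its boundary cases and the unbiased correction", {
  expect_equal(gene_diversity(c(1), n = 50), 0)
  # n observations all distinct: sum p^2 = 1/n, GD exactly 1
  n <- 12
  expect_equal(gene_diversity(rep(1 / n, n), n = n), 1)
  expect_equal(gene_diversity(c(0.98, 0.02), n = 50), 50 / 49 * (1 - (0.98^2 + 0.02^2)))
  expect_error(gene_diversity(c(0.5, 0.5), n = 1), "n >= 2")
  expect_error(gene_diversity(c(0.5, 0.4)), "sum to 1")
})

test_that("closed-form PIC equals the double-sum oracle", {
  expect_equal(pic(c(1)), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(0.5, 0.5)), oracle_pic(c(0.5, 0.5)), tolerance = 1e-14)
  set.seed(4)
  for (r in 1:20) {
    k <- sample(2:8, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    expect_equal(pic(p), oracle_pic(p), tolerance = 1e-12)
  }
})

test_that("match probability equals the with-replacement pairwise oracle", {
  expect_equal(match_probability(rep("12/13", 7))$MP, 1)
  expect_equal(match_probability(rep("12/13", 7))$PD, 0)
  expect_equal(match_probability(as.character(1:9))$MP, 1 / 9)
  set.seed(8)
  g <- sample(c("a/a", "a/b", "b/b", "b/c"), 40, replace = TRUE)
  mp <- match_probability(g)
  expect_equal(mp$MP, oracle_match_probability(g), tolerance = 1e-12)
  expect_equal(mp$PD, 1 - mp$MP)
  expect_error(match_probability(character(0)), "empty locus")
})

test_that("PE and TPI follow the heterozygosity closed forms with boundaries", {
  expect_equal(pe_tpi(0), list(PE = 0, TPI = 0.5))
  expect_equal(pe_tpi(0.5), list(PE = 0.1875, TPI = 1))
  r <- pe_tpi(1)
  expect_equal(r$PE, 1)
  expect_identical(r$TPI, Inf)
})

test_that("panel combination multiplies in log space and renders the 1-x style", {
  one <- data.frame(MP = 0.1, PE = 0.3, TPI = 2)
  ps1 <- combine_panel(one)
  expect_equal(ps1$CMP, 0.1)
  expect_equal(ps1$CPE, 0.3)
  expect_equal(ps1$CPI, 2)
  two <- data.frame(MP = c(0.1, 0.1), PE = c(0.3, 0.5), TPI = c(2, 3))
  ps2 <- combine_panel(two)
  expect_equal(ps2$CMP, 0.01, tolerance = 1e-12)
  expect_equal(ps2$CPE, 1 - 0.7 * 0.5, tolerance = 1e-12)
  expect_equal(ps2$CPI, 6, tolerance = 1e-12)
  expect_match(ps2$CPD_rendered, "^1-")
  # log-space survives magnitudes that underflow double precision
  many <- data.frame(MP = rep(0.01, 60), PE = rep(0.9, 60), TPI = rep(10, 60))
  psm <- combine_panel(many)
  expect_equal(psm$log10_CMP, -120)
  expect_equal(psm$log10_CPI, 60)
  expect_equal(psm$CPD_rendered, "1-1.000e-120")
})

test_that("CMP decreases (CPD increases) monotonically as loci are added", {
  set.seed(12)
  mp <- runif(10, 0.05, 0.6)
  logs <- vapply(1:10, function(k) {
    combine_panel(data.frame(MP = mp[1:k], PE = 0.5, TPI = 1))$log10_CMP
  }, numeric(1))
  expect_true(all(diff(logs) < 0))
})

test_that("MEC closed forms equal their enumeration oracles on the 0.05-grid", {
  # monomorphic: every scenario excludes no one
  m <- mec_suite(c(1))
  expect_equal(unlist(m[1:4], use.names = FALSE), rep(0, 4))

  # values at p = (1/2, 1/2), frozen from the enumeration oracles
  p2 <- c(0.5, 0.5)
  expect_equal(oracle_mec_trio(p2), 0.375)
  expect_equal(oracle_mec_duo(p2), 0.25)
  expect_equal(oracle_mec_kruger(p2), 0.1875)
  m2 <- mec_suite(p2)
  expect_equal(m2$MEC_Kishida, 0.375)
  expect_equal(m2$MEC_Desmarais, 0.375)
  expect_equal(m2$MEC_Desmarais_Duo, 0.25)
  expect_equal(m2$MEC_Kruger, 0.1875)

  # trio beats duo with 10 equifrequent alleles (information from the mother)
  p10 <- rep(0.1, 10)
  expect_gte(mec_suite(p10)$MEC_Desmarais, mec_suite(p10)$MEC_Desmarais_Duo)
  expect_equal(mec_suite(p10)$MEC_Desmarais, oracle_mec_trio(p10), tolerance = 1e-12)

  # all grid vectors (<= 5 classes, 1/20 grid; oracles are exchangeable so
  # sorted representatives cover the full grid)
  for (p in grid_frequency_vectors(5L, 20L)) {
    m <- mec_suite(p)
    expect_equal(m$MEC_Kishida, oracle_mec_trio(p), tolerance = 1e-10)
    expect_equal(m$MEC_Desmarais_Duo, oracle_mec_duo(p), tolerance = 1e-10)
    expect_equal(m$MEC_Kruger, oracle_mec_kruger(p), tolerance = 1e-10)
  }
  expect_error(mec_suite(c(0.7, 0.2)), "sum to 1")
})

test_that("X discrimination powers match enumeration and the hemizygote closed form", {
  xm <- x_discrimination(c(1))
  expect_equal(xm$PD_M, 0)
  expect_equal(xm$PD_F, 0)
  x2 <- x_discrimination(c(0.5, 0.5))
  expect_equal(x2$PD_M, 0.5)
  expect_equal(x2$PD_F, 0.625)
  for (k in c(2, 4, 7)) {
    expect_equal(x_discrimination(rep(1 / k, k))$PD_M, 1 - 1 / k, tolerance = 1e-12)
  }
  for (p in grid_frequency_vectors(5L, 20L)) {
    expect_equal(x_discrimination(p)$PD_F, oracle_pd_f(p), tolerance = 1e-10)
  }
})

test_that("haplotype diversity and discrimination capacity follow the direct-count formulas", {
  all_same <- c(10)
  hd0 <- haplotype_diversity(all_same)
  expect_equal(hd0$HD, 0)
  expect_equal(hd0$DC, 1 / 10)

  all_distinct <- rep(1, 25)
  hd1 <- haplotype_diversity(all_distinct)
  expect_equal(hd1$HD, 1)
  expect_equal(hd1$DC, 1)
  expect_equal(hd1$unique_fraction, 1)

  # 50 males, 48 singletons and one doubleton (k = 49)
  cfg <- c(rep(1, 48), 2)
  hd <- haplotype_diversity(cfg)
  expect_equal(hd$HD, 50 / 49 * (1 - 52 / 2500), tolerance = 1e-12)
  expect_equal(round(hd$HD, 4), 0.9992)
  expect_equal(hd$DC, 0.98)
  expect_equal(hd$unique_fraction, 48 / 49)
  expect_error(haplotype_diversity(c(1)), "N >= 2")
})

test_that("HD and GD are invariant under allele/haplotype relabelling", {
  set.seed(9)
  counts <- c(4, 9, 1, 1, 3, 7)
  perm <- sample(counts)
  expect_equal(haplotype_diversity(counts)$HD, haplotype_diversity(perm)$HD)
  p <- counts / sum(counts)
  expect_equal(gene_diversity(p, sum(counts)),
               gene_diversity(sample(p), sum(counts)))
  expect_equal(pic(p), pic(sample(p)))
})

test_that("SNP statistics equal the STR machinery restricted to two alleles", {
  cat1 <- locus_catalogue(locus_def("S", "autosomal", NA, marker_type = "SNP"))
  df <- data.frame(sample = sprintf("s%d", 1:8), sex = rep("F", 8),
                   S = c("A/A", "A/G", "A/G", "G/G", "A/G", "A/A", "G/G", "A/G"),
                   stringsAsFactors = FALSE)
  gt <- genotype_table(df, cat1)
  st <- snp_stats(gt, "S")
  expect_equal(st$DP, st$PD)
  expect_equal(st$MP, oracle_match_probability(
    c("A/A", "A/G", "A/G", "G/G", "A/G", "A/A", "G/G", "A/G")), tolerance = 1e-12)
  # monomorphic SNP: DP 0
  df0 <- data.frame(sample = c("a", "b"), sex = c("F", "F"), S = c("A/A", "A/A"),
                    stringsAsFactors = FALSE)
  expect_equal(snp_stats(genotype_table(df0, cat1), "S")$DP, 0)
  # a third allele is a validation error
  df3 <- data.frame(sample = c("a", "b"), sex = c("F", "F"), S = c("A/G", "A/T"),
                    stringsAsFactors = FALSE)
  expect_error(snp_stats(genotype_table(df3, cat1), "S"), "3 alleles")
})

test_that("on synthetic HWE populations Hobs tracks Hexp within 3 standard errors", {
  study <- cached_study()
  loci <- loci_of(study$gt, "autosomal", "STR")[1:12]
  for (l in loci) {
    st <- locus_stats(study$gt, l)
    se <- sqrt(st$Hexp * (1 - st$Hexp) / st$n_genotypes)
    expect_lt(abs(st$Hobs - st$Hexp), 3 * se + 1e-9)
  }
})
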