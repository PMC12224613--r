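#' Exact Hardy-Weinberg test
#'
#' Conditional exact test on the genotype array given the allele counts
#' (Levene's distribution). The p-value is the probability mass of genotype
#' arrays no more probable than the observed one. For small problems (at
#' most 4 alleles and 15 diploid individuals) the array space is enumerated
#' in full; otherwise the mass is estimated by Monte-Carlo shuffling of the
#' allele vector into random pairs, with the add-one estimate
#' `(hits + 1) / (steps + 1)`.
#'
#' @param geno Two-column matrix or data.frame of allele labels, one row per
#'   diploid individual; or a `genotype_table` together with `locus`.
#' @param locus Locus name when `geno` is a `genotype_table`. X loci use
#'   females only by default (hemizygotes carry no HWE information).
#' @param steps Monte-Carlo shuffles.
#' @param seed Seed for the Monte-Carlo path (required for reproducibility
#'   in pipeline runs).
#' @param method `"auto"` (enumerate small problems), `"enumeration"`, or
#'   `"monte_carlo"`.
#' @param females_only X-locus convention, default `TRUE`.
#' @return `"hwe_test"`: list with `p_value`, `method`, `statistic` (log
#'   conditional probability of the observed array), `steps`, `seed`,
#'   `n`, `k`.
#' @export
hwe_exact <- function(geno, locus = NULL, steps = 100000, seed = NULL,
                      method = c("auto", "enumeration", "monte_carlo"),
                      females_only = TRUE) {
  method <- match.arg(method)
  if (inherits(geno, "genotype_table")) {
    stopifnot(!is.null(locus))
    row <- catalogue_row(geno$catalogue, locus)
    df <- geno$data
    if (row$chrom_class == "X" && females_only) df <- df[df$sex == "F", , drop = FALSE]
    if (row$chrom_class == "Y") stop("HWE is undefined for haploid Y data")
    calls <- lapply(df[[locus]], split_call)
    calls <- calls[lengths(calls) == 2L]
    geno <- do.call(rbind, calls)
  }
  geno <- as.matrix(geno)
  if (ncol(geno) != 2L) stop("diploid genotypes required (two columns)")
  if (nrow(geno) < 2L) stop("HWE test needs >= 2 individuals")
  lev <- sort(unique(as.vector(geno)))
  k <- length(lev)
  n <- nrow(geno)
  if (k == 1L) {
    return(structure(list(p_value = 1, method = "degenerate", statistic = 0,
                          steps = 0L, seed = seed, n = n, k = k),
                     class = "hwe_test"))
  }
  a <- matrix(match(geno, lev), ncol = 2L)
  alleles <- as.vector(a)
  acounts <- tabulate(alleles, k)
  obs_tab <- pair_table(a[, 1], a[, 2], k)
  lp_obs <- log_levene(obs_tab, acounts, n, k)

  if (method == "auto") {
    method <- if (k <= 4L && n <= 15L) "enumeration" else "monte_carlo"
  }
  if (method == "enumeration") {
    res <- hwe_enumerate(acounts, n, k, lp_obs)
    structure(list(p_value = res, method = "enumeration", statistic = lp_obs,
                   steps = 0L, seed = seed, n = n, k = k), class = "hwe_test")
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    m <- 2L * n
    for (s in seq_len(steps)) {
      perm <- alleles[sample.int(m)]
      tab <- pair_table(perm[seq_len(n)], perm[n + seq_len(n)], k)
      if (log_levene(tab, acounts, n, k) <= lp_obs + 1e-9) hits <- hits + 1L
    }
    structure(list(p_value = (hits + 1) / (steps + 1), method = "monte_carlo",
                   statistic = lp_obs, steps = steps, seed = seed, n = n, k = k),
              class = "hwe_test")
  }
}

# genotype counts as a k*k upper-triangular vector indexed (i-1)*k + j, i<=j
pair_table <- function(x, y, k) {
  i <- pmin(x, y); j <- pmax(x, y)
  tabulate((i - 1L) * k + j, k * k)
}

# log conditional probability of a genotype array given allele counts
log_levene <- function(tab, acounts, n, k) {
  idx <- which(tab > 0L)
  het <- sum(tab[idx[((idx - 1L) %/% k + 1L) != ((idx - 1L) %% k + 1L)]])
  lgamma(n + 1) + sum(lgamma(acounts + 1)) + het * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(tab[idx] + 1))
}

# enumerate all genotype arrays with the given allele-count margins
hwe_enumerate <- function(acounts, n, k, lp_obs) {
  pairs <- list()
  for (i in seq_len(k)) for (j in i:k) pairs[[length(pairs) + 1L]] <- c(i, j)
  total <- 0
  mass <- 0
  tab <- integer(k * k)
  rec <- function(idx, rem) {
    if (idx > length(pairs)) {
      if (all(rem == 0L)) {
        lp <- log_levene(tab, acounts, n, k)
        total <<- total + exp(lp)
        if (lp <= lp_obs + 1e-9) mass <<- mass + exp(lp)
      }
      return(invisible())
    }
    ij <- pairs[[idx]]
    i <- ij[1]; j <- ij[2]
    gmax <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (g in 0:gmax) {
      r2 <- rem
      if (i == j) r2[i] <- r2[i] - 2L * g else {
        r2[i] <- r2[i] - g; r2[j] <- r2[j] - g
      }
      # prune: once row i is exhausted of later pairs, its remainder must be 0
      if (j == k && r2[i] != 0L) next
      tab[(i - 1L) * k + j] <<- g
      rec(idx + 1L, r2)
    }
    tab[(i - 1L) * k + j] <<- 0L
    invisible()
  }
  rec(1L, acounts)
  mass / total  # normalization guards rounding; total == 1 analytically
}

#' Pairwise linkage-disequilibrium test
#'
#' For unphased diploid data the statistic is the likelihood-ratio between
#' two-locus haplotype frequencies fitted by expectation-maximization and
#' the independence model (allele-frequency products); the null distribution
#' comes from permuting one locus's genotypes across individuals. For
#' haploid data (Y markers) the G statistic on the haplotype contingency
#' table is permuted directly. `p = (exceedances + 1) / (permutations + 1)`,
#' so a p-value of exactly 0 is impossible.
#'
#' @param ga,gb Either two-column matrices (diploid) or vectors (haploid) of
#'   allele labels per individual, row-aligned.
#' @param permutations Number of permutations.
#' @param seed RNG seed.
#' @return `"ld_test"`: list with `p_value`, `statistic`, `method`,
#'   `permutations`, `seed`.
#' @export
ld_pairwise <- function(ga, gb, permutations = 1000, seed = NULL) {
  haploid <- is.null(dim(ga))
  if (!is.null(seed)) set.seed(seed)
  if (haploid) {
    ga <- as.vector(ga); gb <- as.vector(gb)
    stopifnot(length(ga) == length(gb))
    if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
      return(structure(list(p_value = 1, statistic = 0, method = "degenerate",
                            permutations = 0L, seed = seed), class = "ld_test"))
    }
    stat_obs <- g_statistic(table(ga, gb))
    exceed <- 0L
    for (i in seq_len(permutations)) {
      if (g_statistic(table(ga, gb[sample.int(length(gb))])) >= stat_obs - 1e-9) {
        exceed <- exceed + 1L
      }
    }
    structure(list(p_value = (exceed + 1) / (permutations + 1),
                   statistic = stat_obs, method = "haploid_g_permutation",
                   permutations = permutations, seed = seed), class = "ld_test")
  } else {
    ga <- as.matrix(ga); gb <- as.matrix(gb)
    stopifnot(ncol(ga) == 2L, ncol(gb) == 2L, nrow(ga) == nrow(gb))
    if (length(unique(as.vector(ga))) < 2L || length(unique(as.vector(gb))) < 2L) {
      return(structure(list(p_value = 1, statistic = 0, method = "degenerate",
                            permutations = 0L, seed = seed), class = "ld_test"))
    }
    stat_obs <- ld_lr_statistic(ga, gb)
    n <- nrow(ga)
    exceed <- 0L
    for (i in seq_len(permutations)) {
      if (ld_lr_statistic(ga, gb[sample.int(n), , drop = FALSE]) >= stat_obs - 1e-9) {
        exceed <- exceed + 1L
      }
    }
    structure(list(p_value = (exceed + 1) / (permutations + 1),
                   statistic = stat_obs, method = "em_lr_permutation",
                   permutations = permutations, seed = seed), class = "ld_test")
  }
}

g_statistic <- function(tab) {
  o <- as.numeric(tab)
  e <- as.numeric(outer(rowSums(tab), colSums(tab))) / sum(tab)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

# likelihood-ratio statistic: EM haplotype fit vs allele-frequency independence
ld_lr_statistic <- function(ga, gb) {
  em <- em_haplotype_freqs(ga, gb)
  2 * (em$loglik - em$loglik_indep)
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Standard gene-counting EM: only double heterozygotes have ambiguous
#' phase; their expected haplotype contributions are reapportioned each
#' iteration. Converges when the log-likelihood gain drops below `tol` or
#' after `max_iter` iterations.
#'
#' @param ga,gb Two-column allele matrices, row-aligned individuals.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List: `haplotypes` (data.frame `a`, `b`, `freq`), `loglik`,
#'   `loglik_indep`, `iterations`.
#' @export
em_haplotype_freqs <- function(ga, gb, tol = 1e-8, max_iter = 1000) {
  ga <- as.matrix(ga); gb <- as.matrix(gb)
  la <- sort(unique(as.vector(ga))); lb <- sort(unique(as.vector(gb)))
  ka <- length(la); kb <- length(lb)
  A <- matrix(match(ga, la), ncol = 2L)
  B <- matrix(match(gb, lb), ncol = 2L)
  n <- nrow(A)
  hid <- function(i, j) (i - 1L) * kb + j  # haplotype index (a_i, b_j)

  # aggregate individuals into phase-configuration records
  key <- paste(pmin(A[, 1], A[, 2]), pmax(A[, 1], A[, 2]),
               pmin(B[, 1], B[, 2]), pmax(B[, 1], B[, 2]))
  agg <- table(key)
  cfg <- lapply(names(agg), function(kk) {
    v <- as.integer(strsplit(kk, " ")[[1]])
    a1 <- v[1]; a2 <- v[2]; b1 <- v[3]; b2 <- v[4]
    if (a1 != a2 && b1 != b2) {
      list(n = agg[[kk]],
           ph = list(c(hid(a1, b1), hid(a2, b2)), c(hid(a1, b2), hid(a2, b1))))
    } else {
      list(n = agg[[kk]], ph = list(c(hid(a1, b1), hid(a2, b2))))
    }
  })

  pa <- tabulate(as.vector(A), ka) / (2 * n)
  pb <- tabulate(as.vector(B), kb) / (2 * n)
  h <- as.vector(outer(pa, pb))

  cfg_loglik <- function(h) {
    sum(vapply(cfg, function(cc) {
      pr <- sum(vapply(cc$ph, function(p) {
        w <- h[p[1]] * h[p[2]]
        if (p[1] != p[2]) 2 * w else w
      }, numeric(1)))
      cc$n * log(max(pr, 1e-300))
    }, numeric(1)))
  }

  ll_indep <- cfg_loglik(h)
  ll <- ll_indep
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(ka * kb)
    for (cc in cfg) {
      ws <- vapply(cc$ph, function(p) {
        w <- h[p[1]] * h[p[2]]
        if (p[1] != p[2]) 2 * w else w
      }, numeric(1))
      ws <- ws / sum(ws)
      for (q in seq_along(cc$ph)) {
        p <- cc$ph[[q]]
        counts[p[1]] <- counts[p[1]] + cc$n * ws[q]
        counts[p[2]] <- counts[p[2]] + cc$n * ws[q]
      }
    }
    h <- counts / (2 * n)
    ll_new <- cfg_loglik(h)
    if (ll_new - ll < tol || iter >= max_iter) { ll <- ll_new; break }
    ll <- ll_new
  }
  hap <- expand.grid(b = lb, a = la, stringsAsFactors = FALSE)[, c("a", "b")]
  list(haplotypes = data.frame(hap, freq = h, stringsAsFactors = FALSE),
       loglik = ll, loglik_indep = ll_indep, iterations = iter)
}

#' Bonferroni bookkeeping for a test family
#'
#' @param n Number of loci (pairwise families) or tests.
#' @param alpha Family-wise level (default 0.05).
#' @param pairwise If `TRUE`, the family is all `n (n - 1) / 2` locus pairs.
#' @return List with `n_tests` and `alpha_prime = alpha / n_tests`.
#' @examples
#' bonferroni_plan(66)$n_tests   # 2145
#' bonferroni_plan(132)$n_tests  # 8646
#' @export
bonferroni_plan <- function(n, alpha = 0.05, pairwise = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  n_tests <- if (pairwise) n * (n - 1L) / 2L else n
  if (n_tests < 1L) stop("pairwise plan needs >= 2 loci")
  list(n_tests = as.integer(n_tests), alpha = alpha,
       alpha_prime = alpha / n_tests)
}

#' Batch HWE tests with Bonferroni flags
#'
#' @param gt A `genotype_table`.
#' @param loci Loci to test (diploid classes only).
#' @param alpha Family-wise level.
#' @param steps,seed Monte-Carlo controls; each locus gets a sub-seed
#'   derived from `seed` and its name so results do not depend on test
#'   order.
#' @return data.frame: locus, statistic, p_value, method, steps, seed,
#'   alpha_prime, significant.
#' @export
hwe_test_panel <- function(gt, loci, alpha = 0.05, steps = 10000, seed = 1) {
  plan <- bonferroni_plan(length(loci), alpha, pairwise = FALSE)
  rows <- lapply(loci, function(l) {
    sseed <- derive_seed(seed, l)
    ht <- hwe_exact(gt, locus = l, steps = steps, seed = sseed)
    data.frame(locus = l, statistic = ht$statistic, p_value = ht$p_value,
               method = ht$method, steps = ht$steps, seed = sseed,
               alpha_prime = plan$alpha_prime,
               significant = ht$p_value < plan$alpha_prime,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Batch pairwise LD tests with Bonferroni flags
#'
#' The Bonferroni denominator always counts the full pairwise family over
#' `loci` (`scope = "all_pairs"`), matching the usual reporting convention,
#' but the tests actually run can be restricted with `max_pairs` for large
#' panels.
#'
#' @param gt A `genotype_table`.
#' @param loci Loci to pair.
#' @param alpha Family-wise level.
#' @param permutations,seed Permutation controls.
#' @param max_pairs Optional cap on the number of pairs actually tested
#'   (first pairs in order); the alpha_prime denominator is unaffected.
#' @return data.frame: locus1, locus2, statistic, p_value, method, seed,
#'   alpha_prime, significant.
#' @export
ld_test_panel <- function(gt, loci, alpha = 0.05, permutations = 200, seed = 1,
                          max_pairs = NULL) {
  plan <- bonferroni_plan(length(loci), alpha, pairwise = TRUE)
  cls <- gt$catalogue$chrom_class[match(loci, gt$catalogue$name)]
  haploid <- all(cls == "Y")
  pairs <- utils::combn(loci, 2L, simplify = FALSE)
  if (!is.null(max_pairs) && length(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs)]
  rows <- lapply(pairs, function(pr) {
    sseed <- derive_seed(seed, paste(pr, collapse = "|"))
    if (haploid) {
      males <- gt$data[gt$data$sex == "M", , drop = FALSE]
      va <- vapply(males[[pr[1]]], function(c) split_call(c)[1], character(1))
      vb <- vapply(males[[pr[2]]], function(c) split_call(c)[1], character(1))
      keep <- !is.na(va) & !is.na(vb)
      lt <- ld_pairwise(va[keep], vb[keep], permutations = permutations, seed = sseed)
    } else {
      ga <- diploid_matrix(gt, pr[1]); gb <- diploid_matrix(gt, pr[2])
      keep <- stats::complete.cases(ga) & stats::complete.cases(gb)
      lt <- ld_pairwise(ga[keep, , drop = FALSE], gb[keep, , drop = FALSE],
                        permutations = permutations, seed = sseed)
    }
    data.frame(locus1 = pr[1], locus2 = pr[2], statistic = lt$statistic,
               p_value = lt$p_value, method = lt$method, seed = sseed,
               alpha_prime = plan$alpha_prime,
               significant = lt$p_value < plan$alpha_prime,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "plan") <- plan
  out
}

diploid_matrix <- function(gt, locus) {
  row <- catalogue_row(gt$catalogue, locus)
  df <- gt$data
  if (row$chrom_class == "X") df <- df[df$sex == "F", , drop = FALSE]
  calls <- lapply(df[[locus]], split_call)
  t(vapply(calls, function(x) if (length(x) == 2L) x else c(NA_character_, NA_character_),
           character(2)))
}

# deterministic per-item sub-seed: stable string hash mixed with the run seed
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483647)
}
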