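# Independent brute-force oracles. These deliberately enumerate rather than
# reuse any closed form from the package.

# PIC as the explicit double sum 1 - sum p_i^2 - sum_{i != j} p_i^2 p_j^2
oracle_pic <- function(p) {
  k <- length(p)
  dd <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) dd <- dd + p[i]^2 * p[j]^2
  1 - sum(p^2) - dd
}

# female X match probability under HWE, enumerated over ordered genotypes
oracle_pd_f <- function(p) {
  k <- length(p)
  mp <- 0
  for (i in seq_len(k)) for (j in i:k) {
    fg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    mp <- mp + fg^2
  }
  1 - mp
}

# Paternal-allele candidate set weight for a mother/daughter configuration:
# enumerate mother (i,j), transmitted maternal allele u, true father k.
# S = {k}, plus u when the daughter is heterozygous and the mother also
# carries k (then either daughter allele could be paternal).
# Returns E[f(pS)] for a supplied excludee non-match function.
oracle_mec_scenario <- function(p, excl_fun) {
  k <- length(p)
  acc <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) for (f in seq_len(k)) {
    w_base <- p[i] * p[j] * p[f]
    for (u in c(i, j)) {
      w <- w_base * 0.5
      pS <- p[f]
      if (u != f && (f == i || f == j)) pS <- pS + p[u]
      acc <- acc + w * excl_fun(pS)
    }
  }
  acc
}

# trio (Kishida/Desmarais): excludee is a hemizygous male
oracle_mec_trio <- function(p) oracle_mec_scenario(p, function(pS) 1 - pS)

# deficiency (Krüger): excludee is the diploid paternal grandmother
oracle_mec_kruger <- function(p) oracle_mec_scenario(p, function(pS) (1 - pS)^2)

# duo: no mother; S is the daughter's genotype
oracle_mec_duo <- function(p) {
  k <- length(p)
  acc <- 0
  for (u in seq_len(k)) for (f in seq_len(k)) {
    pS <- if (u == f) p[u] else p[u] + p[f]
    acc <- acc + p[u] * p[f] * (1 - pS)
  }
  acc
}

# pairwise match probability by counting matching ordered pairs
oracle_match_probability <- function(genotypes) {
  n <- length(genotypes)
  hits <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (genotypes[i] == genotypes[j]) hits <- hits + 1
  }
  hits / n^2
}

# exact HWE p for tiny n by enumerating every permutation of the allele
# vector (all pairings equally likely given the allele counts)
oracle_hwe_tiny <- function(geno) {
  geno <- as.matrix(geno)
  lev <- sort(unique(as.vector(geno)))
  k <- length(lev)
  a <- matrix(match(geno, lev), ncol = 2)
  n <- nrow(a)
  alleles <- as.vector(a)
  perms <- all_permutations(length(alleles))
  logp <- function(x, y) {
    i <- pmin(x, y); j <- pmax(x, y)
    tab <- tabulate((i - 1L) * k + j, k * k)
    idx <- which(tab > 0)
    het <- sum(tab[idx[((idx - 1L) %/% k) + 1L != ((idx - 1L) %% k) + 1L]])
    het * log(2) - sum(lgamma(tab[idx] + 1))  # shared constants omitted
  }
  lp_obs <- logp(a[, 1], a[, 2])
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    v <- alleles[perms[r, ]]
    if (logp(v[seq_len(n)], v[n + seq_len(n)]) <= lp_obs + 1e-9) hits <- hits + 1L
  }
  hits / nrow(perms)
}

all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, nrow = m * nrow(sub), ncol = m)
  r <- 1L
  for (pos in seq_len(m)) {
    for (s in seq_len(nrow(sub))) {
      rest <- sub[s, ] + (sub[s, ] >= pos)
      out[r, ] <- c(pos, rest)
      r <- r + 1L
    }
  }
  out
}

# all frequency vectors with <= kmax positive entries on a 1/20 grid,
# deduplicated up to permutation (every oracle here is exchangeable)
grid_frequency_vectors <- function(kmax = 5L, denom = 20L) {
  parts <- list()
  rec <- function(remaining, maxpart, acc) {
    if (remaining == 0L) {
      if (length(acc) <= kmax) parts[[length(parts) + 1L]] <<- acc
      return(invisible())
    }
    if (length(acc) == kmax) return(invisible())
    for (v in seq_len(min(maxpart, remaining))) rec(remaining - v, v, c(acc, v))
  }
  rec(denom, denom, integer(0))
  lapply(parts, function(x) x / denom)
}
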