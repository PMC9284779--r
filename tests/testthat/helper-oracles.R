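# Independent oracles and tiny fixtures used across the suite. Oracles are
# deliberately brute-force (enumeration / grid search) and share no code
# with the implementation paths they check.

# Exhaustive conditional HWE distribution via log-factorials: p-value for
# observed het count given genotype counts.
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * n_aa + n_ab
  n2 <- 2 * n_bb + n_ab
  rare <- min(n1, n2)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n1 - h) / 2; nbb <- (n2 - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-10)])
}

# Two-sided Fisher exact p by full hypergeometric enumeration over the 2x2
# tables with the observed margins.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# 1-D likelihood-grid oracle for the two-locus haplotype MLE: profiles the
# multinomial genotype-class likelihood over pAB with marginal allele
# frequencies fixed at their (closed-form) MLEs.
oracle_two_locus_grid <- function(g1, g2, grid_n = 20001) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  pA <- 1 - mean(g1) / 2
  pB <- 1 - mean(g2) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, function(pAB) {
    f <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    f <- pmax(f, 1e-12)
    pr <- matrix(0, 3, 3)
    pr[1, 1] <- f[1]^2; pr[1, 2] <- 2 * f[1] * f[2]; pr[1, 3] <- f[2]^2
    pr[2, 1] <- 2 * f[1] * f[3]
    pr[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
    pr[2, 3] <- 2 * f[2] * f[4]
    pr[3, 1] <- f[3]^2; pr[3, 2] <- 2 * f[3] * f[4]; pr[3, 3] <- f[4]^2
    sum(tab[tab > 0] * log(pmax(pr[tab > 0], 1e-300)))
  }, numeric(1))
  pAB <- grid[which.max(ll)]
  c(pAB = pAB, pAb = pA - pAB, paB = pB - pAB, pab = 1 - pA - pB + pAB)
}

# Brute-force simplex-grid maximiser of the multi-marker phasing
# likelihood for a small haplotype universe (used on 3-SNP toys): a full
# coarse grid over the simplex refined around the incumbent in shrinking
# steps, with the likelihood evaluated vectorised over grid points.
oracle_em_simplex <- function(genotypes, haps_bits) {
  K <- nrow(haps_bits)
  # compatible ordered hap pairs per individual
  pair_sets <- lapply(seq_len(nrow(genotypes)), function(r) {
    g <- genotypes[r, ]
    idx <- which(outer(seq_len(K), seq_len(K), Vectorize(function(i, j)
      all(haps_bits[i, ] + haps_bits[j, ] == g))), arr.ind = TRUE)
    idx
  })
  eval_ll <- function(FF) {   # FF: n_combo x K frequency matrix
    ll <- rep(0, nrow(FF))
    for (ps in pair_sets) {
      s <- rep(0, nrow(FF))
      for (r in seq_len(nrow(ps))) s <- s + FF[, ps[r, 1]] * FF[, ps[r, 2]]
      ll <- ll + log(pmax(s, 1e-300))
    }
    ll
  }
  grid_around <- function(centre, half, step) {
    axes <- lapply(centre[-K], function(x)
      seq(max(0, x - half), min(1, x + half), by = step))
    combos <- as.matrix(expand.grid(axes))
    combos <- combos[rowSums(combos) <= 1 + 1e-9, , drop = FALSE]
    cbind(combos, 1 - rowSums(combos))
  }
  best <- rep(1 / K, K)
  for (stage in list(c(0.5, 0.1), c(0.1, 0.02), c(0.02, 0.004),
                     c(0.004, 0.0008), c(0.0008, 0.00016))) {
    FF <- grid_around(best, stage[1], stage[2])
    ll <- eval_ll(FF)
    best <- FF[which.max(ll), ]
  }
  list(freqs = as.numeric(best), loglik = max(ll))
}

# Small toy pool with complete LD between its sites; positions default to
# a 100 bp ladder matching the haplotype length.
toy_pool <- function(freqs = c(0.6, 0.4), haps = c("AAA", "CCC"),
                     block_id = "toy", positions = NULL) {
  m <- nchar(haps[1])
  if (is.null(positions)) positions <- as.integer(seq_len(m) * 100L)
  hap_pool(block_id, "1", positions,
           tibble::tibble(hap = haps, freq = freqs))
}

# Published per-stage OR (95% CI) pairs used for the meta-analysis worked
# examples: stage 1 and stage 2 estimates for three replicated
# sub-haplotypes.
published_stage_pairs <- function() {
  list(
    H1.2c = list(s1 = c(1.31, 1.16, 1.47), s2 = c(1.12, 0.97, 1.30)),
    H1.2e = list(s1 = c(1.17, 0.99, 1.39), s2 = c(1.05, 0.85, 1.30)),
    H1.1e = list(s1 = c(2.51, 2.20, 2.86), s2 = c(1.45, 0.98, 2.17))
  )
}

stage_pair_effects <- function(pair) {
  s1 <- logor_from_or_ci(pair$s1[1], pair$s1[2], pair$s1[3])
  s2 <- logor_from_or_ci(pair$s2[1], pair$s2[2], pair$s2[3])
  study_effects(c("stage1", "stage2"), c(s1$b, s2$b), c(s1$se, s2$se))
}

# Stage-1 printed OR and 95% CI per non-reference sub-haplotype of the
# three default blocks, keyed by allele string.
published_stage1_cis <- function() {
  tibble::tribble(
    ~hap,         ~or,   ~lo,   ~hi,
    "ACTTG",       1.60, 1.45, 1.78,
    "GCCTG",       0.37, 0.32, 0.42,
    "ATCTG",       0.22, 0.19, 0.26,
    "ACCTG",       2.51, 2.20, 2.86,
    "TCTCGATG",    1.27, 1.14, 1.40,
    "TTAAAATA",    1.31, 1.16, 1.47,
    "TTAAGATG",    1.36, 1.16, 1.59,
    "CTTCGATG",    1.17, 0.99, 1.39,
    "TTTCGGTG",    1.16, 0.96, 1.39,
    "TTAAAATG",    1.10, 0.77, 1.54,
    "TTTCGACG",    1.28, 0.89, 1.84,
    "CATTAGGGC",   0.43, 0.38, 0.49,
    "GATTGAGAT",   1.11, 0.99, 1.24,
    "CTTTGGTGC",   0.61, 0.54, 0.70,
    "CATTGGGGC",   1.67, 1.45, 1.92,
    "CATTGGGGT",   0.60, 0.51, 0.70,
    "GATCGAGAT",   0.83, 0.67, 1.03
  )
}
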