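test_that("two-locus EM matches closed-form counting without double hets", {
  # individuals: AB/AB, AB/ab, ab/ab as homozygote-anchored genotypes
  g1 <- c(0L, 0L, 2L, 2L, 0L)
  g2 <- c(0L, 0L, 2L, 2L, 2L)   # one AB/Ab-style recombinant, no double het
  em <- two_locus_em(g1, g2)
  expect_equal(em$n_iter, 1L)
  expect_equal(unname(em$freqs),
               c(4, 2, 0, 4) / 10, tolerance = 1e-12)
  # complete-LD sample: only AB/AB, ab/ab, AB/ab individuals
  g1 <- c(0L, 0L, 2L, 1L, 1L)
  g2 <- c(0L, 0L, 2L, 1L, 1L)
  em2 <- two_locus_em(g1, g2)
  expect_equal(unname(em2$freqs[2:3]), c(0, 0), tolerance = 1e-9)
  # marginal allele frequencies preserved exactly
  expect_equal(unname(em2$freqs[1] + em2$freqs[2]), 1 - mean(g1) / 2)
})

test_that("two-locus EM frequencies maximise the likelihood (grid oracle)", {
  withr::with_seed(20, {
    for (r in 1:50) {
      n <- sample(30:120, 1)
      pA <- runif(1, 0.2, 0.8); pB <- runif(1, 0.2, 0.8)
      d <- runif(1, -0.5, 0.9) *
        (if (runif(1) < 0.5) min(pA * (1 - pB), (1 - pA) * pB)
         else min(pA * pB, (1 - pA) * (1 - pB)))
      f <- c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
             (1 - pA) * (1 - pB) + d)
      if (any(f < 0.01)) next
      hap1 <- sample(1:4, 2 * n, TRUE, prob = f)
      hap2 <- sample(1:4, 2 * n, TRUE, prob = f)
      a1 <- as.integer(hap1 %in% c(3, 4)) ; b1 <- as.integer(hap1 %in% c(2, 4))
      g1 <- a1[1:n] + a1[(n + 1):(2 * n)]
      g2 <- b1[1:n] + b1[(n + 1):(2 * n)]
      if (var(g1) == 0 || var(g2) == 0) next
      em <- two_locus_em(g1, g2, tol = 1e-10)
      oracle <- oracle_two_locus_grid(g1, g2)
      expect_equal(unname(em$freqs), unname(oracle), tolerance = 1e-4)
      expect_true(all(diff(em$loglik) >= -1e-8))   # monotone likelihood
    }
  })
})

test_that("ld_stats reproduces the D-prime and r2 definitions", {
  perfect <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$Dprime, 1)
  expect_equal(perfect$r2, 1)
  indep <- ld_stats(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(indep$D, 0)
  expect_equal(indep$Dprime, 0)
  hand <- ld_stats(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(hand$D, 0.15)
  expect_equal(hand$Dprime, 0.6)
  expect_equal(hand$r2, 0.36)
  mono <- ld_stats(c(0.5, 0.5, 0, 0))
  expect_true(is.na(mono$Dprime) && is.na(mono$r2))
})

test_that("D-prime matches phased-truth counting on simulated pools", {
  pool <- build_default_pools()$H1.1
  bits <- subhapr:::pool_hap_bits(pool)
  withr::with_seed(21, {
    dip <- sample_diplotypes(pool, 1000)
    geno <- genotypes_from_diplotypes(dip, pool)$genotypes
    chroms <- rbind(bits[dip[, 1], ], bits[dip[, 2], ])
    for (pair in list(c(1, 2), c(2, 5), c(1, 5))) {
      em <- two_locus_em(geno[, pair[1]], geno[, pair[2]])
      est <- ld_stats(em$freqs)
      a <- chroms[, pair[1]]; b <- chroms[, pair[2]]
      truth <- ld_stats(c(mean(a == 0 & b == 0), mean(a == 0 & b == 1),
                          mean(a == 1 & b == 0), mean(a == 1 & b == 1)))
      expect_equal(est$Dprime, truth$Dprime, tolerance = 0.02)
    }
  })
})

test_that("D-prime CI concentrates with information and widens at tiny n", {
  withr::with_seed(22, {
    h <- rbinom(1000, 1L, 0.5)
    g <- matrix(h[1:500] + h[501:1000], ncol = 1)
    ci_big <- dprime_ci(g[, 1], g[, 1])
    expect_gte(ci_big$ci_low, 0.98)
    # 10 chromosomes: CI too wide for "strong LD" even at MLE 1
    ci_small <- dprime_ci(g[1:5, 1], g[1:5, 1])
    expect_equal(ci_small$dprime_mle, 1)
    expect_lt(ci_small$ci_low, 0.7)
    # doubling identical data never widens the CI
    g2 <- c(g[1:50, 1], g[1:50, 1])
    ci1 <- dprime_ci(g[1:50, 1], g[1:50, 1])
    ci2 <- dprime_ci(g2, g2)
    expect_gte(ci2$ci_low, ci1$ci_low)
    expect_lte(ci2$ci_high - ci2$ci_low, ci1$ci_high - ci1$ci_low)
  })
})

test_that("ld_matrix is pairwise-complete, symmetric in samples, and EM-consistent", {
  co <- simulate_cohort(n = 200, tag = NULL, seed = 23)
  members <- co$variants$id[co$variants$block_id %in% "H1.1"]
  g <- co$genotypes[, members]
  ld <- ld_matrix(g, positions = co$variants$pos[match(members, co$variants$id)])
  expect_equal(nrow(ld), choose(5, 2))
  # entries equal direct two_locus_em results
  em <- two_locus_em(g[, 1], g[, 3])
  row <- ld[ld$i == 1 & ld$j == 3, ]
  expect_equal(c(row$pAB, row$pAb, row$paB, row$pab), unname(em$freqs))
  # permuting samples leaves the matrix unchanged
  perm <- withr::with_seed(1, sample(nrow(g)))
  ld2 <- ld_matrix(g[perm, ], positions = co$variants$pos[match(members, co$variants$id)])
  expect_equal(ld2$Dprime, ld$Dprime)
  expect_equal(ld2$ci_low, ld$ci_low)
})

test_that("Gabriel detection finds one tight block and rejects independence", {
  withr::with_seed(24, {
    pool <- toy_pool(freqs = c(0.55, 0.45), haps = c("AAAAA", "CCCCC"),
                     positions = as.integer(c(100, 600, 1100, 1600, 2100)))
    dip <- sample_diplotypes(pool, 1000)
    g <- genotypes_from_diplotypes(dip, pool)$genotypes
    blocks <- gabriel_blocks(g, pool$positions)
    expect_equal(nrow(blocks), 1L)
    expect_equal(blocks$n_snps, 5L)
    expect_equal(blocks$start, 100L)
    expect_equal(blocks$stop, 2100L)
    # mutually independent SNPs: no blocks
    ind <- vapply(runif(6, 0.2, 0.8), function(p) rbinom(1000, 2L, p),
                  integer(1000))
    expect_equal(nrow(gabriel_blocks(ind, seq(1, 6) * 1000)), 0L)
  })
})

test_that("blocks never violate the marker-count or span limits", {
  withr::with_seed(25, {
    pool <- toy_pool(freqs = c(0.5, 0.5),
                     haps = c(strrep("A", 8), strrep("C", 8)),
                     positions = as.integer(seq(1, 8) * 30000))  # 210 kb
    dip <- sample_diplotypes(pool, 800)
    g <- genotypes_from_diplotypes(dip, pool)$genotypes
    blocks <- gabriel_blocks(g, pool$positions, max_markers = 4,
                             max_span_bp = 100000)
    expect_true(all(blocks$n_snps <= 4))
    expect_true(all(blocks$stop - blocks$start <= 100000))
  })
})
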