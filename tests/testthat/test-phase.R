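test_that("EM on homozygote-only cohorts equals direct chromosome counts", {
  g <- rbind(matrix(0L, 6, 3), matrix(2L, 4, 3))
  hs <- em_haplotype_freqs(g, block_id = "hom")
  # one move from the uniform start plus one no-op convergence check
  expect_lte(hs$n_iter, 2L)
  expect_equal(sort(hs$haplotypes$frequency, decreasing = TRUE), c(0.6, 0.4))
  expect_equal(hs$haplotypes$hap[hs$haplotypes$frequency == 0.6], "000")
})

test_that("3-SNP EM matches the exhaustive simplex-grid oracle", {
  # anchoring homozygotes plus one double heterozygote
  g <- rbind(
    matrix(rep(c(0L, 0L, 0L), 4), ncol = 3, byrow = TRUE),
    matrix(rep(c(2L, 2L, 0L), 2), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 2L, 2L), 2), ncol = 3, byrow = TRUE),
    c(1L, 1L, 0L))
  hs <- em_haplotype_freqs(g, block_id = "toy", tol = 1e-10, max_iter = 500)
  universe_bits <- do.call(rbind, lapply(strsplit(hs$haplotypes$hap, ""),
                                         as.integer))
  oracle <- oracle_em_simplex(g, universe_bits)
  expect_equal(hs$loglik[length(hs$loglik)], oracle$loglik, tolerance = 1e-6)
  expect_equal(hs$haplotypes$frequency, oracle$freqs, tolerance = 1e-3)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  co <- simulate_cohort(n = 400, missing_rate = 0.02, seed = 30)
  for (b in c("H1.1", "H1.2")) {
    members <- co$variants$id[co$variants$block_id %in% b]
    hs <- em_haplotype_freqs(co$genotypes[, members], block_id = b)
    expect_true(all(diff(hs$loglik) >= -1e-8))
  }
})

test_that("default-pool haplotypes are recovered from cohort genotypes", {
  pool <- build_default_pools()$H1.2
  res <- em_recovery_study(pool, n = 2000, seeds = 1:3)
  expect_true(all(res$max_abs_err <= 0.02))
  expect_true(all(res$max_spurious <= 0.01))
})

test_that("pruning keeps the boundary, drops artifacts, and never renormalises", {
  pool <- build_default_pools()$H1.2
  dip <- sample_diplotypes(pool, 4000, seed = 33)
  g <- genotypes_from_diplotypes(dip, pool)
  al <- subhapr:::pool_alleles(pool)
  hs <- em_haplotype_freqs(g$genotypes, block_id = "H1.2",
                           alleles = list(ref = al$ref, alt = al$alt))
  pr <- prune_rare(hs, min_freq = 0.01)
  # retention follows the >= rule exactly, on the estimated frequencies
  expect_equal(pr$haplotypes$retained, pr$haplotypes$frequency >= 0.01)
  # both published boundary haplotypes are present in the estimate
  expect_true(all(c("TTAAAATG", "TTTCGACG") %in% pr$haplotypes$hap))
  # raw-scale frequencies unchanged by pruning
  expect_equal(pr$haplotypes$frequency, hs$haplotypes$frequency)
  # a haplotype at exactly the threshold frequency is kept (>= semantics)
  gx <- rbind(matrix(0L, 99, 2), matrix(2L, 1, 2))
  hx <- em_haplotype_freqs(gx)
  px <- prune_rare(hx, min_freq = 0.01)
  expect_true(all(px$haplotypes$retained))
  expect_equal(min(px$haplotypes$frequency), 0.01)
  # an all-common hap_set passes through unchanged
  hs2 <- em_haplotype_freqs(rbind(matrix(0L, 5, 2), matrix(2L, 5, 2)))
  expect_equal(prune_rare(hs2)$haplotypes$retained, c(TRUE, TRUE))
  expect_error(prune_rare(hs2, min_freq = 0.9), "below")
})

test_that("diplotype posteriors are normalised and EM-consistent", {
  pool <- build_default_pools()$H1.1
  dip <- sample_diplotypes(pool, 500, seed = 34)
  g <- genotypes_from_diplotypes(dip, pool)$genotypes
  hs <- em_haplotype_freqs(g, block_id = "H1.1", tol = 1e-8, max_iter = 200)
  # posteriors sum to 1 per individual
  for (i in c(1, 17, 250)) {
    post <- diplotype_posteriors(hs, i)
    expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  }
  # an unambiguous homozygote has a single pair at posterior 1
  hom <- which(apply(g, 1, function(x) all(x %in% c(0L, 2L))))[1]
  expect_equal(nrow(diplotype_posteriors(hs, hom)), 1L)
  # summing posterior dosages reproduces the M-step numerator:
  # mean dosage = 2 * frequency at the EM fixed point
  dos <- haplotype_dosages(hs, retained_only = FALSE)
  expect_equal(unname(colMeans(dos) / 2),
               hs$haplotypes$frequency, tolerance = 1e-6)
  # rows sum to 2 and dosages stay in [0, 2]
  expect_equal(unname(rowSums(dos)), rep(2, nrow(dos)), tolerance = 1e-9)
  expect_true(all(dos >= -1e-12 & dos <= 2 + 1e-12))
})

test_that("a balanced double heterozygote splits its posterior 50/50", {
  # two equally frequent complementary resolutions
  g <- rbind(matrix(c(0L, 0L), 3, 2), matrix(c(2L, 2L), 3, 2),
             matrix(c(0L, 2L), 3, 2), matrix(c(2L, 0L), 3, 2),
             c(1L, 1L), c(1L, 0L))
  hs <- em_haplotype_freqs(g, tol = 1e-10, max_iter = 500)
  post <- diplotype_posteriors(hs, 13)
  expect_equal(sort(post$posterior), c(0.5, 0.5), tolerance = 1e-6)
  # each resolution's two haplotypes share the double het's mass equally
  dos <- haplotype_dosages(hs, retained_only = FALSE)
  expect_equal(unname(sort(dos[13, ], decreasing = TRUE)), rep(0.5, 4),
               tolerance = 1e-6)
  # a heterozygote with a single compatible unordered pair (row 14, het at
  # one site) gives both its haplotypes dosage exactly 1
  d_sh <- sort(dos[14, dos[14, ] > 1e-6], decreasing = TRUE)
  expect_equal(unname(d_sh), c(1, 1), tolerance = 1e-6)
})

test_that("expected dosages track true dosages under complete LD", {
  pool <- build_default_pools()$H1.3
  dip <- sample_diplotypes(pool, 1000, seed = 35)
  g <- genotypes_from_diplotypes(dip, pool)
  al <- subhapr:::pool_alleles(pool)
  hs <- em_haplotype_freqs(g$genotypes, block_id = "H1.3",
                           alleles = list(ref = al$ref, alt = al$alt))
  dos <- haplotype_dosages(hs, retained_only = FALSE)
  for (k in 1:4) {
    truth <- rowSums(matrix(dip %in% k, ncol = 2))
    lbl <- hs$haplotypes$label[hs$haplotypes$hap ==
                                 pool$haplotypes$hap[k]]
    expect_gt(cor(dos[, lbl], truth), 0.99)
  }
})

test_that("individuals with no block genotypes are excluded with a message", {
  g <- rbind(matrix(0L, 4, 3), NA, matrix(2L, 3, 3))
  rownames(g) <- sprintf("s%d", 1:8)
  expect_message(hs <- em_haplotype_freqs(g), "excluding 1")
  expect_identical(hs$excluded, "s5")
  expect_equal(length(hs$sample_ids), 7L)
})

test_that("tag-SNP clade calls follow HWE and flag missing genotypes", {
  co <- simulate_cohort(n = 4000, coupling = "clade", seed = 36)
  clades <- call_tag_snp_clades(co$genotypes, "tagH2")
  frac <- table(clades$clade) / nrow(clades)
  expect_lt(abs(frac[["H1/H1"]] - 0.64), 0.03)
  expect_lt(abs(frac[["H1/H2"]] - 0.32), 0.03)
  expect_lt(abs(frac[["H2/H2"]] - 0.04), 0.02)
  # all-reference cohort: everyone H1/H1
  g0 <- matrix(0L, 5, 1, dimnames = list(NULL, "tag"))
  expect_true(all(call_tag_snp_clades(g0, "tag")$clade == "H1/H1"))
  # missing tag genotype becomes NA with a message
  g0[2, 1] <- NA
  expect_message(cl <- call_tag_snp_clades(g0, "tag"), "missing tag")
  expect_true(is.na(cl$clade[2]))
})
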