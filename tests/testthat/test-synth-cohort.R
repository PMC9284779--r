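test_that("default pools match the published block structure", {
  pools <- build_default_pools()
  expect_named(pools, c("H1.1", "H1.2", "H1.3"))
  expect_equal(vapply(pools, function(p) length(p$positions), integer(1)),
               c(H1.1 = 5L, H1.2 = 8L, H1.3 = 9L))
  for (p in pools) expect_equal(sum(p$haplotypes$freq), 1, tolerance = 1e-12)
  # frequencies sum exactly for H1.1
  h11 <- pools$H1.1$haplotypes
  expect_identical(sum(c(0.25, 0.27, 0.18, 0.18, 0.12)), 1)
  # the strongest risk haplotype carries OR 2.51, the reference OR 1
  expect_equal(exp(h11$log_or[h11$hap == "ACCTG"]), 2.51)
  expect_equal(h11$log_or[h11$hap == "ACTCT"], 0)
  expect_equal(pools$H1.2$haplotypes$log_or[1], 0)
  expect_equal(pools$H1.3$haplotypes$log_or[1], 0)
  # positions live inside the published block spans
  expect_true(all(pools$H1.1$positions >= 44040184 &
                    pools$H1.1$positions <= 44041992))
  expect_true(all(pools$H1.3$positions >= 44119987 &
                    pools$H1.3$positions <= 44131305))
})

test_that("diplotype sampling is seed-deterministic and frequency-faithful", {
  pool <- build_default_pools()$H1.1
  expect_identical(sample_diplotypes(pool, 50, seed = 7),
                   sample_diplotypes(pool, 50, seed = 7))
  # degenerate single-haplotype pool
  solo <- hap_pool("solo", "1", c(10L, 20L),
                   tibble::tibble(hap = c("AC"), freq = 1))
  dip <- sample_diplotypes(solo, 10, seed = 1)
  expect_true(all(dip == 1L))
  # empirical chromosome frequencies within binomial error at 10,000 chrom
  dip <- sample_diplotypes(pool, 5000, seed = 11)
  emp <- tabulate(c(dip[, 1], dip[, 2]), 5) / 10000
  expect_true(all(abs(emp - pool$haplotypes$freq) <= 0.02))
})

test_that("case/control assignment follows the logistic dosage model", {
  pool <- toy_pool()
  dip <- sample_diplotypes(pool, 5000, seed = 2)
  # beta = 0, intercept 0 -> case fraction near 1/2
  st <- assign_case_control(dip, pool, baseline_logit = 0, seed = 3)
  expect_lt(abs(mean(st) - 0.5), 3 * sqrt(0.25 / 5000))
  # saturating effect: carriers essentially always cases
  hot <- pool
  hot$haplotypes$log_or <- c(0, 10)
  st2 <- assign_case_control(dip, hot, baseline_logit = 0, seed = 3)
  carrier <- dip[, 1] == 2L | dip[, 2] == 2L
  expect_gt(mean(st2[carrier]), 0.98)
  # unknown haplotype index rejected
  bad <- dip; bad[1, 1] <- 99L
  expect_error(assign_case_control(bad, pool), "not present")
})

test_that("genotyping noise injects the configured missing/error rates", {
  g <- matrix(rep(c(0L, 1L, 2L), length.out = 10000), ncol = 20)
  expect_identical(add_genotyping_noise(g, 0, 0), g)
  noisy <- add_genotyping_noise(g, missing_rate = 0.05, error_rate = 0,
                                seed = 5)
  expect_lt(abs(mean(is.na(noisy)) - 0.05), 0.01)
  # errors hit the configured fraction and stay valid genotypes
  err <- add_genotyping_noise(g, missing_rate = 0, error_rate = 0.5, seed = 5)
  expect_lt(abs(mean(err != g) - 0.5), 0.02)
  expect_true(all(err %in% 0:2))
  # a monomorphic column becomes polymorphic under error
  mono <- matrix(0L, 500, 1)
  poly <- add_genotyping_noise(mono, 0, 0.2, seed = 6)
  expect_gt(length(unique(as.vector(poly))), 1L)
})

test_that("quantitative trait is the planted affine function of dosage", {
  pool <- build_default_pools()$H1.1
  dip <- sample_diplotypes(pool, 300, seed = 4)
  # all effects equal, no noise -> constant
  flat <- pool; flat$haplotypes$trait_effect <- rep(1, 5)
  y0 <- simulate_quant_trait(dip, flat, noise_sd = 0, seed = 1)
  expect_equal(var(y0), 0)
  # effect on one haplotype only, no noise -> exact affine in its dosage
  solo <- flat; solo$haplotypes$trait_effect[3] <- 4.7
  y <- simulate_quant_trait(dip, solo, noise_sd = 0, seed = 1)
  dos <- rowSums(matrix(dip %in% 3, ncol = 2))
  expect_equal(y, 2 + (4.7 - 1) * dos)
})

test_that("copy-number trait is the diploid sum of per-haplotype copies", {
  pool <- build_default_pools()$H1.1
  dip <- sample_diplotypes(pool, 400, seed = 9)
  ones <- pool; ones$haplotypes$copy_number <- rep(1, 5)
  expect_equal(simulate_copy_number(dip, ones, noise_sd = 0), rep(2, 400))
  cn <- simulate_copy_number(dip, pool, noise_sd = 0)
  hom_c <- dip[, 1] == 3L & dip[, 2] == 3L     # GCCTG carries 2 copies
  expect_true(all(cn[hom_c] == 4))
  # group separation: protective homozygotes above non-carriers
  noisy <- simulate_copy_number(dip, pool, noise_sd = 0.2, seed = 2)
  non <- dip[, 1] != 3L & dip[, 2] != 3L
  expect_gt(mean(noisy[hom_c]), mean(noisy[non]))
})

test_that("simulated genotypes equal the allele sum of the true haplotypes", {
  co <- simulate_cohort(n = 200, missing_rate = 0, error_rate = 0, seed = 21)
  for (b in names(co$pools)) {
    bits <- subhapr:::pool_hap_bits(co$pools[[b]])
    members <- co$variants$id[co$variants$block_id %in% b]
    recon <- bits[co$diplotypes[[b]][, 1], ] + bits[co$diplotypes[[b]][, 2], ]
    expect_equal(unname(co$genotypes[, members]), unname(recon))
  }
})

test_that("clade coupling ties the tag SNP to block reference strings", {
  co <- simulate_cohort(n = 3000, coupling = "clade", seed = 31)
  tagg <- co$genotypes[, "tagH2"]
  # tag allele frequency ~0.2 and HWE-consistent homozygote fractions
  expect_lt(abs(mean(tagg) / 2 - 0.2), 0.02)
  # H2/H2 samples are reference-homozygous in every block
  h2hom <- tagg == 2L
  for (b in names(co$pools)) {
    ref_idx <- which.max(co$pools[[b]]$haplotypes$freq)
    expect_true(all(co$diplotypes[[b]][h2hom, ] == ref_idx))
  }
})
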