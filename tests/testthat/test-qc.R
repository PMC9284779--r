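test_that("call-rate filters apply the >= threshold on the stated axis", {
  g <- matrix(0L, 100, 5, dimnames = list(sprintf("s%d", 1:100),
                                          sprintf("v%d", 1:5)))
  g[, 2] <- 1L
  expect_equal(ncol(filter_variant_call_rate(g)$genotypes), 5L)
  # variant missing 3/100 -> rate 0.97 < 0.98 -> removed
  g2 <- g; g2[1:3, 4] <- NA
  out <- filter_variant_call_rate(g2, 0.98)
  expect_identical(out$removed, "v4")
  expect_equal(out$report$n_removed, 1L)
  # sample missing 5% of variants -> removed at 98%
  g3 <- matrix(0L, 10, 1000, dimnames = list(sprintf("s%d", 1:10), NULL))
  g3[, seq(2, 1000, 2)] <- 1L
  g3[7, 1:50] <- NA
  expect_identical(filter_sample_call_rate(g3, 0.98)$removed, "s7")
})

test_that("sample rates are computed after variant filters (order matters)", {
  # one terrible variant concentrates sample 1's missingness: filtering
  # variants first rescues the sample
  g <- matrix(0L, 20, 10, dimnames = list(sprintf("s%d", 1:20),
                                          sprintf("v%d", 1:10)))
  g[, seq(2, 10, 2)] <- 1L
  g[1:10, 1] <- NA          # v1 has 50% call rate
  g[1, 2] <- NA             # s1 additionally misses one good variant
  direct <- filter_sample_call_rate(g, 0.95)
  expect_true("s1" %in% direct$removed)
  chained <- qc_pipeline(g, call_rate = 0.98, maf = 0,
                         sample_call_rate = 0.95, hwe_alpha = 0)
  expect_true("s1" %in% rownames(chained$genotypes))
})

test_that("MAF filter counts non-missing chromosomes with >= semantics", {
  g <- matrix(0L, 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  g[, 2] <- rep(c(0L, 1L), 25)
  g[1, 3] <- 1L                       # 1 alt in 100 chromosomes: MAF 0.01
  out <- filter_maf(g, 0.01)
  expect_true("v1" %in% out$removed)   # monomorphic
  expect_true("v4" %in% out$removed)
  expect_false("v3" %in% out$removed)  # boundary kept
  # hand count: AA=90, Aa=9, aa=1 -> MAF 11/200
  g5 <- matrix(c(rep(0L, 90), rep(1L, 9), 2L), ncol = 1)
  expect_equal(unname(filter_maf(g5)$maf), 11 / 200)
})

test_that("HWE exact p-values equal the enumeration oracle", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe_exact(25, 50, 25),
               tolerance = 1e-12)
  # randomised agreement for n <= 200
  withr::with_seed(42, {
    for (r in 1:200) {
      n <- sample(5:200, 1)
      p <- runif(1, 0.05, 0.95)
      g <- sample(0:2, n, replace = TRUE, prob = c(p^2, 2 * p * (1 - p),
                                                   (1 - p)^2))
      cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
      expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                   oracle_hwe_exact(cnt[1], cnt[2], cnt[3]),
                   tolerance = 1e-12)
    }
  })
})

test_that("HWE p-values are super-uniform under the null", {
  # tail calibration: P(p <= 1e-4) <= 1e-4 over 1e5 HWE draws
  withr::with_seed(7, {
    n <- 100
    p <- 0.3
    gprob <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    draws <- stats::rmultinom(1e5, n, gprob)
    key <- paste(draws[1, ], draws[2, ], draws[3, ])
    tab <- table(key)
    uniq <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
    pv <- hwe_exact_test(uniq[, 1], uniq[, 2], uniq[, 3])
    rate <- sum(as.integer(tab)[pv <= 1e-4]) / 1e5
    expect_lte(rate, 1e-4 + 3 * sqrt(1e-4 / 1e5))
    # and the filter drops what the test flags
    g <- c(rep(0L, 30), rep(1L, 10), rep(2L, 60))
    flt <- filter_hwe(matrix(g, ncol = 1), alpha = 1e-2)
    expect_equal(ncol(flt$genotypes),
                 as.integer(hwe_exact_test(30, 10, 60) >= 1e-2))
  })
})

test_that("IBD moments recover self, unrelated and parent-offspring pairs", {
  pool_freqs <- withr::with_seed(10, runif(500, 0.2, 0.8))
  draw <- function(n) vapply(pool_freqs, function(p) rbinom(n, 2L, p),
                             integer(n))
  withr::with_seed(11, {
    g <- draw(20)
    rownames(g) <- sprintf("i%02d", 1:20)
    # self pair: Z2 = 1
    self <- estimate_ibd(rbind(g, g[1, , drop = FALSE]),
                         pairs = cbind(1, 21))
    expect_equal(self$z2, 1, tolerance = 1e-6)
    expect_equal(self$z0, 0, tolerance = 1e-6)
    expect_true(self$flagged)
    # unrelated pairs: mean Z0 near 1
    unrel <- estimate_ibd(g)
    expect_lt(abs(mean(unrel$z0) - 1), 0.1)
    # parent-offspring: one allele shared IBD everywhere -> PI_HAT ~ 0.5
    n_po <- 30
    po <- vapply(seq_along(pool_freqs), function(v) {
      p <- pool_freqs[v]
      pa <- rbinom(n_po, 1L, p) + rbinom(n_po, 1L, p)      # parent
      transmitted <- ifelse(pa == 2L, 1L,
                            ifelse(pa == 0L, 0L, rbinom(n_po, 1L, 0.5)))
      child <- transmitted + rbinom(n_po, 1L, p)
      pa * 10L + child    # pack both genotypes
    }, integer(n_po))
    parents <- po %/% 10L; children <- po %% 10L
    stacked <- rbind(parents, children)
    rownames(stacked) <- c(sprintf("p%d", 1:n_po), sprintf("c%d", 1:n_po))
    res <- estimate_ibd(stacked, pairs = cbind(1:n_po, n_po + 1:n_po))
    expect_lt(abs(mean(res$pi_hat) - 0.5), 0.05)
  })
})

test_that("PCA covariates separate planted subpopulations and are orthogonal", {
  withr::with_seed(12, {
    n_per <- 60; m <- 150
    f1 <- runif(m, 0.1, 0.9)
    f2 <- pmin(pmax(f1 + sample(c(-1, 1), m, TRUE) * 0.35, 0.02), 0.98)
    g <- rbind(
      vapply(f1, function(p) rbinom(n_per, 2L, p), integer(n_per)),
      vapply(f2, function(p) rbinom(n_per, 2L, p), integer(n_per)))
    rownames(g) <- sprintf("s%03d", seq_len(2 * n_per))
    pcs <- pca_covariates(g, k = 4)
    grp <- rep(c(0, 1), each = n_per)
    expect_gt(abs(cor(pcs$PC1, grp)), 0.9)
    sc <- as.matrix(pcs[, -1])
    gram <- crossprod(sc)
    expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
    # permutation equivariance
    perm <- sample(nrow(g))
    pcs2 <- pca_covariates(g[perm, ], k = 4)
    expect_equal(as.matrix(pcs2[, -1]), sc[perm, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
  })
})

test_that("INFO-score filter honours boundaries and absent columns", {
  vt <- tibble::tibble(id = c("a", "b", "c"), info = c(0.29, 0.3, 0.9))
  out <- filter_info_score(vt)
  expect_identical(out$removed, "a")
  expect_true("b" %in% out$variants$id)
  expect_warning(out2 <- filter_info_score(vt[, "id"]), "skipped")
  expect_equal(nrow(out2$variants), 3L)
})

test_that("the QC chain is idempotent on its own output", {
  co <- simulate_cohort(n = 300, missing_rate = 0.03, error_rate = 0.01,
                        seed = 13)
  once <- qc_pipeline(co$genotypes)
  twice <- qc_pipeline(once$genotypes)
  expect_identical(dim(twice$genotypes), dim(once$genotypes))
  expect_true(all(twice$report$n_removed == 0L))
})
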