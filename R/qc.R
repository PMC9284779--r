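#' Variant call-rate filter
#'
#' Retains variants whose non-missing genotype fraction is at least
#' `threshold` (default 98%, the pre-imputation convention).
#'
#' @param genotypes Sample-by-variant genotype matrix (0/1/2/NA).
#' @param threshold Minimum call rate in `(0, 1]`.
#' @return List with `genotypes` (filtered), `removed` (variant names) and
#'   `report` (one-row tibble).
#' @export
filter_variant_call_rate <- function(genotypes, threshold = 0.98) {
  assert_genotype_matrix(genotypes)
  assert_proportion(threshold, "threshold", allow_one = TRUE)
  if (ncol(genotypes) == 0L) abort("empty genotype matrix")
  rate <- colMeans(!is.na(genotypes))
  keep <- rate >= threshold
  list(genotypes = genotypes[, keep, drop = FALSE],
       removed = colnames(genotypes)[!keep],
       report = qc_report_row("variant_call_rate", threshold,
                              ncol(genotypes), sum(!keep), "variants"))
}

#' Minor-allele-frequency filter
#'
#' MAF is computed on non-missing chromosomes; variants with MAF below
#' `threshold` (default 1%) are removed. An all-missing variant has MAF 0
#' and is removed.
#'
#' @inheritParams filter_variant_call_rate
#' @param threshold Minimum MAF.
#' @return As [filter_variant_call_rate()], plus `maf` (named vector).
#' @export
filter_maf <- function(genotypes, threshold = 0.01) {
  assert_genotype_matrix(genotypes)
  n_called <- colSums(!is.na(genotypes))
  alt <- colSums(genotypes, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), 0)
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_called == 0] <- 0
  keep <- maf >= threshold
  list(genotypes = genotypes[, keep, drop = FALSE],
       removed = colnames(genotypes)[!keep], maf = maf,
       report = qc_report_row("maf", threshold, ncol(genotypes),
                              sum(!keep), "variants"))
}

#' Sample call-rate filter
#'
#' Row-wise analogue of [filter_variant_call_rate()]: removes samples whose
#' genotyping rate (over the variants present in the matrix, i.e. after any
#' variant filters) is below `threshold`.
#'
#' @inheritParams filter_variant_call_rate
#' @return List with `genotypes`, `removed` (sample names), `report`.
#' @export
filter_sample_call_rate <- function(genotypes, threshold = 0.98) {
  assert_genotype_matrix(genotypes)
  rate <- rowMeans(!is.na(genotypes))
  keep <- rate >= threshold
  list(genotypes = genotypes[keep, , drop = FALSE],
       removed = rownames(genotypes)[!keep],
       report = qc_report_row("sample_call_rate", threshold,
                              nrow(genotypes), sum(!keep), "samples"))
}

#' Imputation-quality (INFO score) filter
#'
#' Generic post-imputation filter: retains variants whose quality score is
#' at least `threshold` (default r^2 >= 0.3). When the score column is
#' absent the table passes through unchanged with a warning.
#'
#' @param variant_table Tibble of variants.
#' @param threshold Minimum score.
#' @param score_col Name of the score column.
#' @return List with `variants`, `removed` (ids) and `report`.
#' @export
filter_info_score <- function(variant_table, threshold = 0.3,
                              score_col = "info") {
  n0 <- nrow(variant_table)
  if (!score_col %in% names(variant_table)) {
    warn(sprintf("no `%s` column; INFO filter skipped", score_col))
    return(list(variants = variant_table, removed = character(0),
                report = qc_report_row("info_score", threshold, n0, 0L,
                                       "variants")))
  }
  keep <- variant_table[[score_col]] >= threshold
  list(variants = variant_table[keep, ],
       removed = variant_table$id[!keep],
       report = qc_report_row("info_score", threshold, n0, sum(!keep),
                              "variants"))
}

qc_report_row <- function(filter, threshold, n_in, n_removed, unit) {
  tibble::tibble(filter = filter, threshold = threshold, unit = unit,
                 n_in = as.integer(n_in), n_removed = as.integer(n_removed),
                 n_out = as.integer(n_in - n_removed))
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions given the allele
#' counts: the p-value is the sum of probabilities of heterozygote counts
#' whose conditional probability does not exceed that of the observed count
#' (two-sided by heterozygote probability). Monomorphic sites return p = 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major-hom, het, minor-hom in any
#'   orientation).
#' @return Exact p-value in `(0, 1]`. Vectorised over equal-length inputs.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  mapply(hwe_exact_one, n_aa, n_ab, n_bb, USE.NAMES = FALSE)
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) abort("genotype counts must be nonnegative")
  n <- n_aa + n_ab + n_bb
  if (n < 1) abort("at least one genotyped individual required")
  n1 <- 2L * n_aa + n_ab            # allele 1 count
  n2 <- 2L * n_bb + n_ab
  rare <- min(n1, n2)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- hwe_het_distribution(n, rare)
  obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# Conditional distribution of the heterozygote count given allele counts,
# by the stable mid-out recurrence; returns probabilities aligned with
# seq(rare %% 2, rare, by = 2).
hwe_het_distribution <- function(n, rare) {
  common <- 2L * n - rare
  hets <- seq(rare %% 2L, rare, by = 2L)
  k <- length(hets)
  # expected het count under HWE, snapped onto the parity lattice
  mid <- floor(rare * common / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  mid <- min(max(mid, hets[1]), rare)
  p <- numeric(k)
  i_mid <- match(mid, hets)
  p[i_mid] <- 1
  # going down: P(h-2)/P(h) = h*(h-1) / ((rare-h+2)*(common-h+2))
  if (i_mid > 1L) {
    for (i in seq(i_mid, 2L)) {
      h <- hets[i]
      p[i - 1L] <- p[i] * h * (h - 1) /
        ((rare - h + 2) * (common - h + 2))
    }
  }
  # going up: P(h+2)/P(h) = (rare-h)*(common-h) / ((h+2)*(h+1))
  if (i_mid < k) {
    for (i in seq(i_mid, k - 1L)) {
      h <- hets[i]
      p[i + 1L] <- p[i] * (rare - h) * (common - h) /
        ((h + 2) * (h + 1))
    }
  }
  p / sum(p)
}

#' Hardy-Weinberg filter across a genotype matrix
#'
#' @inheritParams filter_variant_call_rate
#' @param alpha Significance threshold; variants with exact HWE p below it
#'   are removed (default 1e-4, the pre-imputation convention; use 1e-6
#'   post-imputation).
#' @return List with `genotypes`, `removed`, `p` (named p-values), `report`.
#' @export
filter_hwe <- function(genotypes, alpha = 1e-4) {
  assert_genotype_matrix(genotypes)
  p <- apply(genotypes, 2L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_one(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  keep <- p >= alpha
  list(genotypes = genotypes[, keep, drop = FALSE],
       removed = colnames(genotypes)[!keep], p = p,
       report = qc_report_row("hwe_exact", alpha, ncol(genotypes),
                              sum(!keep), "variants"))
}

#' Run the standard variant/sample QC chain
#'
#' Applies, in order: variant call rate, MAF, sample call rate, HWE exact
#' filter — the order used for array genotype QC at this locus.
#'
#' @inheritParams filter_variant_call_rate
#' @param call_rate,maf,sample_call_rate,hwe_alpha Thresholds.
#' @return List with `genotypes` and the combined `report` tibble.
#' @export
qc_pipeline <- function(genotypes, call_rate = 0.98, maf = 0.01,
                        sample_call_rate = 0.98, hwe_alpha = 1e-4) {
  s1 <- filter_variant_call_rate(genotypes, call_rate)
  s2 <- filter_maf(s1$genotypes, maf)
  s3 <- filter_sample_call_rate(s2$genotypes, sample_call_rate)
  s4 <- filter_hwe(s3$genotypes, hwe_alpha)
  list(genotypes = s4$genotypes,
       report = dplyr::bind_rows(s1$report, s2$report, s3$report, s4$report))
}

#' Method-of-moments identity-by-descent estimation
#'
#' PLINK-style moment estimator: identity-by-state counts for each sample
#' pair are compared with their expectations under 0/1/2 alleles shared
#' identical by descent, computed from sample allele frequencies. Z
#' components are truncated to `[0, 1]` and renormalised;
#' `PI_HAT = Z1/2 + Z2`. Pairs with `Z0 <= 0.8` are flagged as relatives or
#' duplicates.
#'
#' @param genotypes Genotype matrix (ideally >= ~100 informative variants).
#' @param pairs Optional two-column matrix/data frame of sample names or
#'   indices; default all pairs.
#' @param flag_z0 Flagging threshold on Z0.
#' @return Tibble: id1, id2, n_snps, ibs0, ibs1, ibs2, z0, z1, z2, pi_hat,
#'   flagged.
#' @export
estimate_ibd <- function(genotypes, pairs = NULL, flag_z0 = 0.8) {
  assert_genotype_matrix(genotypes)
  n <- nrow(genotypes)
  ids <- rownames(genotypes) %||% as.character(seq_len(n))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) pairs <- matrix(match(pairs, ids), ncol = 2L)
  }
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  q <- 1 - p
  poly <- !is.na(p) & p > 0 & p < 1
  # per-locus expected IBS probabilities conditional on IBD state
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e2_z0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_z1 <- 2 * p^2 * q + 2 * p * q^2
  e2_z1 <- p^3 + q^3 + p^2 * q + p * q^2
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    gi <- genotypes[i, ]; gj <- genotypes[j, ]
    use <- poly & !is.na(gi) & !is.na(gj)
    L <- sum(use)
    if (L < 2L) abort("fewer than 2 informative overlapping variants for an IBD pair")
    d <- abs(gi[use] - gj[use])
    # both-het pairs are IBS2 regardless of phase
    n_ibs0 <- sum(d == 2L)
    n_ibs1 <- sum(d == 1L)
    n_ibs2 <- L - n_ibs0 - n_ibs1
    E0 <- sum(e0_z0[use]); E1a <- sum(e1_z0[use]); E2a <- sum(e2_z0[use])
    E1b <- sum(e1_z1[use]); E2b <- sum(e2_z1[use])
    z0 <- n_ibs0 / E0
    z1 <- (n_ibs1 - z0 * E1a) / E1b
    z2 <- (n_ibs2 - z0 * E2a - z1 * E2b) / L
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    z <- z / sum(z)
    tibble::tibble(id1 = ids[i], id2 = ids[j], n_snps = L,
                   ibs0 = n_ibs0, ibs1 = n_ibs1, ibs2 = n_ibs2,
                   z0 = z[1], z1 = z[2], z2 = z[3],
                   pi_hat = z[2] / 2 + z[3], flagged = z[1] <= flag_z0)
  })
  out
}

#' Principal-component covariates from genotypes
#'
#' Variants are standardised by mean `2p` and SD `sqrt(2p(1-p))` with
#' missing entries mean-imputed, and the top `k` sample scores of the SVD
#' are returned for use as ancestry covariates in association models. The
#' sign of each component is fixed so that its largest-magnitude variant
#' loading is positive.
#'
#' @param genotypes Genotype matrix.
#' @param k Number of components (default 10).
#' @return Tibble with `sample_id` and columns `PC1..PCk`.
#' @export
pca_covariates <- function(genotypes, k = 10) {
  assert_genotype_matrix(genotypes)
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1
  g <- genotypes[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(g, 2L, 2 * p, `-`)
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), `/`)
  z[is.na(z)] <- 0
  sv <- svd(z)
  avail <- sum(sv$d > max(dim(z)) * max(sv$d) * 1e-12)
  if (k > avail) {
    warn(sprintf("only %d non-null components available (requested %d)",
                 avail, k))
    k <- avail
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(scores, 2L, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(genotypes) %||%
                     as.character(seq_len(nrow(genotypes)))),
    tibble::as_tibble(scores))
}
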