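# Seeded simulation studies used to calibrate and validate the pipeline.
# Each study regenerates its cohorts from the pool definitions, runs the
# relevant pipeline stage, and summarises recovery/calibration; they back
# both the test suite and the reproducibility script.

#' Haplotype-frequency recovery study
#'
#' Samples cohorts from a pool, phases them with the block EM, and
#' measures the absolute frequency error of every true haplotype plus the
#' largest spurious (non-pool) haplotype frequency.
#'
#' @param pool A [hap_pool()].
#' @param n Individuals per cohort.
#' @param seeds Integer vector of seeds (one cohort each).
#' @param min_true_freq Only true haplotypes at or above this frequency
#'   enter the error summary.
#' @return Tibble: seed, max_abs_err (over true haplotypes >=
#'   `min_true_freq`), max_spurious (largest estimated frequency of a
#'   haplotype absent from the pool).
#' @export
em_recovery_study <- function(pool, n = 2000, seeds = 1:20,
                              min_true_freq = 0.05) {
  al <- pool_alleles(pool)
  purrr::map_dfr(seeds, function(s) {
    dip <- sample_diplotypes(pool, n, seed = s)
    geno <- genotypes_from_diplotypes(dip, pool)$genotypes
    hs <- em_haplotype_freqs(geno, block_id = pool$block_id,
                             alleles = list(ref = al$ref, alt = al$alt))
    est <- hs$haplotypes
    truth <- pool$haplotypes
    err <- abs(est$frequency[match(truth$hap, est$hap)] - truth$freq)
    err[is.na(err)] <- truth$freq[is.na(err)]   # unrecovered haplotype
    spur <- est$frequency[!est$hap %in% truth$hap]
    tibble::tibble(seed = s,
                   max_abs_err = max(err[truth$freq >= min_true_freq]),
                   max_spurious = if (length(spur)) max(spur) else 0)
  })
}

#' Block boundary recovery study
#'
#' Builds a region from two independent pools plus flanking
#' linkage-equilibrium SNPs, runs Gabriel block detection, and records
#' whether exactly the two generating blocks are recovered with their
#' exact boundaries.
#'
#' @param pool_a,pool_b Two [hap_pool()] objects.
#' @param n Individuals per cohort.
#' @param seeds Seeds (one region each).
#' @param n_flank Independent SNPs placed on each side of the two pools.
#' @return Tibble: seed, n_blocks, exact (both boundaries match).
#' @export
block_recovery_study <- function(pool_a = build_default_pools()$H1.1,
                                 pool_b = build_default_pools()$H1.3,
                                 n = 1000, seeds = 1:100, n_flank = 3) {
  purrr::map_dfr(seeds, function(s) {
    withr::with_seed(s, {
      ga <- genotypes_from_diplotypes(sample_diplotypes(pool_a, n), pool_a)
      gb <- genotypes_from_diplotypes(sample_diplotypes(pool_b, n), pool_b)
      # flanking / intervening SNPs in linkage equilibrium
      flank_pos <- list(
        before = min(pool_a$positions) - rev(seq_len(n_flank)) * 4000L,
        after = max(pool_b$positions) + seq_len(n_flank) * 4000L)
      flank <- lapply(unlist(flank_pos), function(p) {
        maf <- runif(1, 0.15, 0.5)
        matrix(rbinom(n, 2L, maf), ncol = 1)
      })
      flank_g <- do.call(cbind, flank)
      colnames(flank_g) <- sprintf("flank%02d", seq_along(unlist(flank_pos)))
      geno <- cbind(flank_g[, seq_len(n_flank), drop = FALSE],
                    ga$genotypes, gb$genotypes,
                    flank_g[, n_flank + seq_len(n_flank), drop = FALSE])
      pos <- c(flank_pos$before, pool_a$positions, pool_b$positions,
               flank_pos$after)
      ord <- order(pos)
      geno <- geno[, ord, drop = FALSE]
      pos <- pos[ord]
      blocks <- gabriel_blocks(geno, pos)
      want <- list(sort(colnames(ga$genotypes)), sort(colnames(gb$genotypes)))
      got <- lapply(blocks$members, sort)
      tibble::tibble(seed = s, n_blocks = nrow(blocks),
                     exact = nrow(blocks) == 2L &&
                       identical(got[[1]], want[[1]]) &&
                       identical(got[[2]], want[[2]]))
    })
  })
}

#' Type-I error calibration study
#'
#' Simulates null cohorts (all haplotype log ORs zero, status Bernoulli at
#' the baseline rate), phases each, and runs the block omnibus LRT and the
#' per-haplotype Wald tests; returns per-replicate p-values so empirical
#' rejection rates can be compared with the nominal level.
#'
#' @param pool Pool defining the block structure (effects are ignored).
#' @param n Individuals per replicate.
#' @param n_reps Replicates.
#' @param seed Master seed.
#' @return Tibble: rep, p_lrt, p_wald (first non-reference haplotype).
#' @export
type1_calibration_study <- function(pool = build_default_pools()$H1.1,
                                    n = 1000, n_reps = 1000, seed = 1L) {
  null_pool <- pool
  null_pool$haplotypes$log_or <- 0
  al <- pool_alleles(null_pool)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      dip <- sample_diplotypes(null_pool, n)
      status <- assign_case_control(dip, null_pool, baseline_logit = 0)
      geno <- genotypes_from_diplotypes(dip, null_pool)$genotypes
      hs <- em_haplotype_freqs(geno, block_id = "null",
                               alleles = list(ref = al$ref, alt = al$alt))
      hs <- prune_rare(hs)
      res <- block_association(hs, status)
      hap_rows <- res[res$type == "haplotype", ]
      tibble::tibble(rep = r,
                     p_lrt = res$p_lrt[res$type == "block"],
                     p_wald = hap_rows$p_wald[1])
    })
  })
}

#' Odds-ratio recovery study
#'
#' Plants the per-haplotype disease log ORs of the pools in retrospective
#' case-control cohorts of the given design, re-estimates each
#' sub-haplotype's odds ratio through the full phasing + chromosome-count
#' pathway, and reports the estimates next to the generating values.
#'
#' @param pools Pools carrying `log_or` effects.
#' @param n_cases,n_controls Stage design.
#' @param seeds Seeds (one stage each).
#' @param baseline_logit Disease intercept. The default -5 keeps even the
#'   highest-risk homozygotes (baseline + 2 log OR at OR 2.5) below ~4%
#'   disease probability, so the rare-disease approximation that ties
#'   chromosome-count ORs to the planted per-copy ORs holds across the
#'   whole planted OR range.
#' @return Tibble: seed, block_id, hap, true_or, est_or.
#' @export
or_recovery_study <- function(pools = build_default_pools(), n_cases = 2780,
                              n_controls = 6384, seeds = 1:50,
                              baseline_logit = -5) {
  purrr::map_dfr(seeds, function(s) {
    cohort <- simulate_stage(pools, n_cases = n_cases,
                             n_controls = n_controls,
                             baseline_logit = baseline_logit,
                             tag = NULL, seed = s)
    purrr::map_dfr(names(pools), function(b) {
      pool <- pools[[b]]
      al <- pool_alleles(pool)
      members <- cohort$variants$id[cohort$variants$block_id %in% b]
      sub <- cohort$genotypes[, members, drop = FALSE]
      hs <- em_haplotype_freqs(sub, block_id = b,
                               alleles = list(ref = al$ref, alt = al$alt))
      hs <- prune_rare(hs)
      # estimate against the generating reference haplotype (the one whose
      # planted log OR is 0); risk effects can promote another haplotype to
      # most-frequent in a case-enriched sample
      ref_hap <- pool$haplotypes$hap[which(pool$haplotypes$log_or == 0)[1]]
      ref_label <- hs$haplotypes$label[match(ref_hap, hs$haplotypes$hap)]
      res <- block_association(hs, cohort$samples$status,
                               reference = ref_label)
      hap_rows <- res[res$type == "haplotype", ]
      truth <- pool$haplotypes
      m <- match(hap_rows$unit,
                 hs$haplotypes$label[match(truth$hap, hs$haplotypes$hap)])
      tibble::tibble(seed = s, block_id = b,
                     hap = truth$hap[m], true_or = exp(truth$log_or[m]),
                     est_or = hap_rows$or)
    })
  })
}

#' Expression-trait pathway study
#'
#' Runs the full quantitative-trait pathway (simulate trait with planted
#' per-copy effects and covariates -> residualize -> z-score -> dosage
#' regression) and reports, per seed, the estimated coefficient and
#' p-value of each effect-carrying haplotype.
#'
#' @param pool Pool with `trait_effect` entries (default block H1.1, whose
#'   protective haplotypes carry 3-5 fold elevations).
#' @param n Individuals per dataset.
#' @param n_datasets Datasets combined after z-scoring.
#' @param seeds Seeds.
#' @param noise_sd Trait noise SD.
#' @return Tibble: seed, hap, true_effect, beta, p.
#' @export
trait_pathway_study <- function(pool = build_default_pools()$H1.1, n = 500,
                                n_datasets = 2, seeds = 1:25,
                                noise_sd = 1) {
  al <- pool_alleles(pool)
  coefs <- c(sex = 0.3, age = 0.02, pmi = -0.05, rin = 0.4)
  purrr::map_dfr(seeds, function(s) {
    withr::with_seed(s, {
      parts <- lapply(seq_len(n_datasets), function(d) {
        dip <- sample_diplotypes(pool, n)
        covar <- simulate_covariates(n)
        y <- simulate_quant_trait(dip, pool, covar, coefs, noise_sd)
        geno <- genotypes_from_diplotypes(dip, pool)$genotypes
        hs <- em_haplotype_freqs(geno, block_id = pool$block_id,
                                 alleles = list(ref = al$ref, alt = al$alt))
        hs <- prune_rare(hs)
        dos <- haplotype_dosages(hs)
        # key dosage columns by allele string: frequency-ranked labels can
        # differ between datasets, allele strings cannot
        colnames(dos) <- hs$haplotypes$hap[match(colnames(dos),
                                                 hs$haplotypes$label)]
        res <- residualize(y, covar)
        list(resid = res$residual, dosages = dos[res$row, , drop = FALSE])
      })
      z <- zscore_combine(setNames(lapply(parts, `[[`, "resid"),
                                   paste0("ds", seq_len(n_datasets))))
      haps <- Reduce(intersect, lapply(parts, function(p) colnames(p$dosages)))
      dos <- do.call(rbind, lapply(parts, function(p) p$dosages[, haps]))
      ref_hap <- pool$haplotypes$hap[which.max(pool$haplotypes$freq)]
      res <- subhap_trait_regression(z$z, dos, reference = ref_hap)
      res$true_effect <- pool$haplotypes$trait_effect[
        match(res$haplotype, pool$haplotypes$hap)]
      tibble::tibble(seed = s, haplotype = res$haplotype,
                     true_effect = res$true_effect,
                     beta = res$beta, p = res$p, r2 = res$r2)
    })
  })
}
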