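#' Sample diplotypes from a haplotype pool
#'
#' Draws unordered haplotype pairs i.i.d. from the pool frequencies
#' (random mating).
#'
#' @param pool A [hap_pool()].
#' @param n Number of individuals.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so that multi-block simulations drawing blocks sequentially stay
#'   reproducible under one outer seed).
#' @return Integer `n x 2` matrix of row indices into `pool$haplotypes`.
#' @export
sample_diplotypes <- function(pool, n, seed = NULL) {
  if (!inherits(pool, "hap_pool")) abort("`pool` must be a hap_pool")
  k <- nrow(pool$haplotypes)
  if (k < 1L) abort("empty haplotype pool")
  if (n < 1L) abort("`n` must be at least 1")
  with_seed_or_stream(seed, {
    idx <- sample.int(k, 2L * n, replace = TRUE, prob = pool$haplotypes$freq)
    matrix(idx, ncol = 2L)
  })
}

#' Assign case/control status under an additive-dosage logistic model
#'
#' Disease probability for an individual is
#' `plogis(baseline_logit + sum over blocks of log_or[h1] + log_or[h2])`,
#' the generative mirror of the additive logistic regression used for
#' analysis. Status is drawn Bernoulli.
#'
#' @param diplotypes A single `n x 2` diplotype index matrix or a list of
#'   them (one per block, row-aligned).
#' @param pools Matching [hap_pool()] or list of pools.
#' @param baseline_logit Disease intercept on the logit scale.
#' @param extra_logit Optional per-individual additional logit term (e.g. the
#'   H2 clade effect); recycled scalar or length-n vector.
#' @param seed Optional seed (see [sample_diplotypes()]).
#' @return Integer vector of 0 (control) / 1 (case).
#' @export
assign_case_control <- function(diplotypes, pools, baseline_logit = -4,
                                extra_logit = 0, seed = NULL) {
  if (is.matrix(diplotypes)) diplotypes <- list(diplotypes)
  if (inherits(pools, "hap_pool")) pools <- list(pools)
  if (length(diplotypes) != length(pools)) {
    abort("`diplotypes` and `pools` must have one element per block")
  }
  n <- nrow(diplotypes[[1]])
  eta <- rep(baseline_logit, n) + extra_logit
  for (b in seq_along(pools)) {
    lo <- pools[[b]]$haplotypes$log_or
    dip <- diplotypes[[b]]
    if (any(dip < 1L | dip > length(lo))) {
      abort("diplotype refers to a haplotype not present in its pool")
    }
    eta <- eta + lo[dip[, 1]] + lo[dip[, 2]]
  }
  with_seed_or_stream(seed, rbinom(n, 1L, stats::plogis(eta)))
}

#' Materialise unphased genotypes from diplotypes
#'
#' @param diplotypes `n x 2` index matrix from [sample_diplotypes()].
#' @param pool The generating [hap_pool()].
#' @return List with `genotypes` (n-by-site integer matrix of ALT dosages)
#'   and `variants` (tibble: id, chrom, pos, ref, alt, block_id).
#' @export
genotypes_from_diplotypes <- function(diplotypes, pool) {
  bits <- pool_hap_bits(pool)
  al <- pool_alleles(pool)
  g <- bits[diplotypes[, 1], , drop = FALSE] +
    bits[diplotypes[, 2], , drop = FALSE]
  storage.mode(g) <- "integer"
  variants <- tibble::tibble(
    id = sprintf("%s_s%02d", pool$block_id, seq_along(pool$positions)),
    chrom = pool$chrom, pos = pool$positions,
    ref = al$ref, alt = al$alt, block_id = pool$block_id
  )
  colnames(g) <- variants$id
  list(genotypes = g, variants = variants)
}

#' Inject missingness and genotyping error
#'
#' Each entry is independently set missing with probability `missing_rate`;
#' each remaining non-missing entry is perturbed with probability
#' `error_rate` by a symmetric single-step move to a different valid
#' genotype (0 -> 1, 2 -> 1, 1 -> 0 or 2 with equal probability).
#'
#' @param genotypes Integer genotype matrix (0/1/2/NA).
#' @param missing_rate,error_rate Proportions in `[0, 1)`.
#' @param seed Optional seed.
#' @return Matrix of the same shape.
#' @export
add_genotyping_noise <- function(genotypes, missing_rate = 0, error_rate = 0,
                                 seed = NULL) {
  assert_genotype_matrix(genotypes)
  assert_proportion(missing_rate, "missing_rate")
  assert_proportion(error_rate, "error_rate")
  if (missing_rate == 0 && error_rate == 0) return(genotypes)
  with_seed_or_stream(seed, {
    g <- genotypes
    nn <- length(g)
    if (missing_rate > 0) g[runif(nn) < missing_rate] <- NA_integer_
    if (error_rate > 0) {
      hit <- which(!is.na(g) & runif(nn) < error_rate)
      if (length(hit)) {
        cur <- g[hit]
        step <- ifelse(cur == 0L, 1L,
                       ifelse(cur == 2L, -1L,
                              sample(c(-1L, 1L), length(hit), replace = TRUE)))
        g[hit] <- cur + step
      }
    }
    g
  })
}

#' Simulate phenotype covariates
#'
#' Sex (0/1), age at death, post-mortem-interval and RNA-integrity analogues
#' with distributions typical of post-mortem brain cohorts.
#'
#' @param n Number of individuals.
#' @param seed Optional seed.
#' @return Tibble with columns `sex`, `age`, `pmi`, `rin`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  with_seed_or_stream(seed, tibble::tibble(
    sex = rbinom(n, 1L, 0.5),
    age = rnorm(n, 72, 9),
    pmi = pmax(rnorm(n, 12, 5), 0.5),
    rin = pmin(pmax(rnorm(n, 7, 1), 2), 10)
  ))
}

#' Simulate an expression-like quantitative trait
#'
#' `trait = sum_h trait_effect[h] * dosage[h] + covariates %*% coefs + noise`.
#' With the default pools, each reference haplotype copy contributes 1 raw
#' unit while protective haplotypes contribute 3-5 units, i.e. a 3-5 fold
#' per-copy elevation over the reference.
#'
#' @param diplotypes `n x 2` index matrix.
#' @param pool Generating [hap_pool()].
#' @param covariates Optional numeric data frame, row-aligned with
#'   `diplotypes`.
#' @param covariate_coefs Named numeric vector of covariate effects; names
#'   must exist in `covariates`.
#' @param noise_sd Gaussian noise standard deviation (raw trait scale).
#' @param seed Optional seed.
#' @return Numeric trait vector.
#' @export
simulate_quant_trait <- function(diplotypes, pool, covariates = NULL,
                                 covariate_coefs = NULL, noise_sd = 1,
                                 seed = NULL) {
  eff <- pool$haplotypes$trait_effect
  y <- eff[diplotypes[, 1]] + eff[diplotypes[, 2]]
  if (!is.null(covariates) && !is.null(covariate_coefs)) {
    if (nrow(covariates) != nrow(diplotypes)) {
      abort("`covariates` must be row-aligned with `diplotypes`")
    }
    miss <- setdiff(names(covariate_coefs), names(covariates))
    if (length(miss)) abort("unknown covariates: ", paste(miss, collapse = ", "))
    cm <- as.matrix(covariates[names(covariate_coefs)])
    y <- y + drop(cm %*% covariate_coefs)
  }
  with_seed_or_stream(seed, y + rnorm(length(y), 0, noise_sd))
}

#' Simulate a copy-number trait
#'
#' The noiseless value is the diploid sum of the two haplotypes' integer
#' copy contributions (`copy_number` column of the pool); Gaussian
#' measurement noise is added on top, mimicking digital-PCR copy calls.
#'
#' @inheritParams simulate_quant_trait
#' @param noise_sd Measurement noise SD (copies).
#' @return Numeric copy-number vector.
#' @export
simulate_copy_number <- function(diplotypes, pool, noise_sd = 0.2,
                                 seed = NULL) {
  cn <- pool$haplotypes$copy_number
  if (any(is.na(cn))) abort("pool lacks copy_number entries")
  y <- cn[diplotypes[, 1]] + cn[diplotypes[, 2]]
  with_seed_or_stream(seed, y + rnorm(length(y), 0, noise_sd))
}

#' Simulate a full case-control cohort
#'
#' Draws per-block diplotypes (independently across blocks by default, or
#' jointly with the inversion clade under `coupling = "clade"`), an H2-clade
#' tag SNP, case/control status under the additive logistic disease model,
#' covariates, quantitative traits, and the unphased genotype matrix with
#' optional missingness/error noise.
#'
#' Under clade coupling every chromosome first draws its clade (H2 with
#' probability `tag$h2_freq`); H2 chromosomes carry the block's reference
#' allele string and the tag SNP ALT allele, so the tag is perfectly
#' correlated with clade as at the real locus, while H1 chromosomes draw
#' sub-haplotypes from the pools renormalised within H1.
#'
#' @param pools List of [hap_pool()] objects (default [build_default_pools()]).
#' @param n Number of individuals.
#' @param baseline_logit Disease model intercept.
#' @param tag `NULL` to omit the clade tag SNP, otherwise [h2_tag_spec()].
#' @param coupling `"independent"` (blocks independent of each other and of
#'   the tag) or `"clade"` (joint clade draw described above).
#' @param missing_rate,error_rate Genotype noise rates.
#' @param trait_noise_sd,cn_noise_sd Trait noise SDs; traits are generated
#'   from the first pool whose haplotypes carry non-unit `trait_effect` /
#'   `copy_number` (the expression- and copy-number-bearing block).
#' @param seed Integer seed for the whole cohort.
#' @return A `sim_cohort` object: list with `genotypes`, `variants`,
#'   `samples` (sample_id, status + covariates), `traits`, `diplotypes`
#'   (per-block true diplotype matrices), `clades` (per-chromosome clade
#'   matrix) and `pools`.
#' @export
simulate_cohort <- function(pools = build_default_pools(), n = 1000,
                            baseline_logit = -4, tag = h2_tag_spec(),
                            coupling = c("independent", "clade"),
                            missing_rate = 0, error_rate = 0,
                            trait_noise_sd = 1, cn_noise_sd = 0.2,
                            seed = 1L) {
  coupling <- match.arg(coupling)
  if (inherits(pools, "hap_pool")) pools <- list(pools)
  if (is.null(names(pools)) || any(!nzchar(names(pools)))) {
    names(pools) <- vapply(pools, function(p) p$block_id, character(1))
  }
  withr::with_seed(as.integer(seed), {
    clades <- NULL
    if (!is.null(tag) && coupling == "clade") {
      clades <- matrix(rbinom(2L * n, 1L, tag$h2_freq), ncol = 2L)
    }
    dips <- lapply(pools, function(p) {
      dip <- sample_diplotypes(p, n)
      if (!is.null(clades)) {
        # H2 chromosomes carry the block reference string
        ref_idx <- which.max(p$haplotypes$freq)
        dip[, 1][clades[, 1] == 1L] <- ref_idx
        dip[, 2][clades[, 2] == 1L] <- ref_idx
      }
      dip
    })
    extra <- 0
    tag_geno <- NULL
    if (!is.null(tag)) {
      if (is.null(clades)) clades <- matrix(rbinom(2L * n, 1L, tag$h2_freq), ncol = 2L)
      tag_geno <- as.integer(clades[, 1] + clades[, 2])
      extra <- tag$h2_log_or * tag_geno
    }
    status <- assign_case_control(dips, pools, baseline_logit, extra_logit = extra)
    covar <- simulate_covariates(n)

    parts <- lapply(names(pools), function(b) genotypes_from_diplotypes(dips[[b]], pools[[b]]))
    geno <- do.call(cbind, lapply(parts, `[[`, "genotypes"))
    variants <- dplyr::bind_rows(lapply(parts, `[[`, "variants"))
    if (!is.null(tag_geno)) {
      geno <- cbind(geno, matrix(tag_geno, ncol = 1,
                                 dimnames = list(NULL, tag$id)))
      variants <- dplyr::bind_rows(
        variants,
        tibble::tibble(id = tag$id, chrom = tag$chrom, pos = tag$position,
                       ref = tag$ref, alt = tag$alt, block_id = NA_character_))
    }
    ord <- order(variants$pos)
    variants <- variants[ord, ]
    geno <- geno[, ord, drop = FALSE]
    geno <- add_genotyping_noise(geno, missing_rate, error_rate)

    sample_id <- sprintf("S%05d", seq_len(n))
    rownames(geno) <- sample_id

    expr_pool <- which(vapply(pools, function(p) any(p$haplotypes$trait_effect != 1), logical(1)))
    expr_pool <- if (length(expr_pool)) expr_pool[1] else 1L
    cn_pool <- which(vapply(pools, function(p) any(p$haplotypes$copy_number != 1), logical(1)))
    cn_pool <- if (length(cn_pool)) cn_pool[1] else 1L
    traits <- tibble::tibble(
      sample_id = sample_id,
      expression = simulate_quant_trait(
        dips[[expr_pool]], pools[[expr_pool]], covar,
        covariate_coefs = c(sex = 0.3, age = 0.02, pmi = -0.05, rin = 0.4),
        noise_sd = trait_noise_sd),
      copy_number = simulate_copy_number(dips[[cn_pool]], pools[[cn_pool]],
                                         noise_sd = cn_noise_sd)
    )

    structure(
      list(genotypes = geno, variants = variants,
           samples = dplyr::bind_cols(
             tibble::tibble(sample_id = sample_id, status = status), covar),
           traits = traits, diplotypes = dips, clades = clades,
           pools = pools, tag = tag),
      class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples (%d cases / %d controls), %d variants, %d blocks\n",
              nrow(x$genotypes), sum(x$samples$status == 1),
              sum(x$samples$status == 0), ncol(x$genotypes),
              length(x$pools)))
  invisible(x)
}

#' Resample a simulated population to fixed case/control counts
#'
#' Mimics a retrospective case-control design: keeps the first `n_cases`
#' cases and `n_controls` controls of the simulated population (draw order
#' is already random). Retrospective sampling leaves haplotype odds ratios
#' unbiased.
#'
#' @param cohort A `sim_cohort`.
#' @param n_cases,n_controls Target counts.
#' @return A `sim_cohort` restricted to the sampled individuals.
#' @export
resample_case_control <- function(cohort, n_cases, n_controls) {
  st <- cohort$samples$status
  cases <- which(st == 1L)
  controls <- which(st == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    abort(sprintf("population too small: %d cases / %d controls available",
                  length(cases), length(controls)))
  }
  keep <- sort(c(cases[seq_len(n_cases)], controls[seq_len(n_controls)]))
  subset_cohort(cohort, keep)
}

subset_cohort <- function(cohort, idx) {
  cohort$genotypes <- cohort$genotypes[idx, , drop = FALSE]
  cohort$samples <- cohort$samples[idx, ]
  cohort$traits <- cohort$traits[idx, ]
  cohort$diplotypes <- lapply(cohort$diplotypes, function(d) d[idx, , drop = FALSE])
  if (!is.null(cohort$clades)) cohort$clades <- cohort$clades[idx, , drop = FALSE]
  cohort
}

#' Simulate a retrospective case-control stage
#'
#' Simulates a population under the disease model and resamples it to fixed
#' case/control counts (e.g. 2,780 / 6,384 for a discovery stage). The
#' population size grows automatically until enough cases are available.
#'
#' @inheritParams simulate_cohort
#' @param n_cases,n_controls Target design counts.
#' @return A `sim_cohort` with exactly the requested counts.
#' @export
simulate_stage <- function(pools = build_default_pools(), n_cases = 2780,
                           n_controls = 6384, baseline_logit = -4,
                           tag = h2_tag_spec(),
                           coupling = "independent",
                           missing_rate = 0, error_rate = 0, seed = 1L) {
  # expected case rate under the generative model, used to size the draw
  p_case <- mean(stats::plogis(baseline_logit +
    Reduce(`+`, lapply(pools, function(p) {
      f <- p$haplotypes$freq
      2 * sum(f * p$haplotypes$log_or)
    }))))
  n_pop <- ceiling(max(n_cases / max(p_case, 1e-3), n_controls / 0.5) * 1.35)
  for (attempt in 1:4) {
    cohort <- simulate_cohort(pools, n = n_pop, baseline_logit = baseline_logit,
                              tag = tag, coupling = coupling,
                              missing_rate = missing_rate,
                              error_rate = error_rate, seed = seed)
    st <- cohort$samples$status
    if (sum(st == 1L) >= n_cases && sum(st == 0L) >= n_controls) {
      return(resample_case_control(cohort, n_cases, n_controls))
    }
    n_pop <- ceiling(n_pop * 1.6)
  }
  abort("could not accumulate the requested case/control counts")
}
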