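#' Additive logistic association for one dosage
#'
#' Fits `status ~ dosage + covariates` by maximum likelihood (IRLS via
#' [stats::glm()]) and reports the Wald log-OR, SE, 95% CI and p-value.
#' Non-convergence and (quasi-)separation are flagged in the result rather
#' than silently returned.
#'
#' @param dosage Numeric vector in `[0, 2]`.
#' @param status Binary 0/1 vector.
#' @param covariates Optional numeric data frame (e.g. principal
#'   components).
#' @param unit_id Label for the tested unit.
#' @return One-row tibble: unit, type, beta, se, or, ci_low, ci_high,
#'   p_wald, n_case, n_control, converged, separation.
#' @export
logistic_additive <- function(dosage, status, covariates = NULL,
                              unit_id = "dosage") {
  if (length(unique(status[!is.na(status)])) != 2L) {
    abort("`status` must contain both cases and controls")
  }
  if (var(dosage, na.rm = TRUE) == 0) abort("zero-variance dosage")
  df <- data.frame(status = status, dosage = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(glm(status ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  b <- sm["dosage", 1]; se <- sm["dosage", 2]
  separation <- !fit$converged || abs(b) > 10 || se > 100
  tibble::tibble(
    unit = unit_id, type = "haplotype",
    beta = b, se = se, or = exp(b),
    ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
    p_wald = sm["dosage", 4],
    n_case = sum(status == 1L), n_control = sum(status == 0L),
    converged = fit$converged, separation = separation
  )
}

#' Block omnibus likelihood-ratio test
#'
#' Tests all non-reference haplotype dosages of a block jointly: the full
#' logistic model (dosages + covariates) against the covariates-only null,
#' with one degree of freedom per non-aliased dosage column. The reference
#' (most common) haplotype must already be excluded from `dosage_matrix` to
#' avoid the rows-sum-to-2 collinearity.
#'
#' @param dosage_matrix Individual-by-haplotype dosage matrix excluding the
#'   reference column.
#' @param status Binary 0/1 vector.
#' @param covariates Optional numeric data frame.
#' @param unit_id Block label.
#' @return One-row tibble: unit, type, df, lrt_stat, p_lrt, n_case,
#'   n_control, dropped (aliased columns).
#' @export
block_omnibus_test <- function(dosage_matrix, status, covariates = NULL,
                               unit_id = "block") {
  dm <- as.matrix(dosage_matrix)
  if (ncol(dm) < 1L) abort("omnibus test undefined: no non-reference haplotypes")
  base <- data.frame(status = status)
  if (!is.null(covariates)) base <- cbind(base, as.data.frame(covariates))
  full_df <- cbind(base, as.data.frame(dm))
  fit0 <- suppressWarnings(glm(status ~ ., data = base, family = binomial()))
  fit1 <- suppressWarnings(glm(status ~ ., data = full_df, family = binomial()))
  aliased <- names(which(is.na(coef(fit1))))
  dropped <- intersect(aliased, colnames(dm))
  df_test <- ncol(dm) - length(dropped)
  if (df_test < 1L) abort("omnibus test undefined after dropping aliased columns")
  if (length(dropped)) {
    inform(sprintf("dropped aliased dosage column(s): %s",
                   paste(dropped, collapse = ", ")))
  }
  stat <- fit0$deviance - fit1$deviance
  tibble::tibble(
    unit = unit_id, type = "block", df = df_test,
    lrt_stat = stat, p_lrt = pchisq(stat, df_test, lower.tail = FALSE),
    n_case = sum(status == 1L), n_control = sum(status == 0L),
    dropped = list(dropped)
  )
}

#' Sub-haplotype odds ratio with Fisher exact p-value
#'
#' Compares chromosome-level counts of a target haplotype against the
#' reference haplotype between cases and controls: sample (Wald) OR with
#' 95% CI from `log OR +/- 1.96 * sqrt(sum of 1/cell)`, and a two-sided
#' Fisher exact p-value from the 2x2 table. A zero cell triggers the
#' Haldane-Anscombe 0.5 correction for the OR and CI (flagged); the Fisher
#' p-value is computed on the uncorrected counts.
#'
#' @param target_case,target_control Chromosome counts of the target
#'   haplotype in cases/controls.
#' @param ref_case,ref_control Chromosome counts of the reference
#'   haplotype.
#' @param unit_id Haplotype label.
#' @return One-row tibble: unit, type, beta, se, or, ci_low, ci_high,
#'   p_fisher, corrected.
#' @export
haplotype_or_fisher <- function(target_case, target_control,
                                ref_case, ref_control,
                                unit_id = "haplotype") {
  cells <- c(target_case, target_control, ref_case, ref_control)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("chromosome counts must be nonnegative integers")
  }
  tab <- matrix(c(target_case, ref_case, target_control, ref_control), 2L)
  p <- fisher.test(tab)$p.value
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  b <- log(cc[1] * cc[4] / (cc[2] * cc[3]))
  se <- sqrt(sum(1 / cc))
  tibble::tibble(
    unit = unit_id, type = "haplotype", beta = b, se = se, or = exp(b),
    ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
    p_fisher = min(p, 1), corrected = corrected
  )
}

#' Benjamini-Hochberg FDR q-values
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Step-up q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Full case-control association for one phased block
#'
#' Combines the block-level omnibus likelihood-ratio test with
#' per-sub-haplotype results against the most common (reference) retained
#' haplotype: chromosome-count odds ratios with Fisher exact p-values, and
#' additive logistic Wald statistics on expected dosages with optional
#' covariates.
#'
#' @param hapset A `hap_set` (after [prune_rare()]).
#' @param status Binary 0/1 vector aligned with the hap_set samples.
#' @param covariates Optional numeric data frame (e.g. 10 PCs).
#' @param reference Reference haplotype label; default the most frequent
#'   retained haplotype.
#' @return A `hap_assoc` tibble with one row per non-reference haplotype
#'   plus one block row carrying the omnibus LRT.
#' @export
block_association <- function(hapset, status, covariates = NULL,
                              reference = NULL) {
  dos <- haplotype_dosages(hapset)
  haps <- hapset$haplotypes[hapset$haplotypes$retained, ]
  if (is.null(reference)) reference <- haps$label[which.max(haps$frequency)]
  if (!reference %in% colnames(dos)) abort("reference haplotype not retained")
  targets <- setdiff(colnames(dos), reference)
  if (!length(targets)) abort("block has a single retained haplotype; nothing to test")

  case <- status == 1L
  chrom_counts <- function(lbl, grp) as.integer(round(sum(dos[grp, lbl])))
  rows <- purrr::map_dfr(targets, function(lbl) {
    orf <- haplotype_or_fisher(chrom_counts(lbl, case), chrom_counts(lbl, !case),
                               chrom_counts(reference, case),
                               chrom_counts(reference, !case), unit_id = lbl)
    lg <- logistic_additive(dos[, lbl], status, covariates, unit_id = lbl)
    orf$p_wald <- lg$p_wald
    orf$beta_logistic <- lg$beta
    orf$se_logistic <- lg$se
    orf$separation <- lg$separation
    orf
  })
  omni <- block_omnibus_test(dos[, targets, drop = FALSE], status, covariates,
                             unit_id = hapset$block_id)
  rows$block_id <- hapset$block_id
  rows$reference <- reference
  rows$frequency <- haps$frequency[match(rows$unit, haps$label)]
  omni$block_id <- hapset$block_id
  omni$reference <- reference
  out <- dplyr::bind_rows(rows, omni)
  class(out) <- c("hap_assoc", class(out))
  out
}

#' Subset a cohort to one clade stratum
#'
#' Restricts a simulated or loaded cohort to samples homozygous for a
#' clade at the tag SNP (e.g. H1/H1 only), so downstream association is
#' run within the major clade.
#'
#' @param cohort A `sim_cohort` (or any list with `genotypes` and
#'   row-aligned `samples`).
#' @param tag_variant Tag SNP column name.
#' @param stratum Clade diplotype to keep (default `"H1/H1"`).
#' @return The subset cohort.
#' @export
stratified_subset <- function(cohort, tag_variant, stratum = "H1/H1") {
  clades <- call_tag_snp_clades(cohort$genotypes, tag_variant)
  keep <- which(!is.na(clades$clade) & clades$clade == stratum)
  if (!length(keep)) abort(sprintf("no samples in stratum %s", stratum))
  subset_cohort(cohort, keep)
}
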