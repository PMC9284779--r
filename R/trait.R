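#' Residualize a trait on covariates
#'
#' Ordinary-least-squares residuals of `trait ~ covariates` (with
#' intercept). Rows with missing trait or covariates are dropped with a
#' message; residuals are orthogonal to the covariates and the intercept.
#'
#' @param trait Numeric vector.
#' @param covariates Data frame of covariates (e.g. sex, age, PMI, RIN).
#' @return Tibble: row (original index), residual.
#' @export
residualize <- function(trait, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(trait)) {
    abort("`covariates` must be row-aligned with `trait`")
  }
  ok <- !is.na(trait) & complete.cases(covariates)
  if (!all(ok)) {
    inform(sprintf("dropping %d incomplete row(s)", sum(!ok)))
  }
  fit <- lm(trait[ok] ~ ., data = covariates[ok, , drop = FALSE])
  tibble::tibble(row = which(ok), residual = unname(resid(fit)))
}

#' Z-score per dataset and combine
#'
#' Standardises each dataset's residuals to mean 0 and SD 1 (denominator
#' `n - 1`) and concatenates them; the combined vector is not
#' re-standardised.
#'
#' @param residuals_by_dataset Named list of numeric vectors (one per
#'   dataset, each with at least 3 values).
#' @return Tibble: dataset, z.
#' @export
zscore_combine <- function(residuals_by_dataset) {
  if (!length(residuals_by_dataset)) abort("need at least one dataset")
  purrr::imap_dfr(residuals_by_dataset, function(x, nm) {
    if (length(x) < 3L) abort(sprintf("dataset %s has fewer than 3 samples", nm))
    tibble::tibble(dataset = nm, z = as.numeric(scale(x)))
  })
}

#' Sub-haplotype quantitative-trait regression
#'
#' Joint linear model of a (residualised, z-scored) trait on the
#' non-reference sub-haplotype dosages; per-haplotype coefficients are the
#' contrasts against the reference haplotype, with two-sided t-test
#' p-values and the overall model R^2. Collinear dosage columns are
#' dropped with a message.
#'
#' @param z_trait Numeric trait vector.
#' @param dosage_matrix Individual-by-haplotype dosage matrix (from
#'   [haplotype_dosages()]).
#' @param reference Reference haplotype label; default the column with the
#'   largest mean dosage.
#' @param trait_name Label for the trait.
#' @return A `trait_assoc` tibble: trait, haplotype, reference, beta, se,
#'   p, r2, n.
#' @export
subhap_trait_regression <- function(z_trait, dosage_matrix, reference = NULL,
                                    trait_name = "trait") {
  dm <- as.matrix(dosage_matrix)
  if (nrow(dm) != length(z_trait)) {
    abort("`dosage_matrix` must be row-aligned with the trait")
  }
  if (is.null(reference)) reference <- colnames(dm)[which.max(colMeans(dm))]
  targets <- setdiff(colnames(dm), reference)
  if (!length(targets)) abort("no non-reference haplotypes to test")
  df <- as.data.frame(dm[, targets, drop = FALSE])
  fit <- lm(z_trait ~ ., data = df)
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased)) {
    inform(sprintf("dropped aliased dosage column(s): %s",
                   paste(gsub("`", "", aliased), collapse = ", ")))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  rows <- rownames(ct)[-1]
  out <- tibble::tibble(
    trait = trait_name,
    haplotype = gsub("`", "", rows),
    reference = reference,
    beta = ct[-1, 1], se = ct[-1, 2], p = ct[-1, 4],
    r2 = sm$r.squared, n = length(fit$residuals)
  )
  class(out) <- c("trait_assoc", class(out))
  out
}

#' Poisson copy-number quantification for digital PCR
#'
#' Standard partition-Poisson quantification: the mean molecules per
#' partition is `lambda = -ln(1 - positives/total)`, and the target copy
#' number per genome is `reference_copies * lambda_target /
#' lambda_reference`. A saturated target (all partitions positive) cannot
#' be quantified.
#'
#' @param target,reference Lists or one-row data frames with `positives`
#'   and `total` partition counts.
#' @param reference_copies Copies per genome of the reference locus
#'   (default 2).
#' @return Tibble: lambda_target, lambda_reference, copies.
#' @export
dpcr_copy_number <- function(target, reference, reference_copies = 2) {
  lam <- function(x, nm) {
    pos <- x$positives; tot <- x$total
    if (pos < 0 || tot <= 0 || pos > tot) {
      abort(sprintf("invalid partition counts for %s", nm))
    }
    if (pos == tot) abort(sprintf("%s assay saturated: cannot quantify", nm))
    -log(1 - pos / tot)
  }
  lt <- lam(target, "target")
  lr <- lam(reference, "reference")
  if (lr <= 0) abort("reference assay has no positive partitions")
  tibble::tibble(lambda_target = lt, lambda_reference = lr,
                 copies = reference_copies * lt / lr)
}
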