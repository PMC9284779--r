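#' Log odds ratio and standard error from a published OR and CI
#'
#' Recovers summary inputs from a printed odds ratio with 95% confidence
#' interval: `b = ln(OR)`, `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`.
#'
#' @param or,ci_low,ci_high Positive odds ratio and CI bounds with
#'   `ci_low <= or <= ci_high`.
#' @return Tibble: b, se.
#' @export
logor_from_or_ci <- function(or, ci_low, ci_high) {
  if (any(c(or, ci_low, ci_high) <= 0)) abort("OR and CI bounds must be positive")
  if (any(ci_low > or | or > ci_high)) abort("need ci_low <= or <= ci_high")
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.959964)
  if (any(se <= 0)) abort("degenerate interval: se must be positive")
  tibble::tibble(b = log(or), se = se)
}

#' Build a study-effect table
#'
#' @param label Study labels.
#' @param b Log odds ratios.
#' @param se Standard errors (positive).
#' @return A `study_effects` tibble with inverse-variance weights.
#' @export
study_effects <- function(label, b, se) {
  if (any(se <= 0)) abort("standard errors must be positive")
  out <- tibble::tibble(label = label, b = b, se = se, w = 1 / se^2)
  class(out) <- c("study_effects", class(out))
  out
}

meta_result_row <- function(method, b, se, k, Q, tau2 = 0) {
  q_df <- max(k - 1L, 0L)
  tibble::tibble(
    method = method, k = k, b = b, se = se, or = exp(b),
    ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
    p = 2 * pnorm(-abs(b / se)),
    Q = Q, q_df = q_df,
    q_p = if (q_df > 0) pchisq(Q, q_df, lower.tail = FALSE) else NA_real_,
    tau2 = tau2
  )
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-study log odds ratios with weights `w = 1/se^2`:
#' `b = sum(w*b)/sum(w)`, `se = 1/sqrt(sum(w))`, heterogeneity
#' `Q = sum(w * (b_i - b)^2)`.
#'
#' @param studies A `study_effects` tibble (or anything with columns `b`,
#'   `se`).
#' @return A `meta_result` tibble (one row, method `"FE-IV"`).
#' @export
fixed_effects_iv <- function(studies) {
  w <- 1 / studies$se^2
  b <- sum(w * studies$b) / sum(w)
  Q <- sum(w * (studies$b - b)^2)
  out <- meta_result_row("FE-IV", b, 1 / sqrt(sum(w)), nrow(studies), Q)
  class(out) <- c("meta_result", class(out))
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` from the
#' fixed-effects Q; random-effects weights `1/(se^2 + tau2)`; pooled
#' estimate and CI as inverse-variance with those weights. With a single
#' study the fixed-effects result is returned with a warning. When
#' `Q <= k - 1`, `tau2` truncates to 0 and the result equals FE-IV.
#'
#' @inheritParams fixed_effects_iv
#' @return A `meta_result` tibble (method `"RE-DL"`).
#' @export
dersimonian_laird <- function(studies) {
  k <- nrow(studies)
  fe <- fixed_effects_iv(studies)
  if (k < 2L) {
    warn("single study: returning fixed-effects result")
    fe$method <- "RE-DL"
    return(fe)
  }
  w <- 1 / studies$se^2
  tau2 <- max(0, (fe$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (studies$se^2 + tau2)
  b <- sum(wr * studies$b) / sum(wr)
  out <- meta_result_row("RE-DL", b, 1 / sqrt(sum(wr)), k, fe$Q, tau2)
  class(out) <- c("meta_result", class(out))
  out
}

#' Cochran's Q heterogeneity test
#'
#' @inheritParams fixed_effects_iv
#' @return Tibble: Q, df, p (chi-square upper tail at k-1 df).
#' @export
cochran_q <- function(studies) {
  if (nrow(studies) < 2L) abort("heterogeneity needs at least 2 studies")
  fe <- fixed_effects_iv(studies)
  tibble::tibble(Q = fe$Q, df = fe$q_df, p = fe$q_p)
}

#' Mantel-Haenszel fixed-effects pooling of 2x2 tables
#'
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over strata
#' `(a, b, c, d)` = (case-exposed, case-unexposed, control-exposed,
#' control-unexposed), with the Robins-Breslow-Greenland variance for the
#' CI.
#'
#' @param tables Data frame or tibble with columns `a`, `b`, `c`, `d` (one
#'   row per stratum).
#' @return A `meta_result` tibble (method `"FE-MH"`).
#' @export
mantel_haenszel <- function(tables) {
  a <- tables$a; b <- tables$b; cc <- tables$c; d <- tables$d
  if (any(c(a, b, cc, d) < 0)) abort("counts must be nonnegative")
  n <- a + b + cc + d
  R <- a * d / n
  S <- b * cc / n
  if (sum(R) == 0 || sum(S) == 0) abort("Mantel-Haenszel OR undefined (zero margin)")
  or_mh <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log OR_MH
  P <- (a + d) / n
  Qv <- (b + cc) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Qv * R) / (2 * sum(R) * sum(S)) +
    sum(Qv * S) / (2 * sum(S)^2)
  bhat <- log(or_mh)
  se <- sqrt(var_log)
  # heterogeneity via Woolf per-stratum log ORs (0.5 correction on zeros)
  corr <- t(apply(cbind(a, b, cc, d), 1L, function(x)
    if (any(x == 0)) x + 0.5 else x))
  bi <- log(corr[, 1] * corr[, 4] / (corr[, 2] * corr[, 3]))
  wi <- 1 / rowSums(1 / corr)
  Q <- sum(wi * (bi - sum(wi * bi) / sum(wi))^2)
  out <- meta_result_row("FE-MH", bhat, se, nrow(tables), Q)
  class(out) <- c("meta_result", class(out))
  out
}

#' Two-stage meta-analysis of association tables
#'
#' Joins per-unit association results from two stages by unit id and pools
#' the log odds ratios by inverse-variance fixed effects and
#' DerSimonian-Laird random effects. Units present in only one stage are
#' reported unpooled with `pooled = FALSE`.
#'
#' @param results_a,results_b `hap_assoc` tibbles (or any tables with
#'   columns `unit`, `beta`, `se`).
#' @return Tibble keyed by unit: fe_or, fe_ci_low, fe_ci_high, fe_p, re_or,
#'   re_ci_low, re_ci_high, re_p, Q, q_p, tau2, pooled.
#' @export
run_meta <- function(results_a, results_b) {
  ha <- dplyr::filter(results_a, .data$type == "haplotype")
  hb <- dplyr::filter(results_b, .data$type == "haplotype")
  units <- union(ha$unit, hb$unit)
  purrr::map_dfr(units, function(u) {
    ra <- ha[ha$unit == u, ]; rb <- hb[hb$unit == u, ]
    if (nrow(ra) == 0L || nrow(rb) == 0L) {
      one <- if (nrow(ra)) ra else rb
      return(tibble::tibble(unit = u, pooled = FALSE,
                            fe_or = one$or, fe_ci_low = one$ci_low,
                            fe_ci_high = one$ci_high, fe_p = NA_real_,
                            re_or = NA_real_, re_ci_low = NA_real_,
                            re_ci_high = NA_real_, re_p = NA_real_,
                            Q = NA_real_, q_p = NA_real_, tau2 = NA_real_))
    }
    st <- study_effects(c("A", "B"), c(ra$beta, rb$beta), c(ra$se, rb$se))
    fe <- fixed_effects_iv(st)
    re <- dersimonian_laird(st)
    tibble::tibble(unit = u, pooled = TRUE,
                   fe_or = fe$or, fe_ci_low = fe$ci_low,
                   fe_ci_high = fe$ci_high, fe_p = fe$p,
                   re_or = re$or, re_ci_low = re$ci_low,
                   re_ci_high = re$ci_high, re_p = re$p,
                   Q = fe$Q, q_p = fe$q_p, tau2 = re$tau2)
  })
}
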