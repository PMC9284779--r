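#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a phased haplotype set
#'
#' @param x A `hap_set`.
#' @param ... Ignored.
#' @return Tibble: block_id, hap, label, frequency, retained.
#' @export
tidy.hap_set <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(block_id = x$block_id), x$haplotypes)
}

#' One-row EM fit summary for a haplotype set
#'
#' @param x A `hap_set`.
#' @param ... Ignored.
#' @return Tibble: block_id, n_samples, n_markers, n_haplotypes,
#'   n_retained, loglik, n_iter, converged.
#' @export
glance.hap_set <- function(x, ...) {
  tibble::tibble(
    block_id = x$block_id, n_samples = length(x$sample_ids),
    n_markers = x$n_markers, n_haplotypes = nrow(x$haplotypes),
    n_retained = sum(x$haplotypes$retained),
    loglik = x$loglik[length(x$loglik)],
    n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy a meta-analysis result
#'
#' @param x A `meta_result`.
#' @param ... Ignored.
#' @return The estimate row as a plain tibble (method, k, b, se, or, CI,
#'   p).
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::as_tibble(x)[c("method", "k", "b", "se", "or", "ci_low",
                         "ci_high", "p")]
}

#' Heterogeneity summary of a meta-analysis result
#'
#' @param x A `meta_result`.
#' @param ... Ignored.
#' @return Tibble: method, k, Q, q_df, q_p, tau2.
#' @export
glance.meta_result <- function(x, ...) {
  tibble::as_tibble(x)[c("method", "k", "Q", "q_df", "q_p", "tau2")]
}
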