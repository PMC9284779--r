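#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rbinom rnorm runif coef glm lm pchisq pnorm qnorm
#'   binomial complete.cases fisher.test p.adjust quantile resid sd var
#'   setNames residuals logLik
#' @importFrom utils head
NULL

# Run `code` under a temporary RNG state when `seed` is given; under the
# current stream when it is NULL. Keeps low-level generators composable
# inside a seeded pipeline without clobbering the caller's RNG.
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_proportion <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a single proportion in [0, 1%s", name,
                  if (allow_one) "]" else ")"))
  }
  invisible(x)
}

# Genotype matrices are integer sample-by-variant matrices with values
# 0/1/2 (ALT allele count) and NA for missing calls.
assert_genotype_matrix <- function(g) {
  if (!is.matrix(g) || !(is.numeric(g) || is.integer(g))) {
    abort("genotypes must be a numeric sample-by-variant matrix")
  }
  bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
  if (any(bad)) abort("genotype values must be 0, 1, 2 or NA")
  invisible(g)
}

label_series <- function(n) {
  base <- letters
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- as.vector(t(outer(letters, letters, paste0)))
  c(base, extra)[seq_len(n)]
}
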