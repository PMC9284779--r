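#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased
#' genotypes at a pair of biallelic variants. Only the double-heterozygote
#' class is phase-ambiguous; the EM splits it between the two resolutions
#' until the largest frequency change is below `tol`. Marginal allele
#' frequencies are preserved exactly by construction.
#'
#' Haplotype labels use allele "A"/"B" for the REF (0-coded) allele at the
#' first/second locus, so `pAB` is the frequency of the doubly-REF
#' haplotype.
#'
#' @param g1,g2 Genotype vectors (0/1/2/NA ALT dosages), equal length.
#' @param tol Convergence tolerance on haplotype frequencies.
#' @param max_iter Iteration cap.
#' @return List with `freqs` (named: pAB, pAb, paB, pab), `n` (individuals
#'   used), `n_iter`, `loglik` (per-iteration trace, non-decreasing) and
#'   `counts` (the 3x3 genotype table).
#' @export
two_locus_em <- function(g1, g2, tol = 1e-6, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2L) abort("fewer than 2 informative samples")
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  # unambiguous haplotype counts; A/B = REF allele (coded 0)
  cAB <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  cAb <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  caB <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]
  cab <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  nd <- tab[2, 2]                       # double heterozygotes
  tot <- 2 * n
  f <- c(cAB, cAb, caB, cab) + nd / 2   # start: split double hets evenly
  f <- f / tot
  ll <- two_locus_loglik(tab, f)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    num <- f[1] * f[4]
    den <- num + f[2] * f[3]
    x <- if (den > 0) num / den else 0.5
    f_new <- (c(cAB, cAb, caB, cab) +
                nd * c(x, 1 - x, 1 - x, x)) / tot
    ll <- c(ll, two_locus_loglik(tab, f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (nd == 0L || delta < tol || iter >= max_iter) break
  }
  names(f) <- c("pAB", "pAb", "paB", "pab")
  list(freqs = f, n = n, n_iter = iter, loglik = ll, counts = tab)
}

# Multinomial genotype-class log-likelihood under HWE on haplotypes.
two_locus_loglik <- function(tab, f) {
  pr <- two_locus_cell_probs(f)
  sum(tab[tab > 0] * log(pr[tab > 0]))
}

# 3x3 genotype-cell probabilities from haplotype frequencies (HWE).
two_locus_cell_probs <- function(f) {
  pAB <- f[1]; pAb <- f[2]; paB <- f[3]; pab <- f[4]
  m <- matrix(0, 3, 3)
  m[1, 1] <- pAB^2;        m[1, 2] <- 2 * pAB * pAb;                 m[1, 3] <- pAb^2
  m[2, 1] <- 2 * pAB * paB; m[2, 2] <- 2 * pAB * pab + 2 * pAb * paB; m[2, 3] <- 2 * pAb * pab
  m[3, 1] <- paB^2;        m[3, 2] <- 2 * paB * pab;                 m[3, 3] <- pab^2
  pmax(m, 1e-300)
}

#' LD statistics from two-locus haplotype frequencies
#'
#' `D = pAB - pA*pB`; `Dmax = min(pA*pb, pa*pB)` when `D > 0`, else
#' `min(pA*pB, pa*pb)`; `Dprime = |D|/Dmax`; `r2 = D^2/(pA*pa*pB*pb)`.
#' A monomorphic locus gives `Dmax = 0` and `Dprime`, `r2` are returned
#' `NA` (undefined).
#'
#' @param freqs Numeric length-4 vector `(pAB, pAb, paB, pab)`.
#' @return Tibble: pA, pB, D, Dprime, r2.
#' @export
ld_stats <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-6) abort("haplotype frequencies must sum to 1")
  pA <- unname(freqs[1] + freqs[2]); pB <- unname(freqs[1] + freqs[3])
  pa <- 1 - pA; pb <- 1 - pB
  D <- unname(freqs[1] - pA * pB)
  dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  denom <- pA * pa * pB * pb
  tibble::tibble(
    pA = pA, pB = pB, D = D,
    Dprime = ifelse(dmax > 0, abs(D) / dmax,
                    ifelse(denom > 0, 0, NA_real_)),
    r2 = ifelse(denom > 0, D^2 / denom, NA_real_)
  )
}

#' Likelihood-based confidence bounds on D-prime
#'
#' Evaluates the genotype-data likelihood on a grid of D-prime values in
#' `[0, 1]` (allele frequencies held at their MLEs, D taking the sign of
#' its MLE), normalises it to a density over the grid, and reports the
#' cumulative 5th and 95th percentile grid points as the one-sided 90%
#' confidence bounds used by Gabriel-style block finding.
#'
#' @inheritParams two_locus_em
#' @param grid_points Grid resolution (default 101, i.e. steps of 0.01).
#' @param coverage Central coverage (default 0.90).
#' @return List: `ci_low`, `ci_high`, `dprime_mle`, plus the `stats` tibble
#'   of [ld_stats()] at the MLE.
#' @export
dprime_ci <- function(g1, g2, grid_points = 101, coverage = 0.90) {
  em <- two_locus_em(g1, g2)
  st <- ld_stats(em$freqs)
  if (is.na(st$Dprime)) abort("monomorphic locus: D-prime undefined")
  pA <- st$pA; pB <- st$pB; pa <- 1 - pA; pb <- 1 - pB
  s <- if (st$D >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  grid <- seq(0, 1, length.out = grid_points)
  ll <- vapply(grid, function(dp) {
    Dg <- s * dp * dmax
    f <- c(pA * pB + Dg, pA * pb - Dg, pa * pB - Dg, pa * pb + Dg)
    f <- pmin(pmax(f, 0), 1)
    two_locus_loglik(em$counts, f)
  }, numeric(1))
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  alpha <- (1 - coverage) / 2
  list(ci_low = grid[which(cdf >= alpha)[1]],
       ci_high = grid[which(cdf >= 1 - alpha)[1]],
       dprime_mle = st$Dprime, stats = st)
}

#' Pairwise LD table
#'
#' Computes two-locus EM haplotype frequencies, D/D-prime/r2 and D-prime
#' confidence bounds for variant pairs of a genotype matrix.
#'
#' @param genotypes Sample-by-variant genotype matrix.
#' @param positions Optional 1-based positions (defaults to column index).
#' @param max_pair_span Only pairs within this many base pairs are
#'   computed (`Inf` for all pairs).
#' @param max_pair_markers Only pairs within this many marker indices are
#'   computed (`Inf` for all).
#' @param informative_min Expected minor two-locus haplotype count (under
#'   linkage equilibrium) below which a pair is flagged non-informative.
#' @return Tibble with one row per pair: i, j, id_i, id_j, pos_i, pos_j,
#'   pAB..pab, D, Dprime, r2, ci_low, ci_high, informative.
#' @export
ld_matrix <- function(genotypes, positions = NULL, max_pair_span = Inf,
                      max_pair_markers = Inf, informative_min = 5) {
  assert_genotype_matrix(genotypes)
  m <- ncol(genotypes)
  if (m < 2L) abort("need at least 2 variants")
  if (is.null(positions)) positions <- seq_len(m)
  ids <- colnames(genotypes) %||% as.character(seq_len(m))
  pairs <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      if ((j - i) > max_pair_markers) break
      if ((positions[j] - positions[i]) > max_pair_span) break
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  purrr::map_dfr(pairs, function(p) {
    i <- p[1]; j <- p[2]
    g1 <- genotypes[, i]; g2 <- genotypes[, j]
    em <- two_locus_em(g1, g2)
    st <- ld_stats(em$freqs)
    mono <- is.na(st$Dprime)
    ci <- if (mono) list(ci_low = NA_real_, ci_high = NA_real_)
          else dprime_ci(g1, g2)
    n_chr <- 2 * em$n
    minf <- n_chr * min(st$pA, 1 - st$pA) * min(st$pB, 1 - st$pB)
    tibble::tibble(
      i = i, j = j, id_i = ids[i], id_j = ids[j],
      pos_i = positions[i], pos_j = positions[j],
      pAB = unname(em$freqs[1]), pAb = unname(em$freqs[2]),
      paB = unname(em$freqs[3]), pab = unname(em$freqs[4]),
      D = st$D, Dprime = st$Dprime, r2 = st$r2,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      informative = !mono & minf >= informative_min
    )
  }) -> out
  class(out) <- c("ld_pairs", class(out))
  out
}

#' Gabriel-style haplotype block detection
#'
#' Classifies variant pairs by their D-prime confidence bounds: "strong LD"
#' when `ci_high >= strong_upper` and `ci_low >= strong_lower`; "historical
#' recombination" when `ci_high < recomb_upper`; otherwise uninformative.
#' A candidate block is a contiguous run of markers whose outermost pair is
#' in strong LD and in which at least `informative_fraction` of informative
#' pairs are strong, subject to `max_markers` markers spanning at most
#' `max_span_bp`. Candidates are ranked by genomic span and accepted
#' greedily without overlap.
#'
#' @param genotypes Sample-by-variant genotype matrix, columns sorted by
#'   position.
#' @param positions 1-based variant positions (sorted, one per column).
#' @param max_markers,max_span_bp Block size limits (defaults 15 markers /
#'   160 kb).
#' @param strong_upper,strong_lower,recomb_upper D-prime CI thresholds.
#' @param informative_fraction Minimum fraction of informative pairs in
#'   strong LD.
#' @param ld Optional precomputed [ld_matrix()] table (pairs within the
#'   size limits must be present).
#' @return A `block_set` tibble: block_id, start_idx, stop_idx, start, stop,
#'   n_snps, span_bp, members (list of column names), frac_strong.
#' @export
gabriel_blocks <- function(genotypes, positions,
                           max_markers = 15, max_span_bp = 160000,
                           strong_upper = 0.98, strong_lower = 0.70,
                           recomb_upper = 0.90,
                           informative_fraction = 0.95, ld = NULL) {
  m <- ncol(genotypes)
  if (is.unsorted(positions)) abort("`positions` must be sorted")
  if (is.null(ld)) {
    ld <- ld_matrix(genotypes, positions, max_pair_span = max_span_bp,
                    max_pair_markers = max_markers - 1L)
  }
  strong <- recomb <- matrix(FALSE, m, m)
  info <- matrix(FALSE, m, m)
  for (r in seq_len(nrow(ld))) {
    i <- ld$i[r]; j <- ld$j[r]
    if (!isTRUE(ld$informative[r])) next
    info[i, j] <- TRUE
    if (!is.na(ld$ci_high[r]) && ld$ci_high[r] >= strong_upper &&
        ld$ci_low[r] >= strong_lower) strong[i, j] <- TRUE
    else if (!is.na(ld$ci_high[r]) && ld$ci_high[r] < recomb_upper) {
      recomb[i, j] <- TRUE
    } else info[i, j] <- FALSE   # CI straddles: uninformative for the rule
  }
  cand <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), min(m, i + max_markers - 1L))) {
      span <- positions[j] - positions[i]
      if (span > max_span_bp) break
      if (!strong[i, j]) next
      sub_strong <- strong[i:j, i:j]
      sub_info <- info[i:j, i:j]
      n_info <- sum(sub_info)
      frac <- if (n_info > 0) sum(sub_strong & sub_info) / n_info else 1
      if (frac >= informative_fraction) {
        cand[[length(cand) + 1L]] <-
          tibble::tibble(start_idx = i, stop_idx = j, span_bp = span,
                         frac_strong = frac)
      }
    }
  }
  ids <- colnames(genotypes) %||% as.character(seq_len(m))
  if (!length(cand)) {
    out <- tibble::tibble(block_id = character(0), start_idx = integer(0),
                          stop_idx = integer(0), start = integer(0),
                          stop = integer(0), n_snps = integer(0),
                          span_bp = numeric(0), members = list(),
                          frac_strong = numeric(0))
    class(out) <- c("block_set", class(out))
    return(out)
  }
  cand <- dplyr::bind_rows(cand)
  cand <- cand[order(-cand$span_bp,
                     -(cand$stop_idx - cand$start_idx), cand$start_idx), ]
  taken <- rep(FALSE, m)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    rng <- cand$start_idx[r]:cand$stop_idx[r]
    if (!any(taken[rng])) {
      keep[r] <- TRUE
      taken[rng] <- TRUE
    }
  }
  blocks <- cand[keep, ]
  blocks <- blocks[order(blocks$start_idx), ]
  out <- tibble::tibble(
    block_id = sprintf("B%d", seq_len(nrow(blocks))),
    start_idx = blocks$start_idx, stop_idx = blocks$stop_idx,
    start = positions[blocks$start_idx], stop = positions[blocks$stop_idx],
    n_snps = blocks$stop_idx - blocks$start_idx + 1L,
    span_bp = blocks$span_bp,
    members = purrr::map2(blocks$start_idx, blocks$stop_idx,
                          function(a, b) ids[a:b]),
    frac_strong = blocks$frac_strong
  )
  class(out) <- c("block_set", class(out))
  out
}

#' Export blocks as BED intervals
#'
#' Internal coordinates are 1-based inclusive; BED output converts to
#' 0-based half-open at this boundary.
#'
#' @param blocks A `block_set` from [gabriel_blocks()].
#' @param chrom Chromosome name.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_blocks_bed <- function(blocks, chrom, path) {
  df <- data.frame(chrom = chrom, start = blocks$start - 1L,
                   end = blocks$stop, name = blocks$block_id)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
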