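# Multi-marker EM haplotype phasing within a block.
#
# Individuals are grouped by identical genotype pattern; for each pattern
# the compatible *ordered* haplotype pairs are enumerated (heterozygous
# sites contribute a factor 2, missing sites a factor 4), which makes the
# E-step a sum over pattern-level pair lists weighted by pattern counts.
# The haplotype universe is the union of compatible haplotypes over all
# patterns, not all 2^m strings.

enumerate_pattern_pairs <- function(g, cap = 1e5) {
  h1 <- 0L; h2 <- 0L
  for (s in seq_along(g)) {
    gs <- g[s]
    opts <- if (is.na(gs)) cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
            else if (gs == 0L) cbind(0L, 0L)
            else if (gs == 2L) cbind(1L, 1L)
            else cbind(c(0L, 1L), c(1L, 0L))
    k <- nrow(opts)
    n_cur <- length(h1)
    if (n_cur * k > cap) {
      abort("compatible-haplotype enumeration exceeds cap (too much missingness)")
    }
    h1 <- rep(h1, each = k) * 2L + opts[, 1]
    h2 <- rep(h2, each = k) * 2L + opts[, 2]
  }
  cbind(h1, h2)
}

hap_code_to_bits <- function(code, m) {
  vapply(seq_len(m), function(s) bitwAnd(bitwShiftR(code, m - s), 1L),
         integer(length(code)))
}

#' EM haplotype frequency estimation for a block
#'
#' Estimates haplotype frequencies for a set of (up to ~15) biallelic
#' markers from unphased genotypes by expectation-maximisation over the
#' haplotypes compatible with the observed genotypes. Stops after
#' `max_iter` iterations or when the largest absolute frequency change
#' falls below `tol` (defaults 50 and 1e-4); if the cap is hit first a
#' convergence warning is logged. The log-likelihood is non-decreasing
#' across iterations.
#'
#' @param genotypes Sample-by-marker genotype matrix for one block
#'   (0/1/2/NA ALT dosages). Individuals with all genotypes missing are
#'   excluded with a message.
#' @param block_id Label used for haplotype names (default "blk").
#' @param max_iter,tol EM stopping rule.
#' @param alleles Optional list with character vectors `ref` and `alt` (one
#'   per marker) used to render haplotypes as nucleotide strings; default
#'   renders 0/1 ALT-dosage strings.
#' @return A `hap_set` object: tibble `haplotypes` (hap, label, frequency,
#'   retained), `dosages` (individual-by-haplotype expected counts, columns
#'   in frequency order), `posteriors` bookkeeping for
#'   [diplotype_posteriors()], `loglik` trace, `converged`, `n_iter`,
#'   `excluded` (sample ids dropped as all-missing).
#' @export
em_haplotype_freqs <- function(genotypes, block_id = "blk", max_iter = 50,
                               tol = 1e-4, alleles = NULL) {
  assert_genotype_matrix(genotypes)
  m <- ncol(genotypes)
  if (m > 15L) warn("more than 15 markers in one block; EM may be slow")
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  all_miss <- rowSums(!is.na(genotypes)) == 0L
  excluded <- ids[all_miss]
  if (any(all_miss)) {
    inform(sprintf("excluding %d individual(s) with no genotypes in block %s",
                   sum(all_miss), block_id))
    genotypes <- genotypes[!all_miss, , drop = FALSE]
    ids <- ids[!all_miss]
  }
  n <- nrow(genotypes)
  if (n < 1L) abort("no genotyped individuals in block")

  key <- apply(genotypes, 1L, paste, collapse = ",")
  pat_of <- match(key, unique(key))
  pat_rows <- match(unique(key), key)
  n_pat <- length(pat_rows)
  pat_w <- tabulate(pat_of, n_pat)

  pair_list <- lapply(pat_rows, function(r)
    enumerate_pattern_pairs(as.integer(genotypes[r, ])))
  universe <- sort(unique(unlist(lapply(pair_list, as.vector))))
  K <- length(universe)
  pair_idx <- lapply(pair_list, function(pp)
    cbind(match(pp[, 1], universe), match(pp[, 2], universe)))

  f <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(K)
    ll <- 0
    for (p in seq_len(n_pat)) {
      idx <- pair_idx[[p]]
      lik <- f[idx[, 1]] * f[idx[, 2]]
      s <- sum(lik)
      if (s <= 0) { s <- .Machine$double.xmin; lik[] <- s / nrow(idx) }
      post <- lik / s
      w <- pat_w[p]
      ll <- ll + w * log(s)
      inc <- post * w
      counts <- counts + rowsum_accumulate(idx, inc, K)
    }
    ll_trace <- c(ll_trace, ll)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("EM for block %s stopped at %d iterations without reaching tol %g",
                 block_id, iter, tol))
  }

  ord <- order(-f, universe)
  bits <- hap_code_to_bits(universe, m)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = length(universe))
  hap_str <- apply(bits, 1L, paste, collapse = "")
  if (!is.null(alleles)) {
    hap_str <- vapply(seq_along(universe), function(h) {
      paste(ifelse(bits[h, ] == 1L, alleles$alt, alleles$ref), collapse = "")
    }, character(1))
  }
  # frequency-ranked labels, ties broken lexicographically by allele string
  ord <- order(-f, hap_str)
  haplotypes <- tibble::tibble(
    hap = hap_str[ord],
    label = paste0(block_id, label_series(K)),
    frequency = f[ord],
    retained = TRUE
  )

  # final E-step quantities in ranked order
  rank_of <- match(seq_len(K), ord)   # old index -> rank
  dos_pat <- matrix(0, n_pat, K)
  post_list <- vector("list", n_pat)
  for (p in seq_len(n_pat)) {
    idx <- pair_idx[[p]]
    lik <- f[idx[, 1]] * f[idx[, 2]]
    post <- lik / sum(lik)
    r1 <- rank_of[idx[, 1]]; r2 <- rank_of[idx[, 2]]
    d <- rowsum_accumulate(cbind(r1, r2), post, K)
    dos_pat[p, ] <- d
    # collapse ordered pairs to unordered diplotypes
    key2 <- paste(pmin(r1, r2), pmax(r1, r2))
    agg <- rowsum(post, key2)
    pr <- as.numeric(agg)
    names(pr) <- rownames(agg)
    post_list[[p]] <- pr
  }
  dosages <- dos_pat[pat_of, , drop = FALSE]
  rownames(dosages) <- ids
  colnames(dosages) <- haplotypes$label

  structure(
    list(block_id = block_id, haplotypes = haplotypes, dosages = dosages,
         pattern_of = pat_of, pattern_posteriors = post_list,
         sample_ids = ids, loglik = ll_trace, converged = converged,
         n_iter = iter, excluded = excluded, n_markers = m),
    class = "hap_set")
}

# sum `w` into an accumulator at idx[,1] and idx[,2]
rowsum_accumulate <- function(idx, w, K) {
  out <- numeric(K)
  a <- rowsum(c(w, w), c(idx[, 1], idx[, 2]))
  out[as.integer(rownames(a))] <- a
  out
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> block %s: %d haplotypes over %d markers, %d samples; EM %s in %d iterations\n",
              x$block_id, nrow(x$haplotypes), x$n_markers,
              length(x$sample_ids),
              if (x$converged) "converged" else "stopped", x$n_iter))
  print(x$haplotypes, ...)
  invisible(x)
}

#' Prune rare haplotypes
#'
#' Marks haplotypes with estimated frequency below `min_freq` (default
#' 0.01; the boundary value is kept) as not retained, removing them from
#' reporting and association. Frequencies are deliberately *not*
#' renormalised, so reported frequencies stay on the raw scale.
#' Individuals whose posterior diplotype mass lies mostly (> 0.5) on pruned
#' haplotypes are flagged.
#'
#' @param hapset A `hap_set`.
#' @param min_freq Frequency threshold.
#' @return The `hap_set` with updated `retained` flags, pruned columns
#'   dropped from `dosages`, and a `flagged_samples` character vector.
#' @export
prune_rare <- function(hapset, min_freq = 0.01) {
  keep <- hapset$haplotypes$frequency >= min_freq
  if (!any(keep)) abort("all haplotypes fall below the frequency threshold")
  hapset$haplotypes$retained <- keep
  pruned_ranks <- which(!keep)
  if (length(pruned_ranks)) {
    pat_mass <- vapply(hapset$pattern_posteriors, function(pr) {
      pairs <- strsplit(names(pr), " ")
      sum(pr[vapply(pairs, function(ab)
        any(as.integer(ab) %in% pruned_ranks), logical(1))])
    }, numeric(1))
    hapset$flagged_samples <-
      hapset$sample_ids[pat_mass[hapset$pattern_of] > 0.5]
  } else {
    hapset$flagged_samples <- character(0)
  }
  hapset$dosages <- hapset$dosages[, keep, drop = FALSE]
  hapset
}

#' Diplotype posterior for one individual
#'
#' Posterior over compatible unordered haplotype pairs,
#' `P(h1, h2) proportional to f_h1 * f_h2 * (2 if h1 != h2)`, normalised.
#'
#' @param hapset A `hap_set`.
#' @param individual Sample id or row index.
#' @return Tibble: hap1, hap2 (labels), posterior.
#' @export
diplotype_posteriors <- function(hapset, individual) {
  i <- if (is.character(individual)) match(individual, hapset$sample_ids)
       else as.integer(individual)
  if (is.na(i) || i < 1L || i > length(hapset$sample_ids)) {
    abort("unknown individual")
  }
  pr <- hapset$pattern_posteriors[[hapset$pattern_of[i]]]
  ranks <- do.call(rbind, lapply(strsplit(names(pr), " "), as.integer))
  tibble::tibble(hap1 = hapset$haplotypes$label[ranks[, 1]],
                 hap2 = hapset$haplotypes$label[ranks[, 2]],
                 posterior = as.numeric(pr))
}

#' Expected haplotype dosages
#'
#' Individual-by-haplotype matrix of posterior-expected haplotype counts
#' (each row sums to 2 for fully-typed individuals). These are the additive
#' regressors used for block association.
#'
#' @param hapset A `hap_set`.
#' @param retained_only Drop pruned haplotype columns (default TRUE; they
#'   are already dropped by [prune_rare()]).
#' @return Numeric matrix.
#' @export
haplotype_dosages <- function(hapset, retained_only = TRUE) {
  d <- hapset$dosages
  if (retained_only && !all(hapset$haplotypes$retained)) {
    keep <- hapset$haplotypes$label[hapset$haplotypes$retained]
    d <- d[, intersect(colnames(d), keep), drop = FALSE]
  }
  d
}

#' Call inversion-clade genotypes from a tag SNP
#'
#' Labels each sample by its clade diplotype at a tag variant (e.g. the
#' H1/H2 inversion tag): 0 ALT copies = `H1/H1`, 1 = `H1/H2`, 2 = `H2/H2`.
#' Samples with a missing tag genotype get `NA` and are excluded from
#' stratified analyses.
#'
#' @param genotypes Genotype matrix containing the tag variant.
#' @param tag_variant Column name or index of the tag SNP.
#' @param ref_clade,alt_clade Clade names for the REF and ALT alleles.
#' @return Tibble: sample_id, tag_genotype, clade.
#' @export
call_tag_snp_clades <- function(genotypes, tag_variant, ref_clade = "H1",
                                alt_clade = "H2") {
  g <- genotypes[, tag_variant]
  if (any(is.na(g))) {
    inform(sprintf("%d sample(s) with missing tag genotype excluded from strata",
                   sum(is.na(g))))
  }
  lab <- c(paste0(ref_clade, "/", ref_clade),
           paste0(ref_clade, "/", alt_clade),
           paste0(alt_clade, "/", alt_clade))
  tibble::tibble(
    sample_id = rownames(genotypes) %||% as.character(seq_len(nrow(genotypes))),
    tag_genotype = as.integer(g),
    clade = lab[g + 1L]
  )
}
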