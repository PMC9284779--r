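#' Construct a haplotype pool
#'
#' A haplotype pool is the simulation ground truth for one sub-haplotype
#' block: the ancestral allele strings segregating in the population, their
#' chromosome frequencies, and the per-haplotype disease and trait effects
#' attached to them.
#'
#' @param block_id Character label for the block (e.g. `"H1.1"`).
#' @param chrom Chromosome name used when genotypes are materialised.
#' @param positions Integer vector of 1-based genomic coordinates, one per
#'   site; strictly increasing.
#' @param haplotypes Tibble (or data frame) with columns `hap` (allele
#'   string, one character per position), `freq` (chromosome frequency,
#'   summing to 1), and optionally `clade` (e.g. `"H1"`/`"H2"`), `log_or`
#'   (per-copy disease log odds ratio; 0 for the reference haplotype),
#'   `trait_effect` (per-copy raw contribution to the expression-like
#'   trait) and `copy_number` (integer-ish per-copy contribution to the
#'   copy-number trait).
#' @return A `hap_pool` object.
#' @export
hap_pool <- function(block_id, chrom, positions, haplotypes) {
  haps <- tibble::as_tibble(haplotypes)
  if (!all(c("hap", "freq") %in% names(haps))) {
    abort("`haplotypes` needs at least columns `hap` and `freq`")
  }
  if (!"clade" %in% names(haps)) haps$clade <- "H1"
  if (!"log_or" %in% names(haps)) haps$log_or <- 0
  if (!"trait_effect" %in% names(haps)) haps$trait_effect <- 1
  if (!"copy_number" %in% names(haps)) haps$copy_number <- 1
  if (any(nchar(haps$hap) != length(positions))) {
    abort("all allele strings must have one character per position")
  }
  if (any(haps$freq <= 0)) abort("haplotype frequencies must be positive")
  if (abs(sum(haps$freq) - 1) > 1e-9) {
    abort("haplotype frequencies must sum to 1 (within 1e-9)")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing")
  }
  structure(
    list(block_id = block_id, chrom = as.character(chrom),
         positions = as.integer(positions), haplotypes = haps),
    class = "hap_pool"
  )
}

#' @export
print.hap_pool <- function(x, ...) {
  cat(sprintf("<hap_pool> block %s: %d sites (%s:%s-%s), %d haplotypes\n",
              x$block_id, length(x$positions), x$chrom,
              format(min(x$positions), big.mark = ","),
              format(max(x$positions), big.mark = ","),
              nrow(x$haplotypes)))
  print(x$haplotypes, ...)
  invisible(x)
}

#' Default 17q21.31 sub-haplotype pools
#'
#' Returns the three H1 sub-haplotype block pools that the synthetic cohorts
#' are built from. Allele strings, chromosome frequencies and per-copy
#' case-control odds ratios are those estimated for the blocks H1.1 (5 SNPs,
#' within MAPT), H1.2 (8 SNPs, MAPT) and H1.3 (9 SNPs, KANSL1) in the larger
#' of the two Parkinson's disease discovery cohorts at this locus; the
#' reference (most common) haplotype of each block carries log OR 0.
#' Protective haplotypes additionally carry a 3-5 fold per-copy elevation of
#' the expression-like trait and, for the two strongest, a doubled per-copy
#' contribution to the copy-number trait, mirroring the structural variation
#' that protective sub-haplotypes tag at this locus.
#'
#' H1.3 block frequencies are published rounded to two decimals and sum to
#' 0.99; they are renormalised proportionally so that the pool is a proper
#' distribution.
#'
#' @return Named list of three [hap_pool()] objects (`H1.1`, `H1.2`, `H1.3`).
#' @examples
#' pools <- build_default_pools()
#' pools$H1.1
#' @export
build_default_pools <- function() {
  h11 <- tibble::tribble(
    ~hap,    ~freq, ~or,   ~trait_effect, ~copy_number,
    "ACTCT", 0.25,  1.00,  1.0,           1,
    "ACTTG", 0.27,  1.60,  1.0,           1,
    "GCCTG", 0.18,  0.37,  4.7,           2,
    "ATCTG", 0.18,  0.22,  3.5,           1,
    "ACCTG", 0.12,  2.51,  1.0,           1
  )
  h12 <- tibble::tribble(
    ~hap,       ~freq, ~or,   ~trait_effect, ~copy_number,
    "TTTCGATG", 0.48,  1.00,  1.0,           1,
    "TCTCGATG", 0.17,  1.27,  1.0,           1,
    "TTAAAATA", 0.15,  1.31,  1.0,           1,
    "TTAAGATG", 0.07,  1.36,  1.0,           1,
    "CTTCGATG", 0.06,  1.17,  1.0,           1,
    "TTTCGGTG", 0.05,  1.16,  1.0,           1,
    "TTAAAATG", 0.01,  1.10,  1.0,           1,
    "TTTCGACG", 0.01,  1.28,  1.0,           1
  )
  h13 <- tibble::tribble(
    ~hap,        ~freq, ~or,   ~trait_effect, ~copy_number,
    "GACTGAGAT", 0.28,  1.00,  1.0,           1,
    "CATTAGGGC", 0.18,  0.43,  4.2,           2,
    "GATTGAGAT", 0.17,  1.11,  1.0,           1,
    "CTTTGGTGC", 0.15,  0.61,  3.4,           1,
    "CATTGGGGC", 0.09,  1.67,  1.0,           1,
    "CATTGGGGT", 0.08,  0.60,  3.1,           1,
    "GATCGAGAT", 0.04,  0.83,  3.8,           1
  )
  h13$freq <- h13$freq / sum(h13$freq)

  spans <- list(H1.1 = c(44040184L, 44041992L),
                H1.2 = c(44090196L, 44097249L),
                H1.3 = c(44119987L, 44131305L))
  make <- function(id, tab) {
    m <- nchar(tab$hap[1])
    pos <- as.integer(round(seq(spans[[id]][1], spans[[id]][2],
                                length.out = m)))
    tab$log_or <- log(tab$or)
    tab$or <- NULL
    tab$clade <- "H1"
    hap_pool(id, "17", pos, tab)
  }
  list(H1.1 = make("H1.1", h11), H1.2 = make("H1.2", h12),
       H1.3 = make("H1.3", h13))
}

#' Specification of the H2 clade tag SNP
#'
#' The two deep clades of the 17q21.31 inversion are tagged by a single SNP
#' (rs8070723-like); the minor (H2) clade segregates at frequency ~0.2 in
#' European-ancestry cohorts and is protective (clade OR ~0.82).
#'
#' @param h2_freq H2 clade (ALT allele) frequency.
#' @param h2_log_or Per-copy disease log OR of the H2 clade.
#' @param position 1-based coordinate for the emitted tag SNP.
#' @return A list with the tag SNP parameters.
#' @export
h2_tag_spec <- function(h2_freq = 0.2, h2_log_or = log(0.82),
                        position = 44081064L) {
  assert_proportion(h2_freq, "h2_freq")
  list(id = "tagH2", chrom = "17", position = as.integer(position),
       ref = "A", alt = "G", h2_freq = h2_freq, h2_log_or = h2_log_or)
}

# Site-level allele table for a pool: REF = allele carried by the most
# frequent haplotype, ALT = the other observed allele. Pools are built from
# strictly biallelic sites.
pool_alleles <- function(pool) {
  haps <- pool$haplotypes
  mat <- do.call(rbind, strsplit(haps$hap, ""))
  ref_row <- which.max(haps$freq)
  m <- ncol(mat)
  ref <- mat[ref_row, ]
  alt <- character(m)
  for (j in seq_len(m)) {
    alleles <- unique(mat[, j])
    if (length(alleles) > 2L) {
      abort(sprintf("site %d of block %s is not biallelic", j, pool$block_id))
    }
    alt[j] <- if (length(alleles) == 1L) NA_character_ else setdiff(alleles, ref[j])
  }
  list(ref = ref, alt = alt, allele_mat = mat)
}

# Haplotype strings as 0/1 ALT-dosage rows (haplotype-by-site matrix).
pool_hap_bits <- function(pool) {
  al <- pool_alleles(pool)
  bits <- t(apply(al$allele_mat, 1L, function(r) as.integer(r != al$ref)))
  dimnames(bits) <- NULL
  bits
}
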