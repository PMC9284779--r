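#' Write a simulated cohort to standard files
#'
#' Emits `<prefix>.vcf` (VCF 4.2, GT-only, unphased "/" separator, 1-based
#' sorted positions), `<prefix>.pheno.tsv` (sample_id, status and
#' covariates) and `<prefix>.traits.tsv`. The files round-trip losslessly
#' through [read_vcf()] / [read_pheno_tsv()] / [read_trait_tsv()].
#'
#' @param cohort A `sim_cohort` (or list with `genotypes`, `variants`,
#'   `samples`, optionally `traits`).
#' @param out_prefix Path prefix for the emitted files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_prefix) {
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = paste0(out_prefix, ".vcf"),
             pheno = paste0(out_prefix, ".pheno.tsv"),
             traits = paste0(out_prefix, ".traits.tsv"))
  write_genotypes_vcf(cohort$genotypes, cohort$variants, paths["vcf"])
  readr::write_tsv(cohort$samples, paths["pheno"])
  if (!is.null(cohort$traits)) readr::write_tsv(cohort$traits, paths["traits"])
  invisible(paths)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param genotypes Sample-by-variant matrix (0/1/2/NA ALT dosages).
#' @param variants Tibble with columns id, chrom, pos, ref, alt (rows
#'   aligned with the matrix columns).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, variants, path) {
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  genotypes <- genotypes[, ord, drop = FALSE]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  samples <- rownames(genotypes) %||%
    sprintf("S%05d", seq_len(nrow(genotypes)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=subhapr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(v) {
    g <- genotypes[, v]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(variants$chrom[v], variants$pos[v], variants$id[v],
            variants$ref[v],
            ifelse(is.na(variants$alt[v]), ".", variants$alt[v]),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read unphased genotypes from a VCF
#'
#' Reads a VCF (via `vcfR`), keeps biallelic SNP records, and converts GT
#' fields to ALT-dosage genotypes. The phased separator "|" is accepted
#' and phase discarded (the pipeline is unphased throughout); `./.` (or
#' any malformed GT) becomes missing. Multi-allelic records are dropped
#' with a message. Positions are 1-based inclusive internally.
#'
#' @param path VCF file (plain or gzipped).
#' @return List with `genotypes` (sample-by-variant integer matrix) and
#'   `variants` (tibble: id, chrom, pos, ref, alt, info when present).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))
  multi <- grepl(",", fix$alt %||% "")
  if (any(multi)) {
    inform(sprintf("dropping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep))
  # tolerate "|" phasing; anything not two alleles of 0/1 -> NA
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  n_bad <- sum(!is.na(gt) & !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")))
  if (n_bad > 0) warn(sprintf("%d malformed GT field(s) set to missing", n_bad))
  variants <- tibble::tibble(
    id = fix$id[keep], chrom = fix$chrom[keep],
    pos = as.integer(fix$pos[keep]), ref = fix$ref[keep], alt = fix$alt[keep]
  )
  g <- t(dose)
  colnames(g) <- variants$id
  rownames(g) <- colnames(gt)
  list(genotypes = g, variants = variants)
}

#' Read a phenotype/covariate table
#'
#' TSV with columns `sample_id`, `status` (0 = control, 1 = case) and any
#' covariate columns.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_pheno_tsv <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "status") %in% names(ph))) {
    abort("phenotype table needs `sample_id` and `status` columns")
  }
  if (!all(ph$status %in% c(0L, 1L, NA))) abort("`status` must be 0/1")
  ph
}

#' Read a quantitative trait table
#'
#' TSV with `sample_id` plus one column per named trait.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_trait_tsv <- function(path) {
  tr <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(tr)) abort("trait table needs `sample_id`")
  tr
}

#' Read a transposed tabular genotype matrix
#'
#' TSV alternative to VCF input: columns `id`, `chrom`, `pos`, `ref`,
#' `alt` followed by one column per sample holding 0/1/2/NA dosages.
#'
#' @param path TSV file.
#' @return As [read_vcf()].
#' @export
read_genotype_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    abort("genotype table needs columns id, chrom, pos, ref, alt")
  }
  variants <- tab[meta_cols]
  g <- t(as.matrix(tab[setdiff(names(tab), meta_cols)]))
  colnames(g) <- variants$id
  storage.mode(g) <- "integer"
  list(genotypes = g, variants = variants)
}

#' Export a haplotype set as TSV tables
#'
#' Writes `<prefix>.haplotypes.tsv` (hap, label, frequency, retained) and
#' `<prefix>.dosages.tsv` (sample_id plus one expected-dosage column per
#' retained haplotype).
#'
#' @param hapset A `hap_set`.
#' @param out_prefix Path prefix.
#' @return Written paths, invisibly.
#' @export
write_hapset <- function(hapset, out_prefix) {
  paths <- c(haplotypes = paste0(out_prefix, ".haplotypes.tsv"),
             dosages = paste0(out_prefix, ".dosages.tsv"))
  readr::write_tsv(hapset$haplotypes, paths["haplotypes"])
  dos <- tibble::as_tibble(hapset$dosages)
  dos <- dplyr::bind_cols(tibble::tibble(sample_id = hapset$sample_ids), dos)
  readr::write_tsv(dos, paths["dosages"])
  invisible(paths)
}

#' Export / import block definitions
#'
#' Blocks detected in one dataset can be serialised to JSON and applied to
#' a second dataset without re-detection (the two-stage replication
#' design).
#'
#' @param blocks A `block_set` tibble.
#' @param path JSON file.
#' @return `write_block_json()`: the path, invisibly.
#' @export
write_block_json <- function(blocks, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(blocks)), function(r) list(
      block_id = blocks$block_id[r], start = blocks$start[r],
      stop = blocks$stop[r], members = blocks$members[[r]])),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_block_json
#' @export
read_block_json <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- purrr::map_dfr(raw, function(b) tibble::tibble(
    block_id = b$block_id, start = b$start, stop = b$stop,
    members = list(unlist(b$members))))
  out$n_snps <- lengths(out$members)
  class(out) <- c("block_set", class(out))
  out
}
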