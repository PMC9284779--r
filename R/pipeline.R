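#' Pipeline configuration
#'
#' Bundles every tunable of the stage pipeline with its conventional
#' default: QC thresholds (98% call rates, MAF 1%, HWE exact 1e-4), Gabriel
#' block parameters (15 markers / 160 kb, CI bounds 0.98 / 0.70), EM
#' phasing controls (50 iterations, tolerance 1e-4, rare-haplotype cutoff
#' 0.01) and association options. The configuration round-trips through
#' YAML unchanged.
#'
#' @param ... Overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    qc = list(call_rate = 0.98, maf = 0.01, sample_call_rate = 0.98,
              hwe_alpha = 1e-4, info_score = 0.3),
    blocks = list(max_markers = 15L, max_span_bp = 160000L,
                  strong_upper = 0.98, strong_lower = 0.70,
                  recomb_upper = 0.90, informative_fraction = 0.95),
    phase = list(max_iter = 50L, tol = 1e-4, min_freq = 0.01),
    assoc = list(n_pcs = 0L),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
read_config_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run one analysis stage
#'
#' Executes the full pipeline on a cohort: QC -> block detection (or
#' imported block definitions, mirroring the detect-in-stage-1 /
#' apply-to-stage-2 design) -> EM phasing per block -> rare-haplotype
#' pruning -> case-control association per block -> block-level FDR. When
#' `out_dir` is given, results, the QC report, the configuration and a log
#' (seed, configuration hash, per-stage counts) are written as TSV/JSON.
#'
#' @param cohort A `sim_cohort`, or a list with `genotypes`, `variants`
#'   and `samples` (e.g. from [read_vcf()] plus [read_pheno_tsv()]).
#' @param config A [pipeline_config()].
#' @param blocks Optional imported `block_set` (skips detection).
#' @param out_dir Optional output directory.
#' @return List: `qc_report`, `blocks`, `hapsets` (named by block),
#'   `association` (combined `hap_assoc` tibble with `fdr_q` on block
#'   rows), `config`.
#' @export
run_stage <- function(cohort, config = pipeline_config(), blocks = NULL,
                      out_dir = NULL) {
  qc <- qc_pipeline(cohort$genotypes,
                    call_rate = config$qc$call_rate, maf = config$qc$maf,
                    sample_call_rate = config$qc$sample_call_rate,
                    hwe_alpha = config$qc$hwe_alpha)
  geno <- qc$genotypes
  variants <- cohort$variants[match(colnames(geno), cohort$variants$id), ]
  samples <- cohort$samples[match(rownames(geno), cohort$samples$sample_id), ]

  if (is.null(blocks)) {
    blocks <- gabriel_blocks(
      geno, variants$pos,
      max_markers = config$blocks$max_markers,
      max_span_bp = config$blocks$max_span_bp,
      strong_upper = config$blocks$strong_upper,
      strong_lower = config$blocks$strong_lower,
      recomb_upper = config$blocks$recomb_upper,
      informative_fraction = config$blocks$informative_fraction)
  }
  covars <- NULL
  if (config$assoc$n_pcs > 0) {
    pcs <- pca_covariates(geno, config$assoc$n_pcs)
    covars <- pcs[match(rownames(geno), pcs$sample_id), -1, drop = FALSE]
  }

  hapsets <- list()
  assoc <- list()
  for (r in seq_len(nrow(blocks))) {
    members <- intersect(blocks$members[[r]], colnames(geno))
    if (length(members) < 2L) next
    sub <- geno[, members, drop = FALSE]
    al <- list(ref = variants$ref[match(members, variants$id)],
               alt = variants$alt[match(members, variants$id)])
    hs <- em_haplotype_freqs(sub, block_id = blocks$block_id[r],
                             max_iter = config$phase$max_iter,
                             tol = config$phase$tol, alleles = al)
    hs <- prune_rare(hs, config$phase$min_freq)
    hapsets[[blocks$block_id[r]]] <- hs
    res <- try(block_association(hs, samples$status, covars), silent = TRUE)
    if (!inherits(res, "try-error")) assoc[[blocks$block_id[r]]] <- res
  }
  association <- if (length(assoc)) dplyr::bind_rows(assoc) else tibble::tibble()
  if (nrow(association)) {
    is_block <- association$type == "block"
    association$fdr_q <- NA_real_
    association$fdr_q[is_block] <- bh_fdr(association$p_lrt[is_block])
    class(association) <- c("hap_assoc", class(association))
  }
  out <- list(qc_report = qc$report, blocks = blocks, hapsets = hapsets,
              association = association, config = config)
  if (!is.null(out_dir)) write_stage_outputs(out, cohort, out_dir)
  out
}

write_stage_outputs <- function(stage, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(stage$qc_report, file.path(out_dir, "qc_report.tsv"))
  if (nrow(stage$blocks)) {
    blk <- stage$blocks
    blk$members <- vapply(blk$members, paste, character(1), collapse = ",")
    readr::write_tsv(blk, file.path(out_dir, "blocks.tsv"))
    write_block_json(stage$blocks, file.path(out_dir, "blocks.json"))
  }
  for (nm in names(stage$hapsets)) {
    write_hapset(stage$hapsets[[nm]], file.path(out_dir, paste0("hapset_", nm)))
  }
  if (nrow(stage$association)) {
    assoc <- stage$association
    assoc$dropped <- NULL
    readr::write_tsv(assoc, file.path(out_dir, "association.tsv"))
  }
  log <- list(
    config_hash = rlang::hash(unclass(stage$config)),
    seed = stage$config$seed,
    n_samples = nrow(cohort$genotypes),
    n_variants_in = ncol(cohort$genotypes),
    n_variants_qc = stage$qc_report$n_out[nrow(stage$qc_report)],
    n_blocks = nrow(stage$blocks),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
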