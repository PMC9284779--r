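#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point
#'   geom_errorbarh geom_hline geom_vline scale_fill_gradient labs
#'   theme_minimal scale_x_log10 geom_segment
NULL

#' @export
ggplot2::autoplot

#' Plot a pairwise LD table as a D-prime heatmap
#'
#' @param object An `ld_pairs` tibble from [ld_matrix()].
#' @param stat Which statistic to fill by (`"Dprime"` or `"r2"`).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ld_pairs <- function(object, stat = c("Dprime", "r2"), ...) {
  stat <- match.arg(stat)
  ggplot(object, aes(x = .data$id_i, y = .data$id_j,
                     fill = .data[[stat]])) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        limits = c(0, 1), name = if (stat == "Dprime") "D'" else expression(r^2)) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Forest plot of sub-haplotype odds ratios
#'
#' One point with 95% CI per non-reference sub-haplotype, on a log OR
#' axis.
#'
#' @param object A `hap_assoc` tibble from [block_association()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hap_assoc <- function(object, ...) {
  df <- object[object$type == "haplotype", ]
  ggplot(df, aes(x = .data$or, y = .data$unit)) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(size = 2) +
    scale_x_log10() +
    labs(x = "odds ratio vs reference sub-haplotype (log scale)",
         y = NULL) +
    theme_minimal()
}

#' Forest plot of a pooled meta-analysis result
#'
#' @param object A `meta_result` row (optionally several stacked, e.g.
#'   FE-IV next to RE-DL).
#' @param studies Optional `study_effects` used for the pooling, drawn
#'   above the pooled estimates.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.meta_result <- function(object, studies = NULL, ...) {
  pooled <- tibble::tibble(label = object$method, or = object$or,
                           lo = object$ci_low, hi = object$ci_high,
                           kind = "pooled")
  df <- pooled
  if (!is.null(studies)) {
    df <- dplyr::bind_rows(
      tibble::tibble(label = studies$label, or = exp(studies$b),
                     lo = exp(studies$b - 1.959964 * studies$se),
                     hi = exp(studies$b + 1.959964 * studies$se),
                     kind = "study"),
      pooled)
  }
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot(df, aes(x = .data$or, y = .data$label, colour = .data$kind)) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    geom_point(size = 2) +
    scale_x_log10() +
    labs(x = "odds ratio (log scale)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Block track plot
#'
#' Draws detected blocks as horizontal segments over genomic position,
#' with the per-block omnibus -log10 p when association results are
#' supplied.
#'
#' @param blocks A `block_set` from [gabriel_blocks()].
#' @param association Optional `hap_assoc` tibble containing block rows.
#' @return A ggplot.
#' @export
plot_block_track <- function(blocks, association = NULL) {
  df <- tibble::tibble(block_id = blocks$block_id, start = blocks$start,
                       stop = blocks$stop, y = 0)
  if (!is.null(association)) {
    blk <- association[association$type == "block", ]
    df$y <- -log10(blk$p_lrt[match(df$block_id, blk$unit)])
  }
  ggplot(df, aes(y = .data$y)) +
    geom_segment(aes(x = .data$start, xend = .data$stop,
                     yend = .data$y), linewidth = 3, colour = "steelblue") +
    ggplot2::geom_text(aes(x = (.data$start + .data$stop) / 2,
                           label = .data$block_id), vjust = -1, size = 3) +
    labs(x = "position (bp)",
         y = if (is.null(association)) NULL else expression(-log[10](p))) +
    theme_minimal()
}
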