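#' Volcano plot of a DE table
#'
#' @param object A `deg_table` from [moderated_t_table()].
#' @param fdr_max,fc_min Thresholds drawn and used to color significant
#'   features (defaults 0.05 / 1.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_table <- function(object, fdr_max = 0.05, fc_min = 1.5, ...) {
  lfc <- log2(fc_min)
  df <- tidy(object) |>
    mutate(status = case_when(
      .data$fdr < fdr_max & .data$log2fc > lfc ~ "up",
      .data$fdr < fdr_max & .data$log2fc < -lfc ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_raw),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Connectivity-score profile of a KS screen
#'
#' Lollipop plot of the normalized connectivity scores, most negative (the
#' candidate reversers) first.
#'
#' @param object A `ks_result` from [run_ks_query()].
#' @param top Number of instances shown from the reversing end (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ks_result <- function(object, top = 20, ...) {
  df <- head(tidy(object), top) |>
    mutate(label = paste0(.data$perturbagen, " [", .data$instance_id, "]"))
  ggplot2::ggplot(df, ggplot2::aes(.data$connectivity,
                                   stats::reorder(.data$label,
                                                  -.data$connectivity))) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$connectivity,
                                       yend = stats::reorder(.data$label,
                                                             -.data$connectivity)),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "connectivity score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Reversal heat map
#'
#' Drugs x genes tile plot of a [reversal_matrix()]: reversed genes in
#' blue, aggravated genes in red, untouched in white. Row order follows the
#' supplied matrix (pass rows in [cluster_drugs()] leaf order to mirror the
#' dendrogram).
#'
#' @param object A `reversal_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reversal_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    drug = factor(rep(rownames(m), times = ncol(m)),
                  levels = rev(rownames(m))),
    gene = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    effect = factor(c("aggravated", "untouched", "reversed")[as.vector(m) + 2],
                    levels = c("reversed", "untouched", "aggravated"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$gene, .data$drug,
                                   fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(reversed = "#2166ac",
                                          untouched = "white",
                                          aggravated = "#b2182b")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Enrichment dot plot
#'
#' @param object An `enrichment_result` from [enrich()].
#' @param top Number of top sets shown (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- head(as_tibble(unclass(object)), top)
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_over),
                                   stats::reorder(.data$set_name,
                                                  -.data$p_over),
                                   size = .data$k)) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "-log10 over-representation p", y = NULL,
                  size = "genes") +
    ggplot2::theme_minimal()
}
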