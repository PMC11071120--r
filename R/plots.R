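# ggplot2 views of the main result types. All plot functions return the
# ggplot object so callers can restyle them.

#' Plot fitted vs observed expression
#'
#' @param object A `regdom_fit`.
#' @param ... Unused.
#' @return A ggplot: observed log10(TPM+1) against fitted values, with the
#'   identity line.
#' @export
autoplot.regdom_fit <- function(object, ...) {
  df <- tibble(fitted = object$fitted,
               observed = object$fitted + object$residuals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "fitted log10(TPM + 1)", y = "observed log10(TPM + 1)",
      subtitle = sprintf("RSE %.3f, r %.3f", object$rse, object$pearson_r)
    )
}

#' Plot an RC ensemble
#'
#' Mean regression coefficient per feature, colored by compartment;
#' significant features (when tested) are labeled solid.
#'
#' @param object A `regdom_ensemble`.
#' @param top Show only the `top` features by |mean RC|.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regdom_ensemble <- function(object, top = 30L, ...) {
  df <- as_tibble(object) |>
    arrange(dplyr::desc(abs(.data$mean_rc))) |>
    head(top) |>
    mutate(feature = stats::reorder(.data$feature, .data$mean_rc))
  if (!"significant" %in% names(df)) df$significant <- TRUE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rc, y = .data$feature,
                                   fill = .data$location,
                                   alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "mean RC (activator > 0 > repressor)", y = NULL)
}

#' Plot a clustered embedding
#'
#' @param object A `regdom_embedding`.
#' @param ... Unused.
#' @return A ggplot of the t-SNE plane, points colored by cluster and
#'   shaped by vertex type when available.
#' @export
autoplot.regdom_embedding <- function(object, ...) {
  df <- object$coords |>
    mutate(type = sub(":.*$", "", .data$vertex),
           cluster = factor(.data$cluster))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$cluster))
  if (length(unique(df$type)) > 1) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$type), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}

#' Plot a motif's positional histogram
#'
#' Observed vs random hit density across promoter bins with the derived
#' positional weight.
#'
#' @param histograms A `regdom_histograms` tibble.
#' @param motif_id Motif to plot.
#' @return A ggplot.
#' @export
plot_positional_histogram <- function(histograms, motif_id) {
  df <- histograms[histograms$motif_id == motif_id, , drop = FALSE]
  if (nrow(df) == 0) abort(paste0("no histogram for motif ", motif_id))
  long <- tidyr::pivot_longer(as_tibble(df),
                              c("d_obs", "d_rnd", "weight"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "promoter bin (0 = farthest upstream)", y = NULL,
                  title = motif_id)
}

#' Plot per-gene effect partitions
#'
#' Stacked proportions of promoter/LRC, activating/repressive contributions
#' per gene, genes ordered by their LRC share.
#'
#' @param partitions Output of [partition_effects()].
#' @return A ggplot.
#' @export
plot_effect_partition <- function(partitions) {
  df <- partitions |>
    filter(!.data$degenerate) |>
    mutate(lrc_share = .data$lrc_pos + .data$lrc_neg,
           gene_id = stats::reorder(.data$gene_id, .data$lrc_share)) |>
    tidyr::pivot_longer(c("prm_pos", "prm_neg", "lrc_pos", "lrc_neg"),
                        names_to = "class", values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$proportion,
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "gene", y = "proportion of |effect|")
}
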