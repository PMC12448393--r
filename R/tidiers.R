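# broom-style accessors and ggplot2 views of fitted models and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training trace
#'
#' @param x An `ecfusion_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `phase`, `loss`, `lr`.
#' @method tidy ecfusion_fit
#' @export
tidy.ecfusion_fit <- function(x, ...) {
  tibble::as_tibble(x$trace)
}

#' One-row summary of a fitted model
#'
#' @param x An `ecfusion_fit`.
#' @param ... Unused.
#' @return Tibble: architecture dimensions, parameter count, label-space
#'   sizes, final loss of each phase.
#' @method glance ecfusion_fit
#' @export
glance.ecfusion_fit <- function(x, ...) {
  tr <- x$trace
  final_loss <- function(ph) {
    v <- tr$loss[tr$phase == ph]
    if (length(v) == 0L) NA_real_ else v[length(v)]
  }
  sizes <- label_space_sizes(x$spaces)
  tibble::tibble(n_feat = x$config$n_feat, n_heads = x$config$n_heads,
                 n_blocks = x$config$n_blocks,
                 n_parameters = length(tree_flatten(x$params)),
                 n_labels_level4 = sizes[4],
                 final_triplet_loss = final_loss(1L),
                 final_bce = final_loss(2L))
}

#' Plot the two-phase training trace
#'
#' @param object An `ecfusion_fit`.
#' @param ... Unused.
#' @return A ggplot: loss per epoch, faceted by training phase (free y
#'   scales, since triplet and BCE losses live on different scales).
#' @method autoplot ecfusion_fit
#' @export
autoplot.ecfusion_fit <- function(object, ...) {
  df <- dplyr::mutate(object$trace,
                      phase = factor(.data$phase, 1:2,
                                     c("phase 1 (triplet)", "phase 2 (BCE)")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase), scales = "free") +
    ggplot2::labs(x = "epoch", y = "mean loss") +
    ggplot2::theme_minimal()
}

#' Plot per-digit F1 across EC levels
#'
#' @param per_digit Tibble from [per_digit_metrics()].
#' @return A ggplot of precision/recall/F1 per EC level.
#' @export
plot_per_digit <- function(per_digit) {
  df <- tidyr::pivot_longer(per_digit, c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$level), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "EC level (digit)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot frequency-binned F1
#'
#' @param binned Tibble from [bin_by_frequency()].
#' @return A ggplot: mean per-EC F1 per training-frequency bin.
#' @export
plot_binned_f1 <- function(binned) {
  df <- dplyr::mutate(binned, bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "EC training frequency bin", y = "mean per-EC F1") +
    ggplot2::theme_minimal()
}

#' Plot per-residue attention importance for one protein
#'
#' @param importance Tibble from [importance_table()].
#' @param protein_id Protein to plot (default: first).
#' @param motifs Optional motif tibble (`protein_id`, `start`, `end`) to
#'   shade the planted functional-site window.
#' @return A ggplot of importance score by residue index.
#' @export
plot_importance <- function(importance, protein_id = NULL, motifs = NULL) {
  if (is.null(protein_id)) protein_id <- importance$protein_id[1]
  df <- importance[importance$protein_id == protein_id, ]
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_index, y = .data$score))
  if (!is.null(motifs)) {
    mt <- motifs[motifs$protein_id == protein_id, ]
    if (nrow(mt) > 0L) {
      g <- g + ggplot2::annotate("rect", xmin = mt$start - 0.5, xmax = mt$end + 0.5,
                                 ymin = -Inf, ymax = Inf, alpha = 0.2,
                                 fill = "orange")
    }
  }
  g + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue (1-based)", y = "attention importance",
                  title = protein_id) +
    ggplot2::theme_minimal()
}
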