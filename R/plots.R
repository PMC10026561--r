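#' Plot motif enrichment
#'
#' Bar chart of mean percentile per motif with the 50th-percentile null
#' reference; error bars show the s.e.m. across ensemble members when
#' available.
#'
#' @param enrich A [motif_enrichment()] tibble.
#' @return A ggplot object.
#' @export
plot_motif_enrichment <- function(enrich) {
  enrich$motif <- factor(enrich$motif, levels = unique(enrich$motif))
  p <- ggplot2::ggplot(enrich,
                       ggplot2::aes(x = .data$motif,
                                    y = .data$mean_percentile)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean percentile") +
    ggplot2::theme_minimal()
  if (any(is.finite(enrich$sem))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percentile - .data$sem,
                   ymax = .data$mean_percentile + .data$sem),
      width = 0.3)
  }
  p
}

#' Plot the motif-pair enrichment matrix
#'
#' Heat map of mean percentile per unordered motif pair (shown symmetric).
#'
#' @param pairs A [pair_enrichment()] tibble.
#' @return A ggplot object.
#' @export
plot_pair_matrix <- function(pairs) {
  full <- dplyr::bind_rows(
    pairs,
    dplyr::rename(pairs[pairs$motif_a != pairs$motif_b, ],
                  motif_a = "motif_b", motif_b = "motif_a")
  )
  lev <- unique(c(pairs$motif_a, pairs$motif_b))
  full$motif_a <- factor(full$motif_a, levels = lev)
  full$motif_b <- factor(full$motif_b, levels = lev)
  ggplot2::ggplot(full, ggplot2::aes(x = .data$motif_a, y = .data$motif_b,
                                     fill = .data$mean_percentile)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 50, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  name = "mean\npercentile") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot positional motif effects
#'
#' Heat map of mean percentile per motif and slot; empty cells are slots a
#' motif never occupies in the analysed library.
#'
#' @param positions A [position_enrichment()] tibble.
#' @return A ggplot object.
#' @export
plot_position_effects <- function(positions) {
  positions$motif <- factor(positions$motif, levels = unique(positions$motif))
  ggplot2::ggplot(positions,
                  ggplot2::aes(x = .data$position, y = .data$motif,
                               fill = .data$mean_percentile)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 50, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  name = "mean\npercentile",
                                  na.value = "grey90") +
    ggplot2::labs(x = "slot", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted versus observed phenotype
#'
#' @param model A trained [train_ensemble()] model.
#' @param records Screen records with the model's phenotype.
#' @return A ggplot object.
#' @export
plot_prediction_fit <- function(model, records) {
  df <- tibble::tibble(
    observed = records[[model$phenotype]],
    predicted = predict(model, records$domain_label)$mean
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste("observed", model$phenotype),
                  y = paste("predicted", model$phenotype)) +
    ggplot2::theme_minimal()
}
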