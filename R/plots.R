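#' Plot an SDEM as a heatmap
#'
#' Mean histogram entropy by sample size (rows) and true sigma (columns);
#' the negative small-sample bias is visible as the vertical gradient.
#'
#' @param object An [build_sdem()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdem <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sigma, y = .data$n, fill = .data$mean)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mean entropy (nats)") +
    ggplot2::labs(x = expression(sigma ~ "(bp)"), y = "tags sampled (n)",
                  title = "SDEM: mean histogram entropy per sampling scenario")
}

#' Plot an ROC curve
#'
#' @param object A [roc_classification()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tss_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Narrow/broad classification (AUC = %.3f)",
                                  attr(object, "auc")))
}

#' Plot mark classes in correlation space
#'
#' Scatter of each mark's Pol II vs H2A.Z correlation, coloured by Class I /
#' Class II assignment; separated clusters reproduce the bimodal correlation
#' structure the classification rests on.
#'
#' @param object A [kmeans_two_classes()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mark_classes <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pcc_polII, y = .data$pcc_h2az,
                                       colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PCC with Pol II", y = "PCC with H2A.Z",
                  colour = "Class",
                  title = "Histone-mark classes by nucleosome-proxy correlation")
}

#' Predictive power by model size
#'
#' Mean CV PCC (and BIC) of the best model per size class, the plateau view
#' of how many features suffice.
#'
#' @param best_by_k A tibble with columns `k`, `mean_pcc` (one row per model
#'   size, e.g. the top model of each [enumerate_models()] run).
#' @return A ggplot.
#' @export
plot_model_performance <- function(best_by_k) {
  ggplot2::ggplot(best_by_k, ggplot2::aes(x = factor(.data$k), y = .data$mean_pcc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Model size (features)", y = "Mean CV PCC",
                  title = "Predictive power by model size")
}
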