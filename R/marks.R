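#' Correlate histone marks with nucleosome-proxy references
#'
#' Computes, across promoters, the Pearson correlation of each mark's
#' window-aggregated level with the Pol II and H2A.Z reference levels (both
#' strong proxies for promoter nucleosome organisation), plus their mean as a
#' summary. A zero-variance column yields PCC 0 with a warning.
#'
#' @param features Tibble with `promoter_id` and one column per mark.
#' @param references Tibble with `promoter_id`, `polII`, `h2az`.
#' @param marks Mark column names; defaults to every non-id column of
#'   `features`.
#' @return A tibble: `mark`, `pcc_polII`, `pcc_h2az`, `summary_pcc`.
#' @export
mark_reference_pcc <- function(features, references, marks = NULL) {
  if (is.null(marks)) marks <- setdiff(names(features), "promoter_id")
  stopifnot(all(c("promoter_id", "polII", "h2az") %in% names(references)))
  joined <- dplyr::inner_join(features[c("promoter_id", marks)], references,
                              by = "promoter_id")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rlang::warn("Zero-variance column in correlation; PCC set to 0.")
      0
    } else {
      stats::cor(x, y)
    }
  }
  tibble::tibble(
    mark = marks,
    pcc_polII = vapply(marks, function(m) safe_cor(joined[[m]], joined$polII),
                       numeric(1), USE.NAMES = FALSE),
    pcc_h2az = vapply(marks, function(m) safe_cor(joined[[m]], joined$h2az),
                      numeric(1), USE.NAMES = FALSE)
  ) |>
    dplyr::mutate(summary_pcc = (.data$pcc_polII + .data$pcc_h2az) / 2)
}

#' Two-class k-means of mark/nucleosome correlations
#'
#' Clusters the (Pol II, H2A.Z) correlation pairs of all marks into two
#' groups with seeded multi-restart k-means. The cluster with the higher
#' centroid summary correlation is Class I (nucleosome-correlated, active
#' type); the other is Class II.
#'
#' @param correlations A [mark_reference_pcc()] tibble.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random initialisations; the lowest
#'   within-cluster SSE wins. Default 10.
#' @return The input tibble with a `class` column (`"I"` / `"II"`), of class
#'   `mark_classes`; centroids are in `attr(, "centers")`.
#' @export
kmeans_two_classes <- function(correlations, seed = 1, restarts = 10) {
  stopifnot(nrow(correlations) >= 2)
  pts <- as.matrix(correlations[c("pcc_polII", "pcc_h2az")])
  if (all(apply(pts, 2, stats::sd) == 0)) {
    rlang::abort("All marks have identical correlation pairs; no two-class structure to recover.")
  }
  set.seed(as.integer(seed))
  if (nrow(pts) == 2L) {
    # two marks: each is its own cluster
    cluster <- 1:2
    centers <- pts
  } else {
    km <- stats::kmeans(pts, centers = 2, nstart = restarts)
    cluster <- km$cluster
    centers <- km$centers
  }
  # relabel by centroid summary correlation so Class I is deterministic
  centroid_summary <- rowMeans(centers)
  class_of_cluster <- unname(ifelse(rank(-centroid_summary, ties.method = "first") == 1,
                                    "I", "II"))
  out <- dplyr::mutate(correlations, class = class_of_cluster[cluster])
  class(out) <- c("mark_classes", class(out))
  attr(out, "centers") <- unname(centers[order(-centroid_summary), , drop = FALSE])
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Cross-class versus same-class 2-model comparison
#'
#' Partitions two-feature models over classified marks into cross-class (one
#' Class I + one Class II mark) and same-class pairs and compares their
#' predictive power: the signature of a bivalent-like chromatin code is that
#' cross-class pairs predict TSS entropy better. Models containing marks
#' outside the classification (or in `exclude`) are ignored.
#'
#' @param results A `tss_models` tibble of 2-models (typically after
#'   [best_models()]).
#' @param classes A [kmeans_two_classes()] tibble.
#' @param exclude Optional character vector of marks to drop from the
#'   comparison (e.g. Class II marks that also signal transcription when in
#'   gene bodies, as a bias control).
#' @return A tibble with rows `cross` and `same`: `partition`, `n`,
#'   `mean_pcc`, `sd_pcc`; the difference of means (cross minus same) is in
#'   `attr(, "diff_means")`.
#' @export
bivalent_comparison <- function(results, classes, exclude = NULL) {
  cls <- stats::setNames(classes$class, classes$mark)
  keep_marks <- setdiff(names(cls), exclude)
  rows <- purrr::map_chr(results$features, function(f) {
    if (length(f) != 2 || !all(f %in% keep_marks)) return(NA_character_)
    if (cls[f[1]] == cls[f[2]]) "same" else "cross"
  })
  out <- tibble::tibble(partition = c("cross", "same")) |>
    dplyr::left_join(
      tibble::tibble(partition = rows, mean_pcc_i = results$mean_pcc) |>
        dplyr::filter(!is.na(.data$partition)) |>
        dplyr::summarise(n = dplyr::n(), mean_pcc = mean(.data$mean_pcc_i),
                         sd_pcc = stats::sd(.data$mean_pcc_i), .by = "partition"),
      by = "partition"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  attr(out, "diff_means") <- out$mean_pcc[out$partition == "cross"] -
    out$mean_pcc[out$partition == "same"]
  out
}
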