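#' Configuration of an end-to-end analysis run
#'
#' Bundles all stage parameters with a single master seed; every stochastic
#' stage (SDEM build, CV folds, k-means restarts, simulation) draws from a
#' stream derived deterministically from it, so a rerun with the same config
#' is byte-identical.
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL` when `inputs`
#'   are given.
#' @param inputs Real-data mode: a list with paths `promoters` (BED6+1),
#'   `ctss` (CTSS tags), `feature_matrix` (TSV: `promoter_id` + feature
#'   columns) and `feature_info` (TSV: `feature`, `type`); optional
#'   `references` columns `polII`/`h2az` inside the feature matrix enable
#'   mark classification.
#' @param sdem_n_max,sdem_sigma_max,sdem_B SDEM build parameters.
#' @param sdem_dir Optional directory of a pre-built SDEM ([write_sdem()]);
#'   when given, the build stage is skipped.
#' @param alpha Likelihood window half-width. Default 0.1.
#' @param min_reads Depth filter (strict). Default 10.
#' @param window Core promoter half-width (bp). Default 1000.
#' @param n_folds CV folds. Default 5.
#' @param ks Model sizes to enumerate. Default `c(1, 2, 3)`.
#' @param include_full Whether to also fit the full model. Default `TRUE`.
#' @param pcc_threshold Best-model threshold. Default 0.1.
#' @param label_sigma_cut Narrow/broad boundary for the synthetic ROC stage.
#' @param seed Master seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), inputs = NULL,
                       sdem_n_max = 200, sdem_sigma_max = 100, sdem_B = 50,
                       sdem_dir = NULL, alpha = 0.1, min_reads = 10,
                       window = 1000, n_folds = 5, ks = c(1, 2, 3),
                       include_full = TRUE, pcc_threshold = 0.1,
                       label_sigma_cut = 10, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim` mapping is
#' passed to [sim_config()].
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    rlang::abort("Package 'yaml' is required to read YAML run configs.")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) tags and features, build (or load) the SDEM, estimate
#' adjusted TSS entropies, enumerate k-feature models per CpG class, classify
#' histone marks, run the bivalent comparison and the narrow/broad ROC, and
#' write every result as TSV plus a JSON manifest. Outputs are a pure
#' function of (inputs, config, master seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly. Side effect: files `entropy.tsv`,
#'   `features.tsv`, `models_<class>_k<k>.tsv`, `best_model_summary.tsv`,
#'   `feature_composition.tsv`, `mark_classes.tsv`, `bivalent_report.tsv`,
#'   `roc.tsv`, `manifest.json` (stages that cannot run are skipped with a
#'   message and recorded in the manifest).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  notices <- character(0)
  note <- function(msg) {
    notices <<- c(notices, msg)
    rlang::inform(paste0("[pipeline] ", msg))
  }

  # --- stage: inputs ---------------------------------------------------
  if (!is.null(config$inputs)) {
    promoters <- read_promoters(config$inputs$promoters, window = config$window)
    tags <- tags_from_ctss(read_ctss(config$inputs$ctss), promoters,
                           window = config$window)
    features <- readr::read_tsv(config$inputs$feature_matrix,
                                show_col_types = FALSE, progress = FALSE)
    feature_info <- readr::read_tsv(config$inputs$feature_info,
                                    show_col_types = FALSE, progress = FALSE)
    references <- if (all(c("polII", "h2az") %in% names(features))) {
      features[c("promoter_id", "polII", "h2az")]
    }
    features <- features[setdiff(names(features), c("polII", "h2az"))]
    truth <- NULL
    cpg_table <- promoters[c("promoter_id", "cpg_class")]
  } else {
    ds <- simulate_dataset(config$sim)
    tags <- ds$tags; truth <- ds$truth
    features <- ds$features; feature_info <- ds$feature_info
    references <- ds$references
    cpg_table <- truth[c("promoter_id", "cpg_class")]
  }
  note(sprintf("inputs: %d promoters, %d tags, %d features.",
               nrow(cpg_table), nrow(tags), ncol(features) - 1L))

  # --- stage: SDEM -----------------------------------------------------
  sdem <- if (!is.null(config$sdem_dir)) {
    read_sdem(config$sdem_dir)
  } else {
    build_sdem(config$sdem_n_max, config$sdem_sigma_max, config$sdem_B,
               seed = derive_seed(config$seed, 11L))
  }

  # --- stage: entropy --------------------------------------------------
  entropy <- estimate_entropy(tags, sdem, alpha = config$alpha,
                              min_reads = config$min_reads,
                              window = config$window)
  readr::write_tsv(entropy, file.path(out_dir, "entropy.tsv"))
  readr::write_tsv(features, file.path(out_dir, "features.tsv"))
  note(sprintf("entropy: %d of %d promoters pass the >%d-read filter.",
               nrow(entropy), nrow(cpg_table), config$min_reads))

  manifest <- list(
    package = as.character(utils::packageVersion("tssentropy")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_promoters = nrow(cpg_table),
    n_tags = nrow(tags),
    n_estimated = nrow(entropy)
  )

  if (nrow(entropy) < 3 * config$n_folds) {
    note("too few estimated promoters; model selection, mark classification and ROC skipped.")
    manifest$skipped <- c("model_selection", "mark_classification", "roc")
    manifest$notices <- notices
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out_dir))
  }

  # --- stage: model selection per CpG class ----------------------------
  model_data <- entropy["promoter_id"] |>
    dplyr::mutate(H_adj = entropy$H_adj) |>
    dplyr::inner_join(features, by = "promoter_id")
  parts <- split_by_cpg(model_data, cpg_table)
  feat_cols <- setdiff(names(features), "promoter_id")
  ks <- config$ks
  if (isTRUE(config$include_full)) ks <- c(ks, length(feat_cols))
  ks <- unique(pmin(ks, length(feat_cols)))
  summaries <- list(); compositions <- list(); best2 <- list()
  for (cls in names(parts)) {
    part <- parts[[cls]]
    if (nrow(part) < 3 * config$n_folds) {
      note(sprintf("model selection skipped for %s (only %d promoters).", cls, nrow(part)))
      next
    }
    for (k in ks) {
      res <- enumerate_models(part, "H_adj", features = feat_cols, k = k,
                              n_folds = config$n_folds,
                              seed = derive_seed(config$seed, 23L))
      readr::write_tsv(flatten_models(res),
                       file.path(out_dir, sprintf("models_%s_k%d.tsv", cls, k)))
      bm <- best_models(res, config$pcc_threshold)
      summaries[[length(summaries) + 1L]] <- dplyr::mutate(
        glance(res), cpg_class = cls, n_best = nrow(bm), .before = 1)
      if (nrow(bm)) {
        compositions[[length(compositions) + 1L]] <- dplyr::mutate(
          feature_composition(bm, feature_info), cpg_class = cls, .before = 1)
      }
      if (k == 2) best2[[cls]] <- bm
    }
  }
  readr::write_tsv(dplyr::bind_rows(summaries),
                   file.path(out_dir, "best_model_summary.tsv"))
  readr::write_tsv(dplyr::bind_rows(compositions),
                   file.path(out_dir, "feature_composition.tsv"))

  # --- stage: mark classification + bivalent report --------------------
  hm_marks <- feature_info$feature[feature_info$type == "HM"]
  if (is.null(references) || length(hm_marks) < 2) {
    note("mark classification skipped (no references or fewer than 2 HM marks).")
    manifest$skipped <- c(manifest$skipped, "mark_classification")
  } else {
    cors <- mark_reference_pcc(features, references, marks = hm_marks)
    classes <- kmeans_two_classes(cors, seed = derive_seed(config$seed, 31L))
    readr::write_tsv(tibble::as_tibble(classes), file.path(out_dir, "mark_classes.tsv"))
    reports <- purrr::imap(best2, function(bm, cls) {
      if (nrow(bm) == 0) return(NULL)
      dplyr::mutate(bivalent_comparison(bm, classes), cpg_class = cls, .before = 1)
    })
    readr::write_tsv(dplyr::bind_rows(reports), file.path(out_dir, "bivalent_report.tsv"))
  }

  # --- stage: ROC ------------------------------------------------------
  if (!is.null(truth) && length(best2) && nrow(best2[[1]])) {
    cls <- names(best2)[1]
    part <- parts[[cls]]
    model <- best2[[cls]][1, ]
    pred <- drop(as.matrix(part[model$features[[1]]]) %*% model$coefficients[[1]]) +
      model$intercept
    labels <- label_promoters(truth[match(part$promoter_id, truth$promoter_id), ],
                              sigma_cut = config$label_sigma_cut)
    if (length(unique(labels)) == 2) {
      roc <- roc_classification(pred, labels)
      readr::write_tsv(tibble::as_tibble(roc), file.path(out_dir, "roc.tsv"))
      manifest$roc_auc <- attr(roc, "auc")
      manifest$roc_cpg_class <- cls
    } else {
      note("ROC skipped (single shape class in this partition).")
    }
  } else if (is.null(truth)) {
    note("ROC skipped (no ground-truth shape labels in real-data mode).")
  }

  manifest$notices <- notices
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# flat TSV representation of a tss_models tibble
flatten_models <- function(results) {
  tibble::tibble(
    features = purrr::map_chr(results$features, paste, collapse = "+"),
    k = results$k,
    intercept = results$intercept,
    coefficients = purrr::map_chr(results$coefficients, function(b) {
      paste(sprintf("%s=%.10g", names(b), b), collapse = ";")
    }),
    fold_pcc = purrr::map_chr(results$fold_pcc, function(p) {
      paste(sprintf("%.10g", p), collapse = ";")
    }),
    mean_pcc = results$mean_pcc,
    bic = results$bic,
    n_obs = results$n_obs
  )
}
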