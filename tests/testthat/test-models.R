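test_that("OLS matches hand-computed normal equations", {
  fit <- fit_ols(cbind(x = c(0, 1, 2)), c(0, 1, 3))
  expect_equal(unname(fit$coefficients), 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, -1 / 6, tolerance = 1e-12)
  # exact linear response: zero residual, exact recovery
  x <- cbind(a = rnorm(20))
  fit2 <- fit_ols(x, 3 + 2 * x[, 1])
  expect_equal(fit2$rss, 0, tolerance = 1e-18)
  expect_equal(unname(fit2$coefficients), 2, tolerance = 1e-9)
  # constant response: zero slope, intercept = mean
  fit3 <- fit_ols(x, rep(5, 20))
  expect_equal(unname(fit3$coefficients), 0, tolerance = 1e-9)
  expect_equal(fit3$intercept, 5, tolerance = 1e-12)
  expect_error(fit_ols(cbind(a = x[, 1], b = x[, 1]), rnorm(20)), "collinear")
})

test_that("BIC arithmetic penalises parameters by log(n)", {
  expect_equal(bic_score(10, 100, 2) - bic_score(10, 100, 1), log(100), tolerance = 1e-12)
  expect_warning(b0 <- bic_score(0, 100, 1))
  expect_identical(b0, -Inf)
})

test_that("CV folds partition the data evenly and deterministically", {
  f1 <- cv_folds(103, 5, seed = 9)
  f2 <- cv_folds(103, 5, seed = 9)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  sizes <- table(f1)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 103)
  expect_false(identical(f1, cv_folds(103, 5, seed = 10)))
})

test_that("cv_pcc finds planted signal, scores null features near zero, is seeded", {
  set.seed(51)
  n <- 1000
  dat <- tibble::tibble(x = rnorm(n), z = rnorm(n))
  dat$y <- 2 * dat$x + rnorm(n, 0, 0.8)
  m <- cv_pcc(dat, "y", "x", seed = 1)
  expect_gt(m$mean_pcc, 0.8)
  expect_equal(m$mean_pcc, mean(m$fold_pcc[[1]]))
  expect_length(m$fold_pcc[[1]], 5)
  expect_true(all(abs(m$fold_pcc[[1]]) <= 1))
  expect_identical(m$mean_pcc, cv_pcc(dat, "y", "x", seed = 1)$mean_pcc)
  # null feature
  nulls <- vapply(1:10, function(s) {
    set.seed(s + 500)
    d <- tibble::tibble(x = rnorm(n), y = rnorm(n))
    cv_pcc(d, "y", "x", seed = s)$mean_pcc
  }, numeric(1))
  expect_gte(mean(abs(nulls) < 0.08), 0.9)
})

test_that("a zero-variance prediction fold scores PCC 0 with a warning", {
  dat <- tibble::tibble(x = rnorm(50), y = rep(1, 50))
  expect_warning(m <- cv_pcc(dat, "y", "x", seed = 1), "Zero-variance")
  expect_equal(m$mean_pcc, 0)
})

test_that("exhaustive enumeration ranks the planted feature first", {
  set.seed(61)
  n <- 600
  dat <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 10), n,
                                                dimnames = list(NULL, paste0("f", 1:10)))))
  dat$y <- dat$f3 + rnorm(n, 0, 0.7)
  m1 <- enumerate_models(dat, "y", k = 1, seed = 5)
  expect_equal(nrow(m1), 10)
  expect_equal(m1$features[[1]], "f3")
  expect_true(all(diff(m1$mean_pcc) <= 0))
  # k = n_features collapses to the single full model
  mfull <- enumerate_models(dat, "y", k = "full", seed = 5)
  expect_equal(nrow(mfull), 1)
  expect_equal(mfull$k, 10)
  expect_error(enumerate_models(dat, "y", k = 11))
})

test_that("greedy beam search agrees with exhaustive search on a small pool", {
  set.seed(62)
  n <- 500
  dat <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 10), n,
                                                dimnames = list(NULL, paste0("f", 1:10)))))
  dat$y <- dat$f2 + 0.8 * dat$f7 + rnorm(n, 0, 0.5)
  ex <- enumerate_models(dat, "y", k = 2, seed = 3, strategy = "exhaustive")
  expect_message(gr <- enumerate_models(dat, "y", k = 2, seed = 3, strategy = "greedy"),
                 "greedy")
  expect_equal(sort(ex$features[[1]]), sort(gr$features[[1]]))
  expect_equal(ex$mean_pcc[1], gr$mean_pcc[1])
})

test_that("best-model filtering and feature composition behave", {
  ds <- shared_dataset()
  dat <- dplyr::inner_join(ds$truth[, c("promoter_id", "entropy_true")],
                           ds$features, by = "promoter_id")
  m2 <- enumerate_models(dat, "entropy_true", k = 2, seed = 17)
  expect_equal(nrow(best_models(m2, pcc_threshold = 1.1)), 0)
  bm <- best_models(m2)
  expect_true(all(bm$mean_pcc > 0.1))
  comp_top <- feature_composition(utils::head(bm, 20), ds$feature_info)
  expect_gte(comp_top$fraction[comp_top$type == "HM"], 0.9)
  comp_all <- feature_composition(bm, ds$feature_info)
  expect_equal(sum(comp_all$fraction), 1)
  expect_gt(comp_all$fraction[comp_all$type == "HM"], 0.5)
})

test_that("an all-inert pool yields an empty or near-empty best-model set", {
  cfg <- sim_config(n_promoters = 1000, c_active = 0, c_repressive = 0, seed = 23)
  ds <- simulate_dataset(cfg)
  dat <- dplyr::inner_join(ds$truth[, c("promoter_id", "entropy_true")],
                           ds$features, by = "promoter_id")
  m1 <- enumerate_models(dat, "entropy_true", k = 1, seed = 2)
  expect_lte(nrow(best_models(m1)), 2)
})

test_that("model performance grows with size up to the full-model plateau", {
  ds <- shared_dataset()
  dat <- dplyr::inner_join(ds$truth[, c("promoter_id", "entropy_true")],
                           ds$features, by = "promoter_id")
  best <- vapply(c(1, 2, 3), function(k) {
    enumerate_models(dat, "entropy_true", k = k, seed = 29)$mean_pcc[1]
  }, numeric(1))
  full <- enumerate_models(dat, "entropy_true", k = "full", seed = 29)$mean_pcc[1]
  path <- c(best, full)
  expect_true(all(diff(path) > -0.02))
})

test_that("transfer keeps frozen coefficients honest", {
  ds <- shared_dataset()
  dat <- dplyr::inner_join(ds$truth[, c("promoter_id", "entropy_true")],
                           ds$features, by = "promoter_id")
  m <- cv_pcc(dat, "entropy_true", c("HM_active_01", "HM_repressive_01"), seed = 3)
  # in-sample application enjoys optimism over CV
  expect_gte(transfer_evaluate(m, dat, "entropy_true"), m$mean_pcc - 1e-9)
  # permuted response: no transferable signal
  set.seed(9)
  perm <- dplyr::mutate(dat, entropy_true = sample(entropy_true))
  expect_lt(abs(transfer_evaluate(m, perm, "entropy_true")), 0.08)
  expect_error(transfer_evaluate(m, dat[, c("promoter_id", "entropy_true")], "entropy_true"),
               "absent")
})

test_that("tidy and glance summarise model sets in broom style", {
  ds <- shared_dataset()
  dat <- dplyr::inner_join(ds$truth[, c("promoter_id", "entropy_true")],
                           ds$features, by = "promoter_id")
  m <- enumerate_models(dat, "entropy_true", features = paste0("HM_active_0", 1:3),
                        k = 2, seed = 4)
  td <- tidy(m)
  expect_true(all(c("model_rank", "term", "estimate", "mean_pcc") %in% names(td)))
  expect_equal(nrow(td), nrow(m) * 2)
  gl <- glance(m)
  expect_equal(gl$n_models, nrow(m))
  expect_equal(gl$best_mean_pcc, m$mean_pcc[1])
})

test_that("ROC sweep matches its definition and the independent pROC oracle", {
  set.seed(71)
  truth <- tibble::tibble(sigma_true = exp(runif(400, log(2), log(80))))
  labels <- label_promoters(truth, sigma_cut = 10)
  # monotone transform of the quantity defining the labels: perfect ranking
  roc1 <- roc_classification(log(truth$sigma_true) * 3 + 1, labels)
  expect_equal(attr(roc1, "auc"), 1)
  # random scores: chance performance
  roc2 <- roc_classification(rnorm(400), labels)
  expect_lt(abs(attr(roc2, "auc") - 0.5), 0.12)
  expect_error(roc_classification(rnorm(5), rep("broad", 5)), "Both classes")
  # cross-check the trapezoid AUC against pROC
  scores <- rnorm(400) + 2 * (labels == "broad")
  got <- attr(roc_classification(scores, labels), "auc")
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c("narrow", "broad"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-9)
  expect_equal(glance(roc2)$auc, attr(roc2, "auc"))
})
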