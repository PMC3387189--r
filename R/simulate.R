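#' Configuration for the synthetic CAGE / chromatin-feature generator
#'
#' The generator is latent-first: it draws a latent nucleosome-organisation
#' signal `N` and an orthogonal latent repressive-chromatin signal `R` per
#' promoter, forms a linear predictor `c_active * N + c_repressive * R +
#' noise`, and maps it affinely onto log-sigma so that true TSS spreads cover
#' `sigma_range` (clamped at the edges). True entropy is the Gaussian entropy
#' of that sigma, so the linear model the selection stage must find exists by
#' construction; the effective (post-scaling) coefficients are recorded in the
#' simulation truth. Active marks are noisy copies of `N`, repressive marks
#' noisy copies of `R`, sequence-motif features pure noise, and the Pol II /
#' H2A.Z nucleosome-proxy references are low-noise copies of `N`.
#'
#' @param n_promoters Number of promoters.
#' @param sigma_range Range (bp) the true sigma is mapped into. Default
#'   `c(2, 80)`.
#' @param depth_mean,depth_dispersion Negative-binomial tag-depth law (mean
#'   and size). Default mean 50, size 5.
#' @param depth_fixed If non-`NULL`, every promoter gets exactly this many
#'   tags, overriding the depth law.
#' @param noise_model Background noise for tags: `"none"`, `"uniform"` over
#'   the core window, or `"gaussian"` with sd `5 * sigma`.
#' @param noise_fraction Expected fraction of tags replaced by background.
#' @param n_active_marks,n_repressive_marks Numbers of histone-mark features
#'   tracking `N` and `R`. Defaults 6 and 6.
#' @param n_sequence_features Number of inert motif-score (SEQ) features.
#' @param include_nu_dnase Whether to add a nucleosome-position (NU) and a
#'   DNase feature, both noisier copies of `N`. Default `TRUE`.
#' @param c_active,c_repressive Latent weights of `N` and `R` in the entropy
#'   predictor. Defaults 0.8 and 0.5.
#' @param entropy_noise_sd Residual sd of the entropy predictor. Default 0.4.
#' @param feature_noise_sd Observation noise sd of histone-mark features.
#' @param nu_dnase_noise_sd Observation noise sd of the NU/DNase features
#'   (noisier proxies than direct ChIP of a mark). Default 1.
#' @param reference_noise_sd Observation noise sd of the Pol II / H2A.Z
#'   reference tracks. Default 0.2.
#' @param cpg_fraction Probability a promoter is CpG-related.
#' @param cpg_logsigma_shift Additive log-sigma shift for CpG promoters (CpG
#'   promoters are broader); non-CpG get the opposite shift. Default 0.3.
#' @param window Core promoter half-width (bp) used for uniform background.
#' @param seed Integer master seed; every stage derives its own stream.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_promoters = 2000,
                       sigma_range = c(2, 80),
                       depth_mean = 50, depth_dispersion = 5, depth_fixed = NULL,
                       noise_model = c("none", "uniform", "gaussian"),
                       noise_fraction = 0,
                       n_active_marks = 6, n_repressive_marks = 6,
                       n_sequence_features = 8, include_nu_dnase = TRUE,
                       c_active = 0.8, c_repressive = 0.5,
                       entropy_noise_sd = 0.4,
                       feature_noise_sd = 0.5, nu_dnase_noise_sd = 1,
                       reference_noise_sd = 0.2,
                       cpg_fraction = 0.5, cpg_logsigma_shift = 0.3,
                       window = 1000, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_promoters >= 0, length(sigma_range) == 2, sigma_range[1] > 0,
            sigma_range[2] > sigma_range[1],
            noise_fraction >= 0, noise_fraction < 1,
            n_active_marks >= 0, n_repressive_marks >= 0,
            n_sequence_features >= 0,
            cpg_fraction >= 0, cpg_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic seed fan-out so that stages draw from independent streams
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 9973) %% 2147483647)
}

#' Simulate CAGE tag samples from planted Gaussian promoters
#'
#' Draws latent signals, maps them to true sigmas and entropies (see
#' [sim_config()]), then samples each promoter's tags from Normal(0, sigma^2)
#' rounded to 1-bp bins, optionally replacing a Binomial(k, noise_fraction)
#' subset with background tags.
#'
#' @param config A [sim_config()].
#' @return A list with `tags` (tibble: `promoter_id`, `offset`) and `truth`
#'   (tibble: `promoter_id`, `cpg_class`, `N`, `R`, `sigma_true`,
#'   `entropy_true`, `k`; the effective planted coefficients are in
#'   `attr(truth, "planted")`).
#' @export
simulate_cage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  set.seed(derive_seed(config$seed, 2L))
  k <- truth$k
  if (sum(k) == 0L) {
    tags <- tibble::tibble(promoter_id = character(0), offset = integer(0))
    return(list(tags = tags, truth = truth))
  }
  sigma_rep <- rep(truth$sigma_true, k)
  offset <- as.integer(round(stats::rnorm(sum(k), 0, sigma_rep)))
  if (config$noise_model != "none" && config$noise_fraction > 0) {
    n_noise <- stats::rbinom(length(k), k, config$noise_fraction)
    # replace the leading n_noise tags of each promoter with background
    idx0 <- cumsum(c(0L, k[-length(k)]))
    noise_at <- unlist(purrr::map2(idx0, n_noise, function(o, m) o + seq_len(m)),
                       use.names = FALSE)
    if (length(noise_at)) {
      bg <- switch(config$noise_model,
        uniform = sample.int(2L * config$window, length(noise_at), replace = TRUE) -
          config$window - 1L,
        gaussian = as.integer(round(stats::rnorm(length(noise_at), 0,
                                                 5 * sigma_rep[noise_at])))
      )
      offset[noise_at] <- bg
    }
  }
  tags <- tibble::tibble(
    promoter_id = rep(truth$promoter_id, k),
    offset = offset
  )
  list(tags = tags, truth = truth)
}

simulate_truth <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_promoters
  N <- stats::rnorm(n)
  R <- stats::rnorm(n)
  eta <- config$c_active * N + config$c_repressive * R +
    stats::rnorm(n, 0, config$entropy_noise_sd)
  ls_mean <- mean(log(config$sigma_range))
  ls_sd <- diff(log(config$sigma_range)) / 4
  eta_sd <- sqrt(config$c_active^2 + config$c_repressive^2 + config$entropy_noise_sd^2)
  b <- ls_sd / eta_sd
  cpg <- stats::runif(n) < config$cpg_fraction
  shift <- ifelse(cpg, config$cpg_logsigma_shift, -config$cpg_logsigma_shift)
  log_sigma <- ls_mean + shift + b * eta
  sigma <- pmin(pmax(exp(log_sigma), config$sigma_range[1]), config$sigma_range[2])
  k <- if (!is.null(config$depth_fixed)) {
    rep(as.integer(config$depth_fixed), n)
  } else {
    stats::rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
  }
  truth <- tibble::tibble(
    promoter_id = sprintf("p%05d", seq_len(n)),
    cpg_class = ifelse(cpg, "CpG", "nonCpG"),
    N = N, R = R,
    sigma_true = sigma,
    entropy_true = if (n > 0) gaussian_entropy(sigma) else numeric(0),
    k = as.integer(k)
  )
  attr(truth, "planted") <- list(
    intercept = 0.5 * log(2 * pi * exp(1)) + ls_mean,
    beta_N = b * config$c_active,
    beta_R = b * config$c_repressive,
    scale = b
  )
  truth
}

#' Simulate the planted chromatin feature pool
#'
#' Builds per-promoter feature columns around the latent signals of a
#' [simulate_cage()] truth table: active histone marks and the NU/DNase
#' proxies are noisy copies of the nucleosome signal `N`, repressive marks
#' noisy copies of the orthogonal signal `R`, and motif-score (SEQ) features
#' pure noise. Pol II and H2A.Z reference tracks are low-noise copies of `N`.
#'
#' @param truth Truth tibble from [simulate_cage()].
#' @param config The same [sim_config()].
#' @return A list with `features` (tibble: `promoter_id` + one column per
#'   feature), `feature_info` (tibble: `feature`, `type` in HM/NU/SEQ/DNase,
#'   `class` in active/repressive/inert) and `references` (tibble:
#'   `promoter_id`, `polII`, `h2az`).
#' @export
simulate_feature_pool <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(truth)
  cols <- list()
  info <- list()
  add <- function(name, values, type, class) {
    cols[[name]] <<- values
    info[[name]] <<- tibble::tibble(feature = name, type = type, class = class)
  }
  for (i in seq_len(config$n_active_marks)) {
    add(sprintf("HM_active_%02d", i),
        truth$N + stats::rnorm(n, 0, config$feature_noise_sd), "HM", "active")
  }
  for (i in seq_len(config$n_repressive_marks)) {
    add(sprintf("HM_repressive_%02d", i),
        truth$R + stats::rnorm(n, 0, config$feature_noise_sd), "HM", "repressive")
  }
  if (isTRUE(config$include_nu_dnase)) {
    add("NU_nucleosome", truth$N + stats::rnorm(n, 0, config$nu_dnase_noise_sd),
        "NU", "active")
    add("DNase", truth$N + stats::rnorm(n, 0, config$nu_dnase_noise_sd),
        "DNase", "active")
  }
  for (i in seq_len(config$n_sequence_features)) {
    add(sprintf("SEQ_cluster_%02d", i), stats::rnorm(n), "SEQ", "inert")
  }
  features <- tibble::as_tibble(c(list(promoter_id = truth$promoter_id), cols))
  references <- tibble::tibble(
    promoter_id = truth$promoter_id,
    polII = truth$N + stats::rnorm(n, 0, config$reference_noise_sd),
    h2az = truth$N + stats::rnorm(n, 0, config$reference_noise_sd)
  )
  list(features = features,
       feature_info = dplyr::bind_rows(info),
       references = references)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_cage()] followed by
#' [simulate_feature_pool()].
#'
#' @inheritParams simulate_cage
#' @return A list with `tags`, `truth`, `features`, `feature_info`,
#'   `references`, `config`.
#' @export
simulate_dataset <- function(config) {
  cage <- simulate_cage(config)
  pool <- simulate_feature_pool(cage$truth, config)
  c(cage, pool, list(config = config))
}

#' Simulate two cell types sharing the planted mechanism
#'
#' Both datasets use the same planted coefficients and feature classes
#' (fixed by `config`) but independent promoters, depths and noise draws, for
#' evaluating cross-cell-type model transfer.
#'
#' @inheritParams simulate_cage
#' @return A list with elements `cell_a` and `cell_b`, each a
#'   [simulate_dataset()] result.
#' @export
simulate_two_celltypes <- function(config) {
  cfg_a <- config; cfg_a$seed <- derive_seed(config$seed, 101L)
  cfg_b <- config; cfg_b$seed <- derive_seed(config$seed, 202L)
  list(cell_a = simulate_dataset(cfg_a), cell_b = simulate_dataset(cfg_b))
}
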