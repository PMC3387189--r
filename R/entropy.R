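#' Differential entropy of a Gaussian TSS model
#'
#' The width of a promoter's TSS distribution is summarised as the Shannon
#' (differential) entropy of the Gaussian assumed to generate its tags,
#' \eqn{H(\sigma) = \tfrac{1}{2}\ln(2\pi e \sigma^2)} in nats.
#'
#' @param sigma Standard deviation in base pairs. Vectorised; all values must
#'   be strictly positive.
#' @param base Logarithm base for the returned value: `"nats"` (default) or
#'   `"log2"`. All internal computation is in nats; `"log2"` only rescales the
#'   output.
#' @return Numeric vector of entropies.
#' @examples
#' gaussian_entropy(1)   # 0.5 * log(2 * pi * exp(1))
#' gaussian_entropy(10) - gaussian_entropy(1)  # log(10)
#' @export
gaussian_entropy <- function(sigma, base = c("nats", "log2")) {
  base <- match.arg(base)
  if (length(sigma) == 0L) return(numeric(0))
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma <= 0)) {
    rlang::abort("`sigma` must be strictly positive (a degenerate point mass has no differential entropy).")
  }
  h <- 0.5 * log(2 * pi * exp(1) * sigma^2)
  if (base == "log2") h / log(2) else h
}

#' Plug-in (histogram) entropy of observed tag offsets
#'
#' The naive estimator \eqn{-\sum_i p(i)\ln p(i)} over 1-bp bins, where
#' \eqn{p(i)} is the fraction of tags at offset \eqn{i}. Negatively biased at
#' low tag counts, which is what the SDEM adjustment corrects.
#'
#' @param offsets Integer vector of tag positions relative to the annotated
#'   TSS (1-bp bins). Must be non-empty.
#' @param base As in [gaussian_entropy()].
#' @return A single entropy in `[0, log(k)]` for `k = length(offsets)`.
#' @examples
#' histogram_entropy(c(5, 5, 5))    # 0: all mass in one bin
#' histogram_entropy(c(0, 1))       # log(2)
#' @export
histogram_entropy <- function(offsets, base = c("nats", "log2")) {
  base <- match.arg(base)
  if (length(offsets) == 0L) {
    rlang::abort("Cannot estimate entropy from an empty tag sample.")
  }
  p <- tabulate(match(offsets, unique(offsets))) / length(offsets)
  h <- -sum(p * log(p))
  if (base == "log2") h / log(2) else h
}

#' Per-promoter tag counts and histogram entropies
#'
#' @param tags A data frame with columns `promoter_id` and `offset` (one row
#'   per tag).
#' @return A tibble with one row per promoter: `promoter_id`, `k`, `U`.
#' @export
tag_entropy <- function(tags) {
  check_tags(tags)
  if (nrow(tags) == 0L) {
    return(tibble::tibble(promoter_id = tags$promoter_id[0], k = integer(0),
                          U = numeric(0)))
  }
  tags |>
    dplyr::summarise(
      k = dplyr::n(),
      U = histogram_entropy(.data$offset),
      .by = "promoter_id"
    )
}

check_tags <- function(tags) {
  if (!is.data.frame(tags) || !all(c("promoter_id", "offset") %in% names(tags))) {
    rlang::abort("`tags` must be a data frame with columns `promoter_id` and `offset`.")
  }
  invisible(tags)
}

#' Build the simulated reference matrix (SDEM) of histogram-entropy moments
#'
#' Each cell (n, sigma) of the SDEM holds the mean and standard deviation of
#' the histogram entropy computed from `B` independent samples of `n` points
#' drawn from Normal(0, sigma^2) and rounded to the nearest base pair
#' (round-half-to-even). Row n corresponds to a promoter sequenced to depth n;
#' column sigma to a promoter whose true TSS spread is sigma bp. The matrix is
#' the lookup table for maximum-likelihood bias correction.
#'
#' @param n_max Largest sample size simulated (rows 1..n_max). Default 200.
#' @param sigma_max Largest sigma simulated (integer columns 1..sigma_max).
#'   Default 100. sigma = 0 is a degenerate point mass and is excluded.
#' @param B Resamples per cell. Default 50.
#' @param seed Integer seed; the build is bit-reproducible given the seed.
#' @return An object of class `"sdem"`: a list with matrices `mean` and `sd`
#'   (`n_max` x `sigma_max`), the grids, `B` and `seed`.
#' @export
build_sdem <- function(n_max = 200, sigma_max = 100, B = 50, seed = 1) {
  stopifnot(n_max >= 1, sigma_max >= 1, B >= 2)
  n_max <- as.integer(n_max); sigma_max <- as.integer(sigma_max); B <- as.integer(B)
  set.seed(as.integer(seed))
  mean_m <- matrix(0, n_max, sigma_max)
  sd_m <- matrix(0, n_max, sigma_max)
  for (s in seq_len(sigma_max)) {
    for (n in seq_len(n_max)) {
      x <- as.integer(round(stats::rnorm(n * B, 0, s)))
      xmin <- min(x)
      K <- max(x) - xmin + 1L
      # one histogram per replicate via a flat (replicate, bin) key
      key <- (rep(seq_len(B), each = n) - 1L) * K + (x - xmin + 1L)
      cnt <- tabulate(key, nbins = B * K)
      nz <- which(cnt > 0L)
      p <- cnt[nz] / n
      ent <- rowsum(-p * log(p), (nz - 1L) %/% K + 1L)
      mean_m[n, s] <- mean(ent)
      sd_m[n, s] <- stats::sd(ent)
    }
  }
  structure(
    list(mean = mean_m, sd = sd_m, n_max = n_max,
         sigma_grid = seq_len(sigma_max), B = B, seed = as.integer(seed)),
    class = "sdem"
  )
}

#' @export
print.sdem <- function(x, ...) {
  cat(sprintf("<SDEM> %d x %d reference matrix (n = 1..%d, sigma = 1..%d), B = %d resamples, seed = %d\n",
              x$n_max, length(x$sigma_grid), x$n_max, max(x$sigma_grid), x$B, x$seed))
  invisible(x)
}

#' @rdname build_sdem
#' @param x An `sdem` object.
#' @param ... Unused.
#' @export
tidy.sdem <- function(x, ...) {
  tidyr::expand_grid(n = seq_len(x$n_max), sigma = x$sigma_grid) |>
    dplyr::mutate(
      mean = as.vector(t(x$mean)),
      sd = as.vector(t(x$sd))
    )
}

# sd floor below which an SDEM cell is treated as degenerate (e.g. row n = 1,
# where every replicate has entropy exactly 0)
.sdem_sd_floor <- 1e-9

#' Maximum-likelihood sigma from an observed histogram entropy
#'
#' Scans row `k` of the SDEM: for each column sigma the likelihood is the
#' normal-CDF mass of the cell's (mean, sd) entropy distribution on the window
#' `[U - alpha, U + alpha]`. The sigma with maximal likelihood wins; ties go
#' to the smallest sigma. Degenerate cells (sd below 1e-9) score 1 when
#' `|U - mean| <= alpha` and 0 otherwise.
#'
#' @param U Observed histogram entropy (nats). Vectorised with `k`.
#' @param k Tag count; values above `sdem$n_max` are clamped to the last row
#'   with a warning.
#' @param sdem An [build_sdem()] object.
#' @param alpha Half-width of the likelihood window. Default 0.1.
#' @return A tibble with columns `sigma_hat` and `likelihood`, one row per
#'   input.
#' @export
infer_sigma <- function(U, k, sdem, alpha = 0.1) {
  stopifnot(inherits(sdem, "sdem"), alpha > 0)
  if (length(k) == 1L && length(U) > 1L) k <- rep(k, length(U))
  if (length(U) != length(k)) rlang::abort("`U` and `k` must have the same length.")
  if (any(k < 1)) rlang::abort("Tag count `k` must be at least 1.")
  if (any(k > sdem$n_max)) {
    rlang::warn(sprintf("%d tag count(s) exceed the SDEM's n_max = %d; clamped to the last row.",
                        sum(k > sdem$n_max), sdem$n_max))
    k <- pmin(k, sdem$n_max)
  }
  res <- purrr::map2(U, as.integer(k), function(u, ki) {
    L <- .row_likelihood(u, ki, sdem, alpha)
    j <- which.max(L) # first max: ties resolved toward smallest sigma
    c(sdem$sigma_grid[j], L[j])
  })
  tibble::tibble(
    sigma_hat = purrr::map_dbl(res, 1),
    likelihood = purrr::map_dbl(res, 2)
  )
}

.row_likelihood <- function(u, k, sdem, alpha) {
  m <- sdem$mean[k, ]
  s <- sdem$sd[k, ]
  L <- numeric(length(m))
  deg <- s < .sdem_sd_floor
  L[deg] <- as.numeric(abs(u - m[deg]) <= alpha)
  if (any(!deg)) {
    L[!deg] <- stats::pnorm((u + alpha - m[!deg]) / s[!deg]) -
      stats::pnorm((u - alpha - m[!deg]) / s[!deg])
  }
  L
}

#' Bias-corrected (adjusted) TSS entropy per promoter
#'
#' Computes the naive histogram entropy `U` per promoter, infers the
#' maximum-likelihood sigma from the SDEM row matching the promoter's tag
#' count, and reports the adjusted entropy as the Gaussian entropy of that
#' sigma. The adjusted entropy is the package's "TSS entropy".
#'
#' @inheritParams tag_entropy
#' @inheritParams infer_sigma
#' @return A tibble with columns `promoter_id`, `k`, `U`, `sigma_hat`,
#'   `H_adj`, `likelihood`.
#' @export
adjusted_entropy <- function(tags, sdem, alpha = 0.1) {
  est <- tag_entropy(tags)
  if (nrow(est) == 0L) {
    return(dplyr::mutate(est, sigma_hat = numeric(0), H_adj = numeric(0),
                         likelihood = numeric(0)))
  }
  inf <- infer_sigma(est$U, est$k, sdem, alpha)
  est |>
    dplyr::mutate(
      sigma_hat = inf$sigma_hat,
      H_adj = gaussian_entropy(inf$sigma_hat),
      likelihood = inf$likelihood
    )
}

#' Keep promoters with sufficient sequencing depth
#'
#' Retains promoters whose tag count is strictly greater than `min_reads`
#' (default 10), the depth below which the entropy estimate no longer
#' converges usefully.
#'
#' @inheritParams tag_entropy
#' @param min_reads Strict lower bound on tag count. Default 10, i.e. a
#'   promoter needs more than 10 reads to be kept.
#' @return The filtered tag tibble.
#' @export
filter_promoters <- function(tags, min_reads = 10) {
  check_tags(tags)
  stopifnot(min_reads >= 0)
  tags |>
    dplyr::mutate(.k = dplyr::n(), .by = "promoter_id") |>
    dplyr::filter(.data$.k > min_reads) |>
    dplyr::select(-".k")
}

#' Estimate TSS entropy from tags: window, filter, adjust
#'
#' The user-facing entry point of the estimation stage: drops tags outside the
#' strand-oriented core-promoter window, applies the depth filter, and returns
#' per-promoter adjusted entropies.
#'
#' @inheritParams adjusted_entropy
#' @inheritParams filter_promoters
#' @param window Half-width of the core promoter window in bp; tags with
#'   offsets outside `[-window, window)` are dropped before estimation.
#'   Default 1000.
#' @return A tibble as in [adjusted_entropy()].
#' @export
estimate_entropy <- function(tags, sdem, alpha = 0.1, min_reads = 10, window = 1000) {
  check_tags(tags)
  tags |>
    dplyr::filter(.data$offset >= -window, .data$offset < window) |>
    filter_promoters(min_reads = min_reads) |>
    adjusted_entropy(sdem = sdem, alpha = alpha)
}

#' Compare entropy and standard deviation as width measures under noise
#'
#' Simulates two promoter populations with distinct true sigmas, contaminates
#' each tag sample with background noise, and measures how well (i) the
#' adjusted entropy and (ii) the per-promoter sample standard deviation
#' separate the populations, as the AUC of ranking population B above A.
#'
#' @param pop_a_sigma,pop_b_sigma True TSS sigma (bp) of the two populations.
#' @param depth Tags per promoter.
#' @param sdem An [build_sdem()] object used for the entropy estimates.
#' @param noise_model One of `"none"`, `"uniform"` (background tags uniform on
#'   the window) or `"gaussian"` (background from Normal(0, (5 sigma)^2)).
#' @param noise_fraction Expected fraction of tags replaced by background, in
#'   `[0, 1)`.
#' @param n_promoters Promoters per population. Default 500.
#' @param window Core promoter half-width, bp.
#' @param alpha Likelihood window half-width for [infer_sigma()].
#' @param seed Integer seed.
#' @return A tibble with one row per measure: `measure` (`"entropy"`, `"sd"`)
#'   and `auc`.
#' @export
std_entropy_robustness <- function(pop_a_sigma, pop_b_sigma, depth, sdem,
                                   noise_model = c("none", "uniform", "gaussian"),
                                   noise_fraction = 0, n_promoters = 500,
                                   window = 1000, alpha = 0.1, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(pop_a_sigma > 0, pop_b_sigma > 0, depth >= 1,
            noise_fraction >= 0, noise_fraction < 1)
  set.seed(as.integer(seed))
  sample_pop <- function(sigma) {
    purrr::map(seq_len(n_promoters), function(i) {
      x <- round(stats::rnorm(depth, 0, sigma))
      if (noise_model != "none" && noise_fraction > 0) {
        n_noise <- stats::rbinom(1, depth, noise_fraction)
        if (n_noise > 0) {
          bg <- switch(noise_model,
            uniform = sample.int(2L * window, n_noise, replace = TRUE) - window - 1L,
            gaussian = round(stats::rnorm(n_noise, 0, 5 * sigma))
          )
          x[seq_len(n_noise)] <- bg
        }
      }
      x[x >= -window & x < window]
    })
  }
  measures <- function(samples) {
    k <- lengths(samples)
    keep <- k >= 2
    U <- purrr::map_dbl(samples[keep], histogram_entropy)
    inf <- infer_sigma(U, k[keep], sdem, alpha)
    tibble::tibble(
      H_adj = gaussian_entropy(inf$sigma_hat),
      sd = purrr::map_dbl(samples[keep], stats::sd)
    )
  }
  a <- measures(sample_pop(pop_a_sigma))
  b <- measures(sample_pop(pop_b_sigma))
  tibble::tibble(
    measure = c("entropy", "sd"),
    auc = c(rank_auc(a$H_adj, b$H_adj), rank_auc(a$sd, b$sd))
  )
}

# AUC of ranking group b above group a (Mann-Whitney statistic)
rank_auc <- function(a, b) {
  r <- rank(c(a, b))
  nb <- length(b)
  (sum(r[(length(a) + 1):(length(a) + nb)]) - nb * (nb + 1) / 2) / (length(a) * nb)
}
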