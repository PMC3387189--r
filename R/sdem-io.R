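#' Serialize an SDEM to plain-text files
#'
#' Writes the matrix of means and the matrix of standard deviations as two
#' TSVs (`sdem_mean.tsv`, `sdem_sd.tsv`) with a header row of sigma values and
#' a first column of sample sizes, plus a small JSON sidecar
#' (`sdem_meta.json`) carrying `B` and the build seed.
#'
#' @param sdem An [build_sdem()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sdem <- function(sdem, dir) {
  stopifnot(inherits(sdem, "sdem"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(m, path) {
    df <- tibble::as_tibble(m, .name_repair = ~ paste0("sigma_", sdem$sigma_grid))
    df <- dplyr::bind_cols(tibble::tibble(n = seq_len(sdem$n_max)), df)
    readr::write_tsv(df, path)
  }
  write_one(sdem$mean, file.path(dir, "sdem_mean.tsv"))
  write_one(sdem$sd, file.path(dir, "sdem_sd.tsv"))
  jsonlite::write_json(list(B = sdem$B, seed = sdem$seed),
                       file.path(dir, "sdem_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_sdem
#' @export
read_sdem <- function(dir) {
  read_one <- function(path) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- NULL
    m
  }
  mean_m <- read_one(file.path(dir, "sdem_mean.tsv"))
  sd_m <- read_one(file.path(dir, "sdem_sd.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "sdem_meta.json"))
  structure(
    list(mean = mean_m, sd = sd_m, n_max = nrow(mean_m),
         sigma_grid = seq_len(ncol(mean_m)), B = meta$B, seed = meta$seed),
    class = "sdem"
  )
}
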