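#' Read promoter annotations from a BED6(+1) file
#'
#' The name field is the promoter id; an optional 7th column carries the CpG
#' class (`CpG` / `nonCpG`). Coordinates are BED-native (0-based, half-open);
#' the TSS is the start coordinate for `+` promoters and `end - 1` for `-`
#' promoters. Strand-oriented core windows `[tss - window, tss + window)` are
#' attached; windows running off the chromosome start are truncated at 0 with
#' a warning. Duplicate (chrom, tss, strand) entries are dropped with a
#' warning.
#'
#' @param path Path to a tab-separated BED6 or BED6+1 file (no header).
#' @param window Core promoter half-width in bp. Default 1000.
#' @return A tibble: `promoter_id`, `chrom`, `tss`, `strand`, `cpg_class`,
#'   `window_start`, `window_end`.
#' @export
read_promoters <- function(path, window = 1000) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(promoter_id = character(0), chrom = character(0),
                          tss = integer(0), strand = character(0),
                          cpg_class = character(0), window_start = integer(0),
                          window_end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad)) {
    rlang::abort(sprintf("Malformed BED line %d: expected at least 6 tab-separated fields, got %d.",
                         bad[1], nf[bad[1]]))
  }
  start <- suppressWarnings(as.integer(purrr::map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(purrr::map_chr(fields, 3)))
  strand <- purrr::map_chr(fields, 6)
  bad <- which(is.na(start) | is.na(end) | !strand %in% c("+", "-"))
  if (length(bad)) {
    rlang::abort(sprintf("Malformed BED line %d: non-numeric coordinates or invalid strand.", bad[1]))
  }
  prom <- tibble::tibble(
    promoter_id = purrr::map_chr(fields, 4),
    chrom = purrr::map_chr(fields, 1),
    tss = ifelse(strand == "+", start, end - 1L),
    strand = strand,
    cpg_class = purrr::map_chr(fields, function(f) if (length(f) >= 7) f[[7]] else "unknown")
  )
  dup <- duplicated(prom[c("chrom", "tss", "strand")])
  if (any(dup)) {
    rlang::warn(sprintf("Dropped %d duplicate promoter(s) by (chrom, tss, strand).", sum(dup)))
    prom <- prom[!dup, ]
  }
  prom$window_start <- prom$tss - as.integer(window)
  prom$window_end <- prom$tss + as.integer(window)
  if (any(prom$window_start < 0L)) {
    rlang::warn(sprintf("%d promoter window(s) truncated at chromosome start.",
                        sum(prom$window_start < 0L)))
    prom$window_start <- pmax(prom$window_start, 0L)
  }
  prom
}

#' Write promoters back to BED6+1
#'
#' @param promoters A [read_promoters()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  bed <- tibble::tibble(
    chrom = promoters$chrom,
    start = ifelse(promoters$strand == "+", promoters$tss, promoters$tss),
    end = promoters$tss + 1L,
    name = promoters$promoter_id,
    score = 0L,
    strand = promoters$strand,
    cpg_class = promoters$cpg_class
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a CTSS-style tag-count file
#'
#' Tab-separated `chrom`, 1-based `position`, `strand`, `count`; converted to
#' 0-based positions at the boundary.
#'
#' @param path Path to the CTSS file (no header).
#' @return A tibble: `chrom`, `pos` (0-based), `strand`, `count`.
#' @export
read_ctss <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "position", "strand", "count"),
                        col_types = "cici", progress = FALSE)
  tibble::tibble(chrom = df$chrom, pos = df$position - 1L,
                 strand = df$strand, count = df$count)
}

#' Expand CTSS counts into per-promoter tag offsets
#'
#' Assigns each tag position to the promoter on the same chromosome and
#' strand whose core window contains it, converts it to a strand-oriented
#' offset (upstream negative), and expands counts into one row per tag.
#'
#' @param ctss A [read_ctss()] tibble.
#' @param promoters A [read_promoters()] tibble.
#' @param window Core promoter half-width in bp. Default 1000.
#' @return A tag tibble: `promoter_id`, `offset`.
#' @export
tags_from_ctss <- function(ctss, promoters, window = 1000) {
  hits <- dplyr::inner_join(
    ctss, promoters,
    by = dplyr::join_by("chrom", "strand", dplyr::between("pos", "window_start", "window_end"))
  ) |>
    dplyr::mutate(offset = ifelse(.data$strand == "+",
                                  .data$pos - .data$tss, .data$tss - .data$pos)) |>
    dplyr::filter(.data$offset >= -window, .data$offset < window)
  tibble::tibble(
    promoter_id = rep(hits$promoter_id, hits$count),
    offset = as.integer(rep(hits$offset, hits$count))
  )
}

#' Aggregate a signal track over promoter windows
#'
#' Per promoter, the overlap-weighted sum of a bedGraph track: each interval
#' contributes `value * overlap_length` to every promoter window it
#' intersects (half-open arithmetic). Promoters with no overlapping signal
#' get 0.
#'
#' @param promoters A [read_promoters()] tibble.
#' @param track Path to a bedGraph file, or a data frame with columns
#'   `chrom`, `start`, `end`, `value` (0-based half-open).
#' @param name Column name for the resulting feature. Default `"signal"`.
#' @return A tibble: `promoter_id` plus one numeric column `name`.
#' @export
aggregate_signal <- function(promoters, track, name = "signal") {
  if (is.character(track)) {
    track <- readr::read_tsv(track, col_names = c("chrom", "start", "end", "value"),
                             col_types = "ciid", progress = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(track$value < 0)) {
    rlang::warn(sprintf("%d track interval(s) have negative values; kept as-is.",
                        sum(track$value < 0)))
  }
  ov <- dplyr::inner_join(
    track, promoters,
    by = dplyr::join_by("chrom", dplyr::overlaps("start", "end", "window_start", "window_end", bounds = "[)"))
  ) |>
    dplyr::mutate(width = pmin(.data$end, .data$window_end) - pmax(.data$start, .data$window_start)) |>
    dplyr::summarise(total = sum(.data$value * .data$width), .by = "promoter_id")
  out <- dplyr::left_join(promoters["promoter_id"], ov, by = "promoter_id") |>
    dplyr::mutate(total = dplyr::coalesce(.data$total, 0))
  names(out)[2] <- name
  out
}

#' Read precomputed motif-cluster score columns
#'
#' Joins a TSV of per-promoter motif-cluster score sums (first column
#' `promoter_id`, one column per cluster) onto the promoter set. Promoters
#' missing from the table get zeros with a warning; table rows for unknown
#' promoters are skipped with a warning; a duplicated promoter row is an
#' error.
#'
#' @param path Path to the TSV (with header).
#' @param promoters A [read_promoters()] tibble.
#' @return A tibble: `promoter_id` plus one numeric column per motif cluster
#'   (feature type SEQ).
#' @export
read_motif_scores <- function(path, promoters) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "promoter_id") names(df)[1] <- "promoter_id"
  if (anyDuplicated(df$promoter_id)) {
    rlang::abort("Duplicate promoter rows in motif score table; aggregation is ambiguous.")
  }
  unknown <- setdiff(df$promoter_id, promoters$promoter_id)
  if (length(unknown)) {
    rlang::warn(sprintf("Skipped %d motif-score row(s) for unknown promoter id(s).",
                        length(unknown)))
    df <- df[!df$promoter_id %in% unknown, ]
  }
  missing <- setdiff(promoters$promoter_id, df$promoter_id)
  if (length(missing)) {
    rlang::warn(sprintf("%d promoter(s) absent from the motif score table; scores set to 0.",
                        length(missing)))
  }
  out <- dplyr::left_join(promoters["promoter_id"], df, by = "promoter_id")
  out[-1] <- lapply(out[-1], function(x) dplyr::coalesce(as.numeric(x), 0))
  out
}

#' Split a feature matrix by promoter CpG class
#'
#' CpG-related and non-CpG promoters are analysed separately throughout;
#' promoters with unknown class are excluded (with a message).
#'
#' @param features A tibble with a `promoter_id` column.
#' @param promoters A promoter tibble with `promoter_id` and `cpg_class`.
#' @return A named list with tibbles `CpG` and `nonCpG`.
#' @export
split_by_cpg <- function(features, promoters) {
  cls <- promoters$cpg_class[match(features$promoter_id, promoters$promoter_id)]
  known <- cls %in% c("CpG", "nonCpG")
  if (!any(known)) rlang::abort("No promoters with a known CpG class.")
  if (any(!known)) {
    rlang::inform(sprintf("Excluded %d promoter(s) with unknown CpG class.", sum(!known)))
  }
  out <- list(
    CpG = features[known & cls == "CpG", , drop = FALSE],
    nonCpG = features[known & cls == "nonCpG", , drop = FALSE]
  )
  if (nrow(out$nonCpG) == 0L || nrow(out$CpG) == 0L) {
    rlang::warn("One CpG partition is empty.")
  }
  out
}
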