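write_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_promoters builds strand-oriented windows and clamps at chromosome start", {
  path <- write_bed(c(
    "chr1\t999\t1000\tp1\t0\t+",
    "chr1\t5000\t5001\tp2\t0\t-\tCpG"
  ))
  expect_warning(prom <- read_promoters(path), "truncated")
  expect_equal(prom$tss, c(999L, 5000L))
  expect_equal(prom$window_start, c(0L, 4000L))
  expect_equal(prom$window_end, c(1999L, 6000L))
  expect_equal(prom$cpg_class, c("unknown", "CpG"))
})

test_that("read_promoters rejects malformed lines, drops duplicates, handles empty files", {
  expect_error(read_promoters(write_bed("chr1\t100\t200")), "line 1")
  expect_error(read_promoters(write_bed(c("chr1\t100\t101\tp\t0\t+",
                                          "chr1\tabc\t200\tq\t0\t+"))), "line 2")
  path <- write_bed(c("chr1\t5000\t5001\tp1\t0\t+", "chr1\t5000\t5001\tp1b\t0\t+"))
  expect_warning(prom <- read_promoters(path), "duplicate")
  expect_equal(nrow(prom), 1)
  empty <- write_bed(character(0))
  expect_equal(nrow(read_promoters(empty)), 0)
})

test_that("promoter BED round-trip is the identity", {
  path <- write_bed(c("chr2\t8000\t8001\ta\t0\t+\tCpG", "chr2\t9000\t9001\tb\t0\t-\tnonCpG"))
  prom <- read_promoters(path)
  out <- withr::local_tempfile(fileext = ".bed")
  write_promoters(prom, out)
  expect_equal(read_promoters(out), prom)
})

test_that("CTSS tags map to strand-oriented offsets", {
  prom <- read_promoters(write_bed(c("chr1\t5000\t5001\tplus\t0\t+",
                                     "chr1\t9000\t9001\tminus\t0\t-")))
  ctss_path <- withr::local_tempfile(fileext = ".ctss")
  # 1-based positions; minus-strand tag at genomic tss+5 must give offset -5
  writeLines(c("chr1\t5006\t+\t2", "chr1\t9006\t-\t1"), ctss_path)
  tags <- tags_from_ctss(read_ctss(ctss_path), prom)
  expect_equal(tags$offset[tags$promoter_id == "plus"], c(5L, 5L))
  expect_equal(tags$offset[tags$promoter_id == "minus"], -5L)
})

test_that("signal aggregation is the overlap-weighted sum with half-open arithmetic", {
  prom <- read_promoters(write_bed("chr1\t5000\t5001\tp\t0\t+"))
  # full coverage at value 1 over the 2000-bp window
  full <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L, value = 1)
  expect_equal(aggregate_signal(prom, full)$signal, 2000)
  # interval [tss+990, tss+1010) at value 2: only 10 bp in-window
  part <- tibble::tibble(chrom = "chr1", start = 5990L, end = 6010L, value = 2)
  expect_equal(aggregate_signal(prom, part)$signal, 20)
  none <- tibble::tibble(chrom = "chr2", start = 0L, end = 10000L, value = 5)
  expect_equal(aggregate_signal(prom, none)$signal, 0)
  neg <- tibble::tibble(chrom = "chr1", start = 4500L, end = 4600L, value = -1)
  expect_warning(out <- aggregate_signal(prom, neg), "negative")
  expect_equal(out$signal, -100)
})

test_that("aggregation is invariant to splitting track intervals", {
  prom <- read_promoters(write_bed(c("chr1\t5000\t5001\tp\t0\t+",
                                     "chr1\t6200\t6201\tq\t0\t-")))
  set.seed(41)
  starts <- sort(sample(3000:8000, 20))
  track <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + sample(50:400, 20, replace = TRUE),
                          value = runif(20, 0, 3))
  split_track <- track |>
    dplyr::rowwise() |>
    dplyr::reframe(chrom = chrom,
                   cut = floor((start + end) / 2),
                   start = c(start, cut), end = c(cut, end), value = value) |>
    dplyr::select("chrom", "start", "end", "value") |>
    dplyr::filter(.data$end > .data$start)
  a <- aggregate_signal(prom, track)
  b <- aggregate_signal(prom, split_track)
  expect_equal(a$signal, b$signal, tolerance = 1e-9)
})

test_that("motif score tables join with explicit handling of missing and unknown rows", {
  prom <- read_promoters(write_bed(c("chr1\t5000\t5001\ta\t0\t+",
                                     "chr1\t9000\t9001\tb\t0\t+",
                                     "chr1\t12000\t12001\tc\t0\t+")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("promoter_id\tm1\tm2\tm3", "a\t1\t2\t3", "b\t4\t5\t6", "zz\t7\t8\t9"), tsv)
  expect_warning(expect_warning(out <- read_motif_scores(tsv, prom), "unknown"), "absent")
  expect_equal(dim(out), c(3, 4))
  expect_equal(out$m2, c(2, 5, 0))
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("promoter_id\tm1", "a\t1", "a\t2"), dup)
  expect_error(read_motif_scores(dup, prom), "Duplicate")
})

test_that("CpG splitting partitions rows and rejects all-unknown labels", {
  prom <- tibble::tibble(promoter_id = sprintf("p%d", 1:16),
                         cpg_class = c(rep("CpG", 10), rep("nonCpG", 5), "unknown"))
  feats <- tibble::tibble(promoter_id = prom$promoter_id, f = rnorm(16))
  expect_message(parts <- split_by_cpg(feats, prom), "unknown")
  expect_equal(nrow(parts$CpG), 10)
  expect_equal(nrow(parts$nonCpG), 5)
  expect_length(intersect(parts$CpG$promoter_id, parts$nonCpG$promoter_id), 0)
  prom$cpg_class <- "unknown"
  expect_error(split_by_cpg(feats, prom), "known CpG class")
  prom$cpg_class <- "CpG"
  expect_warning(parts <- split_by_cpg(feats, prom), "empty")
  expect_equal(nrow(parts$nonCpG), 0)
})
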