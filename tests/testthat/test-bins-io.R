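test_that("genome partitioning tiles contigs with ceil-boundary bins", {
  g <- bin_grid(c(chrA = 1000), 200)
  expect_equal(g$n_total, 5L)
  expect_equal(bin_coords(g, 4)$start, 800)
  expect_equal(bin_coords(g, 4)$end, 1000)

  g2 <- bin_grid(c(chrA = 1001), 200)
  expect_equal(g2$n_total, 6L)
  expect_equal(bin_coords(g2, 5)[, c("start", "end")],
               data.frame(start = 1000, end = 1001))

  g3 <- bin_grid(c(A = 500, B = 300), 200)
  bc <- bin_coords(g3)
  expect_equal(bc$idx, 0:4)
  expect_equal(bc$contig, c("A", "A", "A", "B", "B"))
  expect_equal(bc$start, c(0, 200, 400, 0, 200))
  expect_equal(g3$n_total, sum(ceiling(c(500, 300) / 200)))

  expect_error(bin_grid(c(A = 100, A = 50), 200), "duplicate contig")
  expect_error(bin_grid(c(A = 0), 200), "positive")
  expect_error(bin_grid(c(A = 100), 0), "bin_width")
})

test_that("bp-to-bin mapping round-trips on bin boundaries", {
  g <- bin_grid(c(A = 1000, B = 777), 200)
  for (idx in seq_len(g$n_total) - 1L) {
    bc <- bin_coords(g, idx)
    expect_equal(bin_index(g, bc$contig, bc$start), idx)
    expect_equal(bin_index(g, bc$contig, bc$end - 1), idx)
  }
  expect_error(bin_index(g, "C", 10), "unknown contig")
  expect_error(bin_index(g, "A", 1000), "out of contig range")
})

test_that("interval-to-bin masks match the per-bp overlap oracle", {
  g <- bin_grid(c(A = 1000), 200)
  iv <- genomic_intervals("A", 250, 260)
  expect_equal(which(intervals_to_bin_mask(iv, g) == 1L), 2L)  # bin 1 only
  expect_equal(intervals_to_bin_mask(genomic_intervals(character(0), numeric(0),
                                                       numeric(0)), g),
               integer(5))
  expect_equal(intervals_to_bin_mask(genomic_intervals("A", 0, 1000), g),
               rep(1L, 5))

  set.seed(42)
  g2 <- bin_grid(c(A = 530, B = 240), 100)
  for (rep in 1:25) {
    n <- sample(0:4, 1)
    if (n == 0) { iv <- genomic_intervals(character(0), numeric(0), numeric(0))
    } else {
      ctg <- sample(c("A", "B"), n, replace = TRUE)
      s <- sapply(ctg, function(cc) sample(0:(c(A = 529, B = 239)[[cc]] - 1), 1))
      e <- s + sample(1:150, n, replace = TRUE)
      iv <- genomic_intervals(ctg, s, e)
    }
    expect_equal(intervals_to_bin_mask(iv, g2), bp_mask_oracle(iv, g2))
  }
})

test_that("strand filtering restricts interval masks", {
  g <- bin_grid(c(A = 1000), 200)
  iv <- genomic_intervals(c("A", "A"), c(0, 600), c(200, 800), c("+", "-"))
  expect_equal(which(intervals_to_bin_mask(iv, g, strand = "+") == 1L), 1L)
  expect_equal(which(intervals_to_bin_mask(iv, g, strand = "-") == 1L), 4L)
})

test_that("BED files round-trip and malformed lines are rejected by number", {
  iv <- genomic_intervals(c("A", "A", "B"), c(0, 400, 100), c(200, 900, 250),
                          c("+", "-", "."), c("x", "y", "z"))
  iv$score <- c(1, 500, 1000)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path, header = "# test")
  back <- read_bed(path)
  expect_equal(back$contig, iv$contig)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$strand, iv$strand)
  expect_equal(back$score, iv$score)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("A\t0\t100\tok\t0\t+", "A\t300\t200\tbad\t0\t+"), bad)
  expect_error(read_bed(bad), "line 2")
  expect_error(genomic_intervals("A", 100, 100), "start must be < end")
})

test_that("GTF exons convert from 1-based inclusive to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\ttest\texon\t101\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), path)
  ann <- read_gtf(path)
  expect_equal(ann$exons$start, 100)
  expect_equal(ann$exons$end, 200)
  expect_equal(ann$transcripts$label, "t1")

  # write_gtf -> read_gtf round-trip preserves coordinates
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path2)
  ann2 <- read_gtf(path2)
  expect_equal(ann2$exons[, c("start", "end", "strand")],
               ann$exons[, c("start", "end", "strand")])
})

test_that("per-bin tables round-trip against their grid", {
  g <- bin_grid(c(A = 900, B = 350), 200)
  vals <- matrix(rpois(g$n_total * 2, 5), ncol = 2,
                 dimnames = list(NULL, c("m1", "m2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_table(vals, g, path, header = provenance_header(list(x = 1)))
  back <- read_bin_table(path, g)
  expect_equal(unname(back$values), unname(vals))
  expect_equal(colnames(back$values), c("m1", "m2"))
  expect_equal(back$grid_cols$idx, seq_len(g$n_total) - 1L)
  g_bad <- bin_grid(c(A = 900), 200)
  expect_error(read_bin_table(path, g_bad), "match grid")
})

test_that("fragment midpoint counting honours MAPQ and duplicate filters", {
  skip_if_not_installed("Rsamtools")
  g <- bin_grid(c(chrT = 1000), 200)
  sam <- withr::local_tempfile(fileext = ".sam")
  # fragment [390,410): mates at POS 391 / 401, TLEN +-20 -> midpoint 400 (bin 2)
  # plus a duplicate-flagged pair and a low-MAPQ pair that must be dropped
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:1000",
    "r1\t99\tchrT\t391\t255\t10M\t=\t401\t20\tACGTACGTAC\t*",
    "r1\t147\tchrT\t401\t255\t10M\t=\t391\t-20\tACGTACGTAC\t*",
    "r2\t1123\tchrT\t391\t255\t10M\t=\t401\t20\tACGTACGTAC\t*",
    "r2\t1171\tchrT\t401\t255\t10M\t=\t391\t-20\tACGTACGTAC\t*",
    "r3\t99\tchrT\t601\t10\t10M\t=\t611\t20\tACGTACGTAC\t*",
    "r3\t147\tchrT\t611\t10\t10M\t=\t601\t-20\tACGTACGTAC\t*")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  counts <- count_reads_midpoint(bam, g)
  expect_equal(sum(counts), 1L)          # one retained fragment in total
  expect_equal(counts[3], 1L)            # bin 2 = [400, 600)
  # relaxing the filters brings the duplicate and low-MAPQ fragments back
  counts_all <- count_reads_midpoint(bam, g, min_mapq = 0, exclude_flag = 0)
  expect_equal(sum(counts_all), 3L)
})
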