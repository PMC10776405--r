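test_that("fragment files parse into records, with optional dup counts and whitelist", {
  frags <- make_fragments("chr1", c(100L, 200L), c(250L, 260L),
                          c("AAACGG-1", "TTTGCC-1"), c(1L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_file(frags, path, header = "# fragment file test")
  got <- read_fragments(path)
  expect_equal(got$chrom, c("chr1", "chr1"))
  expect_equal(got$start, c(100L, 200L))
  expect_equal(got$end, c(250L, 260L))
  expect_equal(got$barcode, c("AAACGG-1", "TTTGCC-1"))
  expect_equal(got$dup_count, c(1L, 3L))

  # gzip round-trip
  pgz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_fragment_file(frags, pgz, gz = TRUE)
  expect_equal(read_fragments(pgz)$end, c(250L, 260L))

  # whitelist drops absent barcodes
  got_w <- read_fragments(path, barcode_whitelist = "AAACGG-1")
  expect_equal(nrow(got_w), 1L)
  expect_equal(got_w$barcode, "AAACGG-1")

  # a 4-column file defaults dup_count to 1
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t250\tAAACGG-1", p4)
  expect_equal(read_fragments(p4)$dup_count, 1L)
})

test_that("malformed fragment lines and missing files are reported", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t250\tA", "chr1\t300\t200\tB"), p)
  expect_error(read_fragments(p), "malformed.*2")
  writeLines(c("chr1\tx\t250\tA"), p)
  expect_error(read_fragments(p), "malformed")
  expect_error(read_fragments(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("short-interval QC removes only fragments below 10 bp and leaves the rest intact", {
  frags <- make_fragments("chr1", c(100L, 100L, 100L), c(109L, 110L, 400L),
                          c("A", "B", "C"))
  out <- qc_filter_fragments(frags)
  expect_equal(out$barcode, c("B", "C"))
  # pure filter: surviving rows identical to their originals
  expect_equal(out, frags[2:3, ], ignore_attr = TRUE)
  expect_equal(nrow(qc_filter_fragments(frags[0, ])), 0L)
})

test_that("extreme-count regions are flagged by either matrix", {
  regions <- toy_regions()
  cells <- c("c1", "c2")
  mk <- function(vals, mode) CountMatrix(Matrix::Matrix(vals, sparse = TRUE),
                                         regions, cells, mode = mode)
  frag <- mk(rbind(c(7, 0), c(6, 6), c(0, 0)), "fragment")
  ins <- mk(rbind(c(2, 0), c(13, 6), c(0, 0)), "insertion")
  keep <- qc_filter_peaks(frag, ins)
  expect_equal(keep, c(FALSE, TRUE, TRUE))  # >=7 frag drops; 13 < 14 kept; zeros kept
  ins14 <- mk(rbind(c(2, 0), c(14, 6), c(0, 0)), "insertion")
  expect_equal(qc_filter_peaks(frag, ins14), c(FALSE, FALSE, TRUE))
  bad <- CountMatrix(Matrix::Matrix(0, 2, 2, sparse = TRUE), regions[1:2, ],
                     cells, mode = "insertion")
  expect_error(qc_filter_peaks(frag, bad), "dimensions")
})

test_that("doublet flagging responds to per-base coverage above 3 and is monotone", {
  regions <- toy_regions()
  # four identical fragments in pA -> coverage 4 at their span
  quad <- make_fragments("chr1", rep(100L, 4), rep(150L, 4), rep("dbl", 4))
  ok <- make_fragments("chr1", c(100L, 120L, 140L), c(115L, 135L, 155L), rep("low", 3))
  frags <- rbind(quad, ok)
  expect_equal(flag_doublets(frags, regions, threshold_regions = 0), "dbl")
  expect_equal(flag_doublets(frags, regions, threshold_regions = Inf), character(0))
  # monotone: adding fragments to a flagged cell never un-flags it
  more <- rbind(frags, make_fragments("chr2", 200L, 300L, "dbl"))
  expect_true("dbl" %in% flag_doublets(more, regions, threshold_regions = 0))
})

test_that("duplicate records collapse unless explicitly retained", {
  frags <- make_fragments("chr1", c(100L, 100L, 120L), c(150L, 150L, 170L),
                          c("A", "A", "A"), c(2L, 3L, 1L))
  out <- deduplicate_fragments(frags)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$dup_count == 1L))
})

test_that("count matrices round-trip through MatrixMarket with sidecars", {
  regions <- toy_regions()
  cells <- c("c1", "c2")
  m <- CountMatrix(Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 3),
                                        dims = c(3, 2)),
                   regions, cells, mode = "pic", flank = 37L)
  dir <- withr::local_tempdir()
  write_count_matrix(m, dir)
  m2 <- read_count_matrix(dir)
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts), ignore_attr = TRUE)
  expect_equal(m2$mode, "pic")
  expect_equal(m2$flank, 37L)
  expect_equal(m2$cells, cells)
  expect_equal(m2$regions$region_id, regions$region_id)

  # empty matrix round-trips too
  e <- CountMatrix(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(3, 2)),
                   regions, cells, mode = "fragment")
  dir2 <- withr::local_tempdir()
  write_count_matrix(e, dir2)
  expect_equal(length(read_count_matrix(dir2)$counts@x), 0L)

  # sidecar mismatch is an error
  writeLines(c("c1", "c2", "c3"), file.path(dir, "barcodes.tsv"))
  expect_error(read_count_matrix(dir), "barcodes")
})

test_that("round-trip identity holds on randomized matrices", {
  withr::local_seed(402)
  for (rep in 1:3) {
    J <- sample(3:20, 1); C <- sample(2:15, 1)
    nnz <- sample(0:(J * C), 1)
    idx <- sample(J * C, nnz)
    m0 <- Matrix::sparseMatrix(i = (idx - 1) %% J + 1, j = (idx - 1) %/% J + 1,
                               x = sample(1:9, nnz, replace = TRUE), dims = c(J, C))
    regions <- data.frame(chrom = "chr1", start = seq_len(J) * 100L,
                          end = seq_len(J) * 100L + 50L,
                          region_id = sprintf("r%d", seq_len(J)))
    m <- CountMatrix(m0, regions, sprintf("c%d", seq_len(C)),
                     mode = sample(c("pic", "insertion", "fragment"), 1))
    dir <- withr::local_tempdir()
    write_count_matrix(m, dir)
    m2 <- read_count_matrix(dir)
    expect_equal(as.matrix(m2$counts), as.matrix(m$counts), ignore_attr = TRUE)
  }
})
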