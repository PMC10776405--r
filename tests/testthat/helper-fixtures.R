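# Shared fixture builders.  Everything is generated in code; coordinates are
# 0-based half-open as in fragment files / BED.

toy_regions <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr2"),
             start = c(90L, 400L, 100L),
             end = c(200L, 900L, 600L),
             region_id = c("pA", "pB", "pC"),
             stringsAsFactors = FALSE)
}

make_fragments <- function(chrom, start, end, barcode, dup_count = 1L) {
  n <- length(start)
  data.frame(chrom = rep(chrom, length.out = n), start = as.integer(start),
             end = as.integer(end), barcode = rep(barcode, length.out = n),
             dup_count = rep(as.integer(dup_count), length.out = n),
             stringsAsFactors = FALSE)
}

# random fragments whose insertions all lie strictly inside one of the regions
random_inside_fragments <- function(n, regions, barcodes) {
  j <- sample(nrow(regions), n, replace = TRUE)
  width <- regions$end[j] - regions$start[j]
  a <- regions$start[j] + floor(runif(n) * (width - 30L))
  b <- a + 10L + floor(runif(n) * pmax(1, regions$end[j] - a - 11L))
  make_fragments(regions$chrom[j], a, pmin(b, regions$end[j]),
                 sample(barcodes, n, replace = TRUE))
}

# random fragments anywhere near the regions (may span or miss them)
random_fragments <- function(n, barcodes) {
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  a <- floor(runif(n, 0, 1000))
  len <- 10L + floor(runif(n, 0, 400))
  make_fragments(chrom, a, a + len, sample(barcodes, n, replace = TRUE))
}

write_fragment_file <- function(fragments, path, gz = FALSE, header = NULL) {
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  apply_cols <- fragments[, c("chrom", "start", "end", "barcode", "dup_count")]
  writeLines(do.call(paste, c(as.list(apply_cols), sep = "\t")), con)
  invisible(path)
}
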