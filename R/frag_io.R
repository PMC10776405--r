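## Fragment-file, region and matrix I/O plus quality-control filters.
##
## Coordinate conventions: fragment files and BED are 0-based half-open.  A
## fragment's two Tn5 insertion loci are `start` and `end - 1` (the recorded
## end is one past the right insertion).  Inputs are assumed pre-shifted by
## the producing pipeline; no additional +4/-5 Tn5 offset is applied.

#' Read an ATAC fragment file
#'
#' Reads a tab-separated (optionally gzip-compressed) fragment file whose
#' first four columns are chromosome, start, end and cell barcode; a fifth
#' column, when present, is parsed as a duplicate count.  Leading lines
#' starting with \code{#} are skipped.
#'
#' @param path Path to the fragment file (.tsv or .tsv.gz).
#' @param barcode_whitelist Optional character vector; fragments whose
#'   barcode is not listed are dropped.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{barcode}, \code{dup_count}, in file order.
#' @export
read_fragments <- function(path, barcode_whitelist = NULL) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  magic <- readBin(path, "raw", n = 2L)
  gz <- length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))
  if (gz) {
    con <- gzfile(path, "r")
    lines <- readLines(con, warn = FALSE)
    close(con)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("fragment file needs at least 4 columns")
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            data.table = FALSE, showProgress = FALSE)
  } else {
    con <- file(path, "r")
    n_skip <- 0L
    repeat {
      ln <- readLines(con, n = 1L, warn = FALSE)
      if (!length(ln) || !startsWith(ln, "#")) break
      n_skip <- n_skip + 1L
    }
    close(con)
    dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = n_skip,
                            data.table = FALSE, showProgress = FALSE)
  }
  if (ncol(dt) < 4L) stop("fragment file needs at least 4 columns")
  frags <- data.frame(chrom = as.character(dt[[1]]),
                      start = suppressWarnings(as.integer(dt[[2]])),
                      end = suppressWarnings(as.integer(dt[[3]])),
                      barcode = as.character(dt[[4]]),
                      dup_count = if (ncol(dt) >= 5L)
                        suppressWarnings(as.integer(dt[[5]])) else 1L,
                      stringsAsFactors = FALSE)
  bad <- which(is.na(frags$start) | is.na(frags$end) |
                 frags$end <= frags$start | is.na(frags$dup_count) |
                 frags$dup_count < 1L)
  if (length(bad))
    stop("malformed fragment line(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  if (!is.null(barcode_whitelist))
    frags <- frags[frags$barcode %in% barcode_whitelist, , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

#' Remove fragments with implausibly short intervals
#'
#' Fragments with interval length (\code{end - start}) below \code{min_len}
#' are likely misalignments and are dropped; surviving records pass through
#' unchanged.
#'
#' @param fragments Fragment data frame (see \code{\link{read_fragments}}).
#' @param min_len Minimum retained interval length (default 10 bp).
#' @return The filtered fragment data frame.
#' @export
qc_filter_fragments <- function(fragments, min_len = 10L) {
  keep <- (fragments$end - fragments$start) >= min_len
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse duplicate fragment records
#'
#' Identical (chrom, start, end, barcode) records are collapsed to a single
#' record with \code{dup_count = 1}; used by default before counting.
#'
#' @param fragments Fragment data frame.
#' @return Deduplicated fragment data frame.
#' @export
deduplicate_fragments <- function(fragments) {
  key <- paste(fragments$chrom, fragments$start, fragments$end,
               fragments$barcode, sep = "\r")
  out <- fragments[!duplicated(key), , drop = FALSE]
  out$dup_count <- rep(1L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag regions with extreme counts
#'
#' Regions where any cell reaches a fragment-mode count >= \code{max_frag}
#' or an insertion-mode count >= \code{max_ins} are flagged for removal;
#' such regions are typically repetitive or uncharacterized blacklist
#' regions.
#'
#' @param frag_matrix \code{\link{CountMatrix}} in \code{fragment} mode.
#' @param ins_matrix \code{\link{CountMatrix}} in \code{insertion} mode,
#'   same regions and cells.
#' @param max_frag,max_ins Flagging thresholds (defaults 7 and 14).
#' @return Logical keep-mask over regions (TRUE = keep).
#' @export
qc_filter_peaks <- function(frag_matrix, ins_matrix, max_frag = 7, max_ins = 14) {
  mf <- .get_counts(frag_matrix); mi <- .get_counts(ins_matrix)
  if (!identical(dim(mf), dim(mi)))
    stop("fragment and insertion matrices must share dimensions")
  .rowmax(mf) < max_frag & .rowmax(mi) < max_ins
}

## per-row maximum of a sparse matrix (zeros implicit)
.rowmax <- function(m) {
  out <- numeric(nrow(m))
  s <- Matrix::summary(m)
  if (nrow(s)) {
    mx <- tapply(s$x, s$i, max)
    out[as.integer(names(mx))] <- mx
  }
  out
}

#' Flag potential doublet cells from per-base coverage
#'
#' For each cell, counts the regions in which some base is covered by more
#' than \code{max_cov} of that cell's fragments; cells with more than
#' \code{threshold_regions} such regions are flagged.  The default threshold
#' of 0 flags any cell with at least one such region (conservative; the rule
#' is exposed as a parameter).
#'
#' @param fragments Fragment data frame.
#' @param regions Region data frame.
#' @param threshold_regions Flag cells with strictly more than this many
#'   high-coverage regions (default 0).
#' @param max_cov Per-base coverage cutoff (default 3).
#' @return Character vector of flagged barcodes.
#' @export
flag_doublets <- function(fragments, regions, threshold_regions = 0L,
                          max_cov = 3L) {
  regions <- .validate_regions(regions)
  if (!nrow(fragments)) return(character(0))
  gr_reg <- .regions_gr(regions)
  flagged <- character(0)
  for (bc in unique(fragments$barcode)) {
    fr <- fragments[fragments$barcode == bc, , drop = FALSE]
    fr <- fr[rep(seq_len(nrow(fr)), fr$dup_count), , drop = FALSE]
    gr <- GenomicRanges::GRanges(fr$chrom,
                                 IRanges::IRanges(fr$start + 1L, fr$end))
    cov <- GenomicRanges::coverage(gr)
    n_high <- 0L
    common <- intersect(names(cov), GenomeInfoDb_seqnames(gr_reg))
    for (chr in common) {
      reg_chr <- gr_reg[GenomeInfoDb_seqnames(gr_reg) == chr]
      rr <- IRanges::ranges(reg_chr)
      covc <- cov[[chr]]
      ## restrict views to the covered extent; bases beyond it have coverage 0
      st <- pmin(IRanges::start(rr), length(covc) + 1L)
      en <- pmin(IRanges::end(rr), length(covc))
      ok <- en >= st
      if (!any(ok)) next
      v <- IRanges::Views(covc, st[ok], en[ok])
      n_high <- n_high + sum(IRanges::viewMaxs(v) > max_cov)
    }
    if (n_high > threshold_regions) flagged <- c(flagged, bc)
  }
  flagged
}

## seqnames accessor without importing GenomeInfoDb directly
GenomeInfoDb_seqnames <- function(x) as.character(GenomicRanges::seqnames(x))

#' Read a BED region file
#'
#' BED3+ (0-based half-open); a fourth column, when present, supplies region
#' identifiers, otherwise \code{chrom:start-end} identifiers are generated.
#'
#' @param path Path to the BED file.
#' @return Region data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{region_id}, \code{width}.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns")
  regions <- data.frame(chrom = as.character(dt[[1]]),
                        start = as.integer(dt[[2]]),
                        end = as.integer(dt[[3]]),
                        stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) regions$region_id <- as.character(dt[[4]])
  .validate_regions(regions)
}

#' Read a barcode list (one barcode per line)
#'
#' @param path Path to the barcode file.
#' @return Character vector of barcodes.
#' @export
read_barcodes <- function(path) {
  if (!file.exists(path)) stop("barcode file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Write a CountMatrix to a directory
#'
#' MatrixMarket coordinate file (\code{matrix.mtx}) plus sidecars:
#' \code{regions.bed}, \code{barcodes.tsv} and \code{metadata.json} holding
#' the counting mode and flank.  \code{\link{read_count_matrix}} inverts it.
#'
#' @param m A \code{\link{CountMatrix}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(m$regions[, c("chrom", "start", "end", "region_id")],
                     file.path(dir, "regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$cells, file.path(dir, "barcodes.tsv"))
  jsonlite::write_json(list(mode = m$mode, flank = m$flank),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a CountMatrix from a directory
#'
#' @param dir Directory written by \code{\link{write_count_matrix}}.
#' @return A \code{\link{CountMatrix}}.
#' @export
read_count_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  regions <- read_regions(file.path(dir, "regions.bed"))
  cells <- read_barcodes(file.path(dir, "barcodes.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  if (nrow(counts) != nrow(regions))
    stop("matrix.mtx has ", nrow(counts), " rows but regions.bed has ",
         nrow(regions), " regions")
  if (ncol(counts) != length(cells))
    stop("matrix.mtx has ", ncol(counts), " columns but barcodes.tsv has ",
         length(cells), " barcodes")
  CountMatrix(counts, regions, cells, mode = meta$mode, flank = meta$flank)
}
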