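#' Region-by-cell count matrix
#'
#' Sparse non-negative integer matrix of counts produced by one of the three
#' counting strategies (\code{pic}, \code{insertion}, \code{fragment}),
#' carrying its region set, cell barcodes and the flanking window used during
#' counting.
#'
#' @param counts Sparse (or dense) numeric matrix, regions in rows, cells in
#'   columns.
#' @param regions Region data frame (see \code{\link{read_regions}}) with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{region_id}.
#' @param cells Character vector of cell barcodes (column order).
#' @param mode Counting mode: \code{"pic"}, \code{"insertion"} or
#'   \code{"fragment"}.
#' @param flank Non-negative flanking window (bp) applied during counting.
#' @return An object of class \code{CountMatrix}.
#' @export
CountMatrix <- function(counts, regions, cells,
                        mode = c("pic", "insertion", "fragment"), flank = 0L) {
  mode <- match.arg(mode)
  counts <- .get_counts(counts)
  regions <- .validate_regions(regions)
  if (nrow(counts) != nrow(regions))
    stop("count matrix has ", nrow(counts), " rows but ", nrow(regions), " regions")
  if (ncol(counts) != length(cells))
    stop("count matrix has ", ncol(counts), " columns but ", length(cells), " cells")
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != floor(counts@x))))
    stop("counts must be non-negative integers")
  if (!(is.numeric(flank) && length(flank) == 1L && flank >= 0))
    stop("'flank' must be a single non-negative number")
  dimnames(counts) <- list(regions$region_id, cells)
  structure(list(counts = counts, regions = regions,
                 cells = as.character(cells), mode = mode,
                 flank = as.integer(flank)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix (%s mode, flank %d bp): %d regions x %d cells, %d nonzero entries\n",
              x$mode, x$flank, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

## accept a CountMatrix, sparse Matrix, or base matrix; return dgCMatrix
.get_counts <- function(x) {
  if (inherits(x, "CountMatrix")) x <- x$counts
  methods::as(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"), "dMatrix")
}

.validate_regions <- function(regions) {
  regions <- as.data.frame(regions)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions)))
    stop("regions need columns chrom, start, end")
  if (is.null(regions$region_id))
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom,
                                 regions$start, regions$end)
  if (any(regions$end <= regions$start))
    stop("regions must satisfy end > start")
  if (anyDuplicated(regions$region_id))
    stop("region_ids must be unique")
  regions$width <- regions$end - regions$start
  regions
}

#' Cap counts at a maximum value
#'
#' Optional post-processing step mirroring pipelines that ceiling counts
#' (commonly at 4).  Off by default everywhere else in the package.
#'
#' @param m A \code{\link{CountMatrix}}.
#' @param cap Maximum retained count.
#' @return The capped \code{CountMatrix}.
#' @export
cap_counts <- function(m, cap = 4) {
  stopifnot(inherits(m, "CountMatrix"), cap >= 1)
  m$counts@x <- pmin(m$counts@x, cap)
  m
}
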