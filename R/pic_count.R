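## Region-by-cell counting under the three strategies.
##
## PIC (paired-insertion counting) scores one unit per fragment with at least
## one insertion locus mapping to the region: fragments fully inside count
## once (the second locus is masked), boundary-spanning fragments also count
## once, and fragments whose insertions both lie outside contribute nothing
## even when their interval spans the region.  Insertion-based counting
## scores each mapping locus (0, 1 or 2 per fragment) and fragment-based
## counting scores interval overlap.

## regions (0-based half-open) -> GRanges (1-based closed)
.regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

#' Per-fragment contribution to a single region
#'
#' Reference implementation of the three counting rules for one fragment and
#' one region; the matrix builder \code{\link{build_count_matrix}} applies
#' the same rules via overlap queries.  An insertion locus \eqn{x} maps to
#' the region \eqn{[a, b)} when the window \eqn{[x - flank, x + flank]}
#' intersects it; in fragment mode the fragment interval is compared against
#' the flank-extended region.
#'
#' @param fragment One-row fragment data frame (0-based half-open interval;
#'   insertion loci at \code{start} and \code{end - 1}).
#' @param region_start,region_end Region interval, 0-based half-open.
#' @param flank Non-negative flanking window (bp).
#' @param mode \code{"pic"}, \code{"insertion"} or \code{"fragment"}.
#' @return Integer contribution (0/1 for pic and fragment modes; 0, 1 or 2
#'   for insertion mode), before any duplicate-count multiplication.
#' @export
count_fragment_in_region <- function(fragment, region_start, region_end,
                                     flank = 0L,
                                     mode = c("pic", "insertion", "fragment")) {
  mode <- match.arg(mode)
  loci <- c(fragment$start, fragment$end - 1L)
  maps <- (loci + flank) >= region_start & (loci - flank) <= (region_end - 1L)
  switch(mode,
         pic = as.integer(any(maps)),
         insertion = sum(maps),
         fragment = as.integer(fragment$start < region_end + flank &
                                 fragment$end > region_start - flank))
}

#' Build a region-by-cell count matrix from fragments
#'
#' Streams fragments against a region set and accumulates per-cell counts
#' under the requested mode.  A fragment whose two insertions fall in two
#' different regions contributes once to each (regions are treated
#' independently; overlapping regions receive independent contributions).
#'
#' @param fragments Fragment data frame (after QC).
#' @param regions Region data frame.
#' @param cells Optional barcode vector fixing the column set; fragments
#'   with other barcodes are dropped (a summary is attached as the
#'   \code{"dropped"} attribute).  Default: all barcodes seen, sorted.
#' @param mode Counting mode.
#' @param flank Flanking window in bp (default 0; 37 and 75 are the common
#'   presets matching peak-caller smoothing).
#' @param dedup Collapse identical fragment records before counting
#'   (default TRUE).  When FALSE, contributions are multiplied by
#'   \code{dup_count}.
#' @return A \code{\link{CountMatrix}}.
#' @export
build_count_matrix <- function(fragments, regions, cells = NULL,
                               mode = c("pic", "insertion", "fragment"),
                               flank = 0L, dedup = TRUE) {
  mode <- match.arg(mode)
  regions <- .validate_regions(regions)
  if (dedup) fragments <- deduplicate_fragments(fragments)
  if (is.null(cells)) cells <- sort(unique(fragments$barcode))
  keep <- fragments$barcode %in% cells
  n_dropped <- sum(!keep)
  fragments <- fragments[keep, , drop = FALSE]
  J <- nrow(regions); C <- length(cells)
  gr_reg <- .regions_gr(regions)
  cell_idx <- match(fragments$barcode, cells)
  n <- nrow(fragments)
  if (n == 0L) {
    out <- CountMatrix(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(J, C)),
                       regions, cells, mode, flank)
    attr(out, "dropped") <- n_dropped
    return(out)
  }
  if (mode %in% c("pic", "insertion")) {
    ## the two insertion loci, 1-based, widened by the flank
    pos1 <- c(fragments$start + 1L, fragments$end)
    gr_ins <- GenomicRanges::GRanges(rep(fragments$chrom, 2L),
                                     IRanges::IRanges(pos1 - flank, pos1 + flank))
    ## suppressWarnings: querying chromosomes absent from the region set is
    ## legitimate (those fragments simply do not map)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_ins, gr_reg))
    frag_of <- (S4Vectors::queryHits(hits) - 1L) %% n + 1L
    reg_of <- S4Vectors::subjectHits(hits)
    if (mode == "pic" && length(frag_of)) {
      ## mask the second locus when both map to the same region
      dupkey <- !duplicated(paste(frag_of, reg_of, sep = "\r"))
      frag_of <- frag_of[dupkey]; reg_of <- reg_of[dupkey]
    }
  } else {
    gr_frag <- GenomicRanges::GRanges(fragments$chrom,
                                      IRanges::IRanges(fragments$start + 1L - flank,
                                                       fragments$end + flank))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_frag, gr_reg))
    frag_of <- S4Vectors::queryHits(hits)
    reg_of <- S4Vectors::subjectHits(hits)
  }
  x <- if (dedup) rep(1, length(frag_of)) else fragments$dup_count[frag_of]
  counts <- Matrix::sparseMatrix(i = reg_of, j = cell_idx[frag_of], x = x,
                                 dims = c(J, C))
  out <- CountMatrix(counts, regions, cells, mode, flank)
  attr(out, "dropped") <- n_dropped
  out
}

#' High-density count frequencies per region and group
#'
#' For each region and cell group, tabulates the frequencies \eqn{f_k} of
#' cells with count \eqn{k} and returns the two conditional probabilities
#' used to assess quantitative information beyond binarization:
#' \eqn{P[y \ge 3 | y > 0] = (f_3 + \dots + f_n)/(f_1 + \dots + f_n)} and
#' \eqn{P[y = 2 | y \in \{1,2\}] = f_2/(f_1 + f_2)}.  Groups with no nonzero
#' cells yield \code{NA} (undefined, not zero).
#'
#' @param m A \code{\link{CountMatrix}} (counts may be capped, e.g. at 4).
#' @param groups Factor or vector of group labels, one per cell.
#' @param min_high_cells Minimum number of cells with count >= 3 for a
#'   region-group to pass the evidence filter (default 5).
#' @return Data frame with columns \code{region_id}, \code{group},
#'   \code{n_pos}, \code{n_ge3}, \code{p_ge3_given_pos},
#'   \code{p_eq2_given_12}, \code{pass_filter}.
#' @export
high_density_stats <- function(m, groups, min_high_cells = 5L) {
  x <- .get_counts(m)
  region_ids <- if (inherits(m, "CountMatrix")) m$regions$region_id
                else as.character(seq_len(nrow(x)))
  groups <- as.factor(groups)
  if (length(groups) != ncol(x)) stop("one group label per cell required")
  s <- Matrix::summary(x)
  g <- groups[s$j]
  out <- do.call(rbind, lapply(levels(groups), function(lev) {
    sel <- which(g == lev)
    i <- s$i[sel]; v <- s$x[sel]
    n_pos <- tabulate(i, nbins = nrow(x))
    n_ge3 <- tabulate(i[v >= 3], nbins = nrow(x))
    n_12 <- tabulate(i[v <= 2], nbins = nrow(x))
    n_2 <- tabulate(i[v == 2], nbins = nrow(x))
    data.frame(region_id = region_ids, group = lev,
               n_pos = n_pos, n_ge3 = n_ge3,
               p_ge3_given_pos = ifelse(n_pos > 0, n_ge3 / n_pos, NA_real_),
               p_eq2_given_12 = ifelse(n_12 > 0, n_2 / n_12, NA_real_),
               pass_filter = n_ge3 >= min_high_cells,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
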