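## Fragment-level generative simulator of the ATAC mechanism:
## per-bp Bernoulli Tn5 insertions (probability lambda / L_p per base), a
## random adapter (primer) configuration at each insertion, viability of each
## adjacent-insertion gap when the facing adapter ends match (probability 1/2,
## independent across gaps), size selection of the resulting fragments to
## [s1, s2], and per-fragment capture thinning.  The same mechanism backs the
## differential-accessibility simulation scenarios.

#' Simulate the fragments of one allele of one region
#'
#' Draws per-bp Bernoulli insertions across \code{L_p} positions, assigns
#' each insertion two independent adapter sides, forms a fragment from each
#' adjacent-insertion gap whose facing adapter ends are compatible, and
#' discards fragments whose insertion distance lies outside
#' \code{[s1, s2]}.
#'
#' @param lam Insertion rate; \code{lam / L_p} must be <= 1.
#' @param L_p Region length (bp).
#' @param s1,s2 Retained fragment-length window (bp).
#' @return Data frame of surviving fragments with 0-based half-open
#'   \code{start}, \code{end} (insertion loci at \code{start} and
#'   \code{end - 1}) and \code{length} (insertion distance).
#' @export
simulate_region_fragments <- function(lam, L_p = 500, s1 = 25, s2 = 600) {
  if (lam > L_p) stop("lam / L_p must be <= 1")
  if (lam < 0) stop("'lam' must be non-negative")
  pos <- which(runif(L_p) < lam / L_p) - 1L   # 0-based insertion loci
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  if (length(pos) < 2L) return(empty)
  ## two independent adapter sides per insertion; a gap yields a fragment
  ## when the right face of the left insertion and the left face of the
  ## right insertion are compatible (probability 1/2)
  side_r <- sample(c(0L, 1L), length(pos), replace = TRUE)
  side_l <- sample(c(0L, 1L), length(pos), replace = TRUE)
  k <- length(pos) - 1L
  viable <- side_r[seq_len(k)] != side_l[seq_len(k) + 1L]
  len <- diff(pos)
  keep <- viable & len >= s1 & len <= s2
  if (!any(keep)) return(empty)
  data.frame(start = pos[which(keep)],
             end = pos[which(keep) + 1L] + 1L,
             length = len[keep])
}

## Vectorized engine: surviving-pair counts for n independent alleles.
## Equivalent to n calls of simulate_region_fragments (conditional on the
## insertion total, per-bp Bernoulli loci are a uniform sample without
## replacement), but grouped by insertion count so that position sampling,
## sorting, gap viability and size selection are all vectorized.
.sim_pair_counts <- function(n, lam, L_p = 500, s1 = 25, s2 = 600) {
  if (any(lam > L_p)) stop("lam / L_p must be <= 1")
  if (any(lam < 0)) stop("'lam' must be non-negative")
  nins <- rbinom(n, size = L_p, prob = lam / L_p)
  counts <- integer(n)
  for (m in unique(nins[nins >= 2L])) {
    idx <- which(nins == m)
    B <- length(idx)
    pos <- matrix(sample.int(L_p, B * m, replace = TRUE), nrow = B)
    ## conditional on m insertions the loci are distinct; redraw collided rows
    repeat {
      o <- order(rep(seq_len(B), m), as.vector(pos))
      pos <- matrix(as.vector(pos)[o], nrow = B, byrow = TRUE)
      dup <- which(rowSums(pos[, -1L, drop = FALSE] ==
                             pos[, -m, drop = FALSE]) > 0L)
      if (!length(dup)) break
      pos[dup, ] <- matrix(sample.int(L_p, length(dup) * m, replace = TRUE),
                           nrow = length(dup))
    }
    gaps <- pos[, -1L, drop = FALSE] - pos[, -m, drop = FALSE]
    viable <- matrix(runif(B * (m - 1L)) < 0.5, nrow = B)
    ok <- viable & gaps >= s1 & gaps <= s2
    counts[idx] <- as.integer(rowSums(ok))
  }
  counts
}

#' Simulate observed PIC counts for a group of cells
#'
#' One (haploid) or two (diploid) allele simulations per cell via the
#' fragment-level mechanism, followed by independent per-fragment capture
#' with probability \code{q}.
#'
#' @param n_cells Number of cells.
#' @param lam Insertion rate per allele.
#' @param q Capture rate(s) in [0, 1]; scalar or one per cell.
#' @param L_p,s1,s2 Region length and fragment-size window (bp).
#' @param diploid Sum two independent alleles per cell (default TRUE).
#' @return Integer vector of observed PIC counts, one per cell.
#' @export
simulate_cell_counts <- function(n_cells, lam, q, L_p = 500, s1 = 25,
                                 s2 = 600, diploid = TRUE) {
  stopifnot(all(q >= 0 & q <= 1))
  w <- .sim_pair_counts(n_cells, lam, L_p, s1, s2)
  if (diploid) w <- w + .sim_pair_counts(n_cells, lam, L_p, s1, s2)
  rbinom(n_cells, size = w, prob = q)
}

#' Define a differential-accessibility simulation scenario
#'
#' The three study settings share a lambda grid spanning 0.05 to 2.5 and
#' log fold changes of +-0.1, 0.15, 0.2 and 0.25 applied to group 2 as
#' \eqn{\lambda \exp(\pm logFC)}:
#' \describe{
#'   \item{setting 1}{500 + 500 cells, 5000 null regions, 6000 DAR regions
#'     with balanced fold-change signs;}
#'   \item{setting 2}{500 + 200 cells, otherwise as setting 1;}
#'   \item{setting 3}{500 + 500 cells, 2000 upregulated and 4000
#'     downregulated DAR regions.}
#' }
#' Any field can be overridden, e.g. to scale the region count down or to
#' give the two groups different capture-rate ranges (the unbalanced-capture
#' condition).
#'
#' @param setting 1, 2 or 3.
#' @param n_cells Integer pair, cells per group.
#' @param n_null,n_dar Region counts.
#' @param lam_grid Insertion-rate grid cycled over regions.
#' @param lfc_set Positive log fold-change magnitudes cycled over DAR
#'   regions.
#' @param frac_pos Fraction of DAR regions with positive sign.
#' @param q_range Capture-rate range per group: list of two length-2
#'   vectors; per-cell rates are drawn uniformly.
#' @param L_p,s1,s2 Region length and fragment-size window (bp).
#' @param diploid Simulate two alleles per cell (default TRUE).
#' @param seed Optional integer seed fixed at generation time.
#' @return An object of class \code{sim_scenario}.
#' @export
sim_scenario <- function(setting = 1,
                         n_cells = NULL, n_null = NULL, n_dar = NULL,
                         lam_grid = c(0.05, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5),
                         lfc_set = c(0.1, 0.15, 0.2, 0.25),
                         frac_pos = NULL,
                         q_range = list(c(0.2, 0.8), c(0.2, 0.8)),
                         L_p = 500, s1 = 25, s2 = 600, diploid = TRUE,
                         seed = NULL) {
  stopifnot(setting %in% 1:3)
  if (is.null(n_cells)) n_cells <- if (setting == 2) c(500L, 200L) else c(500L, 500L)
  if (is.null(n_null)) n_null <- 5000L
  if (is.null(n_dar)) n_dar <- 6000L
  if (is.null(frac_pos)) frac_pos <- if (setting == 3) 1 / 3 else 0.5
  stopifnot(length(n_cells) == 2L, all(n_cells >= 1), n_null >= 0, n_dar >= 0,
            all(lam_grid > 0), all(lfc_set > 0), frac_pos >= 0, frac_pos <= 1)
  structure(list(setting = setting, n_cells = as.integer(n_cells),
                 n_null = as.integer(n_null), n_dar = as.integer(n_dar),
                 lam_grid = lam_grid, lfc_set = lfc_set, frac_pos = frac_pos,
                 q_range = q_range, L_p = L_p, s1 = s1, s2 = s2,
                 diploid = diploid, seed = seed),
            class = "sim_scenario")
}

#' Simulate a full differential-accessibility scenario
#'
#' Generates a region-by-cell PIC \code{\link{CountMatrix}} from the
#' fragment-level mechanism, with group-2 insertion rates multiplied by
#' \eqn{\exp(\pm logFC)} in DAR regions, together with the per-region ground
#' truth and per-cell group labels.
#'
#' @param scenario A \code{\link{sim_scenario}}.
#' @return List with elements \code{counts} (\code{CountMatrix}),
#'   \code{truth} (data frame: \code{region_id}, \code{lambda},
#'   \code{lfc}, \code{is_dar}), \code{labels} (factor \code{g1}/\code{g2})
#'   and \code{q} (true per-cell capture rates).
#' @export
simulate_dar_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n1 <- scenario$n_cells[1]; n2 <- scenario$n_cells[2]
  labels <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
  q <- c(runif(n1, scenario$q_range[[1]][1], scenario$q_range[[1]][2]),
         runif(n2, scenario$q_range[[2]][1], scenario$q_range[[2]][2]))
  J <- scenario$n_null + scenario$n_dar
  lam <- rep_len(scenario$lam_grid, J)
  lfc <- numeric(J)
  if (scenario$n_dar > 0) {
    n_pos <- round(scenario$n_dar * scenario$frac_pos)
    sgn <- rep(c(1, -1), c(n_pos, scenario$n_dar - n_pos))
    lfc[scenario$n_null + seq_len(scenario$n_dar)] <-
      sgn * rep_len(scenario$lfc_set, scenario$n_dar)
  }
  trip_i <- vector("list", J); trip_j <- vector("list", J)
  trip_x <- vector("list", J)
  for (j in seq_len(J)) {
    w1 <- simulate_cell_counts(n1, lam[j], q[seq_len(n1)],
                               scenario$L_p, scenario$s1, scenario$s2,
                               scenario$diploid)
    w2 <- simulate_cell_counts(n2, lam[j] * exp(lfc[j]), q[n1 + seq_len(n2)],
                               scenario$L_p, scenario$s1, scenario$s2,
                               scenario$diploid)
    w <- c(w1, w2)
    nz <- which(w > 0L)
    trip_i[[j]] <- rep.int(j, length(nz)); trip_j[[j]] <- nz
    trip_x[[j]] <- w[nz]
  }
  counts <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                 x = as.numeric(unlist(trip_x)),
                                 dims = c(J, n1 + n2))
  region_id <- sprintf("region_%05d", seq_len(J))
  regions <- data.frame(chrom = "chrS", start = (seq_len(J) - 1L) * 1000L,
                        end = (seq_len(J) - 1L) * 1000L + scenario$L_p,
                        region_id = region_id, stringsAsFactors = FALSE)
  cells <- sprintf("cell_%04d", seq_len(n1 + n2))
  list(counts = CountMatrix(counts, regions, cells, mode = "pic", flank = 0L),
       truth = data.frame(region_id = region_id, lambda = lam, lfc = lfc,
                          is_dar = lfc != 0, stringsAsFactors = FALSE),
       labels = labels, q = q)
}
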