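## Generalized likelihood ratio test for differentially accessible regions.
##
## M0 fits one insertion rate to both cell groups, M1 one per group; the
## statistic -2(LL_M0 - LL_M1) is referred to a chi-square distribution with
## one degree of freedom.

#' Likelihood-ratio test for one region
#'
#' Fits the pooled (M0) and per-group (M1) insertion rates by maximum
#' likelihood under the capture-thinned diploid ssPoisson model and returns
#' the chi-square statistic \eqn{-2(LL_{M0} - LL_{M1})} with its 1-d.f.
#' p-value.  Regions with zero counts in both groups carry no information
#' and are reported as degenerate with p = 1.
#'
#' @param w1,w2 Observed PIC counts in groups 1 and 2.
#' @param q1,q2 Per-cell capture rates for the two groups.
#' @param L_p,s1,s2 Region length and fragment-size window (bp).
#' @param diploid Model counts as diploid sums (default TRUE).
#' @return One-row data frame: \code{lambda_pooled}, \code{lambda_g1},
#'   \code{lambda_g2}, \code{ll_m0}, \code{ll_m1}, \code{chi2},
#'   \code{p_value}, \code{status} (\code{"tested"} or
#'   \code{"degenerate"}).
#' @export
lrt_single_region <- function(w1, q1, w2, q2, L_p = 500, s1 = 25, s2 = 600,
                              diploid = TRUE) {
  stopifnot(length(w1) >= 1, length(w2) >= 1,
            length(w1) == length(q1), length(w2) == length(q2))
  if (all(w1 == 0) && all(w2 == 0)) {
    return(data.frame(lambda_pooled = 0, lambda_g1 = 0, lambda_g2 = 0,
                      ll_m0 = 0, ll_m1 = 0, chi2 = 0, p_value = 1,
                      status = "degenerate", stringsAsFactors = FALSE))
  }
  f0 <- mle_estimate(c(w1, w2), c(q1, q2), L_p, s1, s2, diploid)
  f1 <- mle_estimate(w1, q1, L_p, s1, s2, diploid)
  f2 <- mle_estimate(w2, q2, L_p, s1, s2, diploid)
  ll0 <- f0$loglik
  ll1 <- f1$loglik + f2$loglik
  ## optimizer noise can leave ll1 a hair below ll0 although M1 nests M0
  chi2 <- max(0, -2 * (ll0 - ll1))
  data.frame(lambda_pooled = f0$lambda, lambda_g1 = f1$lambda,
             lambda_g2 = f2$lambda, ll_m0 = ll0, ll_m1 = ll1,
             chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
             status = "tested", stringsAsFactors = FALSE)
}

#' Capture rates for a matrix of cells
#'
#' Convenience wrapper around \code{\link{estimate_capture}}: rates are
#' estimated from the binarized matrix either per group (each group's
#' matrix fitted separately; the default, letting open probabilities differ
#' by group), pooled across all cells, or from a sequencing-depth
#' proportional fallback (per-cell total counts scaled to a maximum of 1).
#'
#' @param m \code{\link{CountMatrix}} or sparse matrix (regions x cells).
#' @param labels Group factor (required for \code{"per_group"}).
#' @param method \code{"per_group"}, \code{"pooled"} or \code{"depth"}.
#' @return Numeric vector of per-cell capture rates in (0, 1].
#' @export
estimate_cell_q <- function(m, labels = NULL,
                            method = c("per_group", "pooled", "depth")) {
  method <- match.arg(method)
  x <- .get_counts(m)
  if (method == "depth") {
    d <- Matrix::colSums(x)
    if (max(d) == 0) stop("cannot derive depth-based rates from an all-zero matrix")
    return(pmax(d / max(d), 1e-6))
  }
  if (method == "pooled") {
    fit <- estimate_capture(x)
    if (fit$non_identifiable) stop("capture rates are non-identifiable (all-zero matrix)")
    return(fit$q)
  }
  labels <- as.factor(labels)
  stopifnot(length(labels) == ncol(x))
  q <- numeric(ncol(x))
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    fit <- estimate_capture(x[, idx, drop = FALSE])
    if (fit$non_identifiable)
      stop("capture rates are non-identifiable in group ", lev)
    q[idx] <- fit$q
  }
  q
}

#' Differential accessibility test across a count matrix
#'
#' Runs the per-region likelihood-ratio test between two cell groups and
#' applies Benjamini-Hochberg adjustment over the tested (non-degenerate)
#' regions; degenerate regions are reported with p = 1 and excluded from the
#' adjustment.  Regions with FDR-adjusted p <= \code{fdr} are the DAR calls.
#'
#' @param m \code{\link{CountMatrix}} (pic mode) or sparse matrix.
#' @param labels Two-level factor of group assignments, one per cell.
#' @param q Per-cell capture rates; when NULL they are estimated with
#'   \code{\link{estimate_cell_q}} using \code{q_method}.
#' @param q_method Capture-rate estimation method (see
#'   \code{\link{estimate_cell_q}}).
#' @param L_p Region length(s); default: region widths of the
#'   \code{CountMatrix}, else 500.
#' @param s1,s2 Fragment-size window (bp).
#' @param diploid Model counts as diploid sums (default TRUE).
#' @param fdr DAR threshold on the adjusted p-value (default 0.05).
#' @return Data frame with one row per region: the
#'   \code{\link{lrt_single_region}} columns plus \code{region_id},
#'   \code{fdr} and \code{is_dar}.
#' @export
dar_test_matrix <- function(m, labels, q = NULL,
                            q_method = c("per_group", "pooled", "depth"),
                            L_p = NULL, s1 = 25, s2 = 600, diploid = TRUE,
                            fdr = 0.05) {
  x <- .get_counts(m)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x)) stop("one group label per cell required")
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  if (any(table(labels) == 0L)) stop("both groups must be non-empty")
  region_ids <- if (inherits(m, "CountMatrix")) m$regions$region_id
                else as.character(seq_len(nrow(x)))
  if (is.null(L_p)) {
    L_p <- if (inherits(m, "CountMatrix")) m$regions$width else 500
  }
  L_p <- rep_len(L_p, nrow(x))
  if (is.null(q)) q <- estimate_cell_q(m, labels, match.arg(q_method))
  stopifnot(length(q) == ncol(x), all(q > 0 & q <= 1))
  i1 <- which(labels == levels(labels)[1])
  i2 <- which(labels == levels(labels)[2])
  xt <- Matrix::t(x)   # cells x regions: fast per-region column access
  rows <- vector("list", nrow(x))
  for (j in seq_len(nrow(x))) {
    w <- xt[, j]
    rows[[j]] <- lrt_single_region(w[i1], q[i1], w[i2], q[i2],
                                   L_p[j], s1, s2, diploid)
  }
  out <- do.call(rbind, rows)
  out <- cbind(region_id = region_ids, out, stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  tested <- out$status == "tested"
  out$fdr[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$is_dar <- !is.na(out$fdr) & out$fdr <= fdr
  out
}
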