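## Evaluation harness: type I error and power against simulated truth, a
## depth-normalized Wilcoxon rank-sum comparator, permutation-calibrated
## critical values, and the pseudotrue-union power protocol for real data
## where truth is unknown.

#' Type I error and power at a nominal level
#'
#' @param p_values Per-region p-values.
#' @param truth Logical vector: TRUE for true DAR regions.
#' @param alpha Nominal significance level (default 0.05).
#' @return List with \code{type1} (fraction of null regions with
#'   p < alpha) and \code{power} (fraction of true DAR regions with
#'   p < alpha); \code{NA} when the corresponding stratum is empty.
#' @export
type1_power <- function(p_values, truth, alpha = 0.05) {
  stopifnot(length(p_values) == length(truth))
  truth <- as.logical(truth)
  list(type1 = if (any(!truth)) mean(p_values[!truth] < alpha) else NA_real_,
       power = if (any(truth)) mean(p_values[truth] < alpha) else NA_real_)
}

#' Depth-normalized Wilcoxon rank-sum comparator
#'
#' Per-region two-sided Wilcoxon rank-sum test on depth-normalized counts
#' (each cell's counts scaled by its total, times the median depth), as a
#' built-in stand-in for external rank-based DAR tools so that power
#' comparisons run offline.
#'
#' @param m \code{\link{CountMatrix}} or sparse matrix (regions x cells).
#' @param labels Two-level factor of group assignments.
#' @param normalize Depth-normalize counts first (default TRUE).
#' @return Data frame with \code{region_id} and \code{p_value}.
#' @export
wilcoxon_dar_test <- function(m, labels, normalize = TRUE) {
  x <- .get_counts(m)
  labels <- as.factor(labels)
  stopifnot(length(labels) == ncol(x), nlevels(labels) == 2L)
  region_ids <- if (inherits(m, "CountMatrix")) m$regions$region_id
                else as.character(seq_len(nrow(x)))
  if (normalize) {
    d <- Matrix::colSums(x)
    d[d == 0] <- 1
    x <- x %*% Matrix::Diagonal(ncol(x), stats::median(d) / d)
  }
  i1 <- which(labels == levels(labels)[1])
  i2 <- which(labels == levels(labels)[2])
  xt <- Matrix::t(x)
  p <- numeric(nrow(x))
  for (j in seq_len(nrow(x))) {
    w <- xt[, j]
    if (all(w == 0)) { p[j] <- 1; next }
    p[j] <- suppressWarnings(
      wilcox.test(w[i1], w[i2], alternative = "two.sided", exact = FALSE)$p.value)
    if (is.na(p[j])) p[j] <- 1
  }
  data.frame(region_id = region_ids, p_value = p, stringsAsFactors = FALSE)
}

#' Permutation-calibrated critical p-value
#'
#' Randomly relabels cells \code{n_perm} times, reruns the test, pools the
#' per-region permutation p-values and returns their \code{alpha} rank
#' percentile: the critical value at which the test's empirical null
#' rejection rate equals \code{alpha}, correcting anti-conservative or
#' conservative behavior.
#'
#' @param test_fun Function \code{(m, labels) -> data.frame} with a
#'   \code{p_value} column (e.g. \code{\link{wilcoxon_dar_test}} or a
#'   wrapper around \code{\link{dar_test_matrix}}).
#' @param m Count matrix passed through to \code{test_fun}.
#' @param labels Group labels whose sizes are preserved under permutation.
#' @param n_perm Number of label permutations (>= 1).
#' @param alpha Target level (default 0.05).
#' @return Critical p-value (scalar).
#' @export
permutation_critical_value <- function(test_fun, m, labels, n_perm = 20,
                                       alpha = 0.05) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  labels <- as.factor(labels)
  pooled <- unlist(lapply(seq_len(n_perm), function(b) {
    test_fun(m, sample(labels))$p_value
  }))
  unname(quantile(pooled, probs = alpha, type = 1))
}

#' Power against the pseudotrue union DAR set
#'
#' When truth is unknown, the pseudotrue DAR set is the union of all
#' methods' calls at their calibrated critical values; each method's power
#' is its number of calls divided by the union size.
#'
#' @param p_list Named list of per-region p-value vectors, one per method
#'   (identical region order).
#' @param critical_values Named numeric vector of per-method critical
#'   p-values.
#' @return Data frame with \code{method}, \code{n_called}, \code{n_union},
#'   \code{power}.
#' @export
pseudotrue_union_power <- function(p_list, critical_values) {
  stopifnot(length(p_list) >= 1,
            all(names(p_list) %in% names(critical_values)))
  calls <- lapply(names(p_list), function(m)
    p_list[[m]] < critical_values[[m]])
  union_set <- Reduce(`|`, calls)
  n_union <- sum(union_set)
  data.frame(method = names(p_list),
             n_called = vapply(calls, sum, integer(1)),
             n_union = n_union,
             power = if (n_union > 0)
               vapply(calls, sum, integer(1)) / n_union else NA_real_,
             stringsAsFactors = FALSE)
}
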