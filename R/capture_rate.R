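## Zero-adjusted open-probability / capture-rate model.
##
## Observed open status y_jc is the product of a biological open indicator
## Z_jc ~ Bernoulli(p_j) and a technical capture indicator T_c ~ Bernoulli(q_c):
## a zero is either a closed region or a capture failure.  p and q are fitted
## by alternating moment updates (coordinate descent).

#' Binarize a count matrix to open/closed status
#'
#' @param m A \code{\link{CountMatrix}} or a (sparse) numeric matrix.
#' @return A sparse binary matrix with 1 where the count is positive.
#' @export
binarize <- function(m) {
  x <- .get_counts(m)
  x@x <- rep(1, length(x@x))
  x <- Matrix::drop0(x)
  x
}

#' Zero-adjusted estimation of open probabilities and capture rates
#'
#' Alternates the two moment updates
#' \eqn{q_c = \sum_j y_{jc} / \sum_j p_j} and
#' \eqn{p_j = \sum_c y_{jc} / \sum_c q_c}
#' until the largest parameter change falls below \code{tol}.  Estimates are
#' clamped into their valid ranges (\code{p} into [0,1], \code{q} into
#' (\code{eps}, 1]); the (p, q) scale trade-off — only the products
#' \eqn{p_j q_c} are identified — is resolved by the \code{q <= 1} clamp,
#' which drives the fixed point to \code{max(q) = 1}.
#'
#' At an interior fixed point the row/column-sum identities
#' \eqn{\sum_j p_j q_c = \sum_j y_{jc}} and
#' \eqn{\sum_c p_j q_c = \sum_c y_{jc}} hold by construction.
#'
#' @param y Binary J x C matrix (regions by cells); a
#'   \code{\link{CountMatrix}} or count matrix is binarized first.
#' @param tol Convergence tolerance on the maximum parameter change.
#' @param max_iter Maximum number of iterations.
#' @param eps Lower clamp for capture rates (they are later used as divisors).
#' @param trace_loglik Record the log-likelihood trace (quadratic cost per
#'   iteration in the matrix size; disable for large matrices).
#' @param p_init Optional initial open-probability vector; default is the
#'   per-region nonzero cell fraction.  The fitted products \eqn{p_j q_c}
#'   do not depend on the initialization.
#' @return An object of class \code{capture_estimate}: list with per-region
#'   open probabilities \code{p}, per-cell capture rates \code{q},
#'   \code{loglik} trace, \code{iterations}, \code{converged}, and a
#'   \code{non_identifiable} flag (all-zero input).
#' @export
estimate_capture <- function(y, tol = 1e-6, max_iter = 100, eps = 1e-6,
                             trace_loglik = FALSE, p_init = NULL) {
  y <- binarize(y)
  J <- nrow(y); C <- ncol(y)
  R <- Matrix::rowSums(y)   # per-region open cells
  S <- Matrix::colSums(y)   # per-cell open regions
  if (sum(R) == 0) {
    return(structure(list(p = numeric(J), q = rep(NA_real_, C),
                          loglik = numeric(0), iterations = 0L,
                          converged = TRUE, non_identifiable = TRUE,
                          n_clamped = 0L),
                     class = "capture_estimate"))
  }
  p <- if (is.null(p_init)) R / C else {   # default: nonzero cell fraction
    stopifnot(length(p_init) == J, all(p_init >= 0 & p_init <= 1))
    p_init
  }
  if (sum(p) == 0) p <- R / C
  q <- rep(NA_real_, C)
  ll <- numeric(0)
  n_clamped <- 0L
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    q_new <- S / sum(p)
    lo <- q_new < eps
    n_clamped <- n_clamped + sum(lo)
    q_new[lo] <- eps
    p_new <- R / sum(q_new)
    ## only the products p_j q_c are identified; fix the free scale at the
    ## point the q <= 1 clamp converges to, max(q) = 1, which keeps both
    ## moment identities intact (they depend on the products only)
    alpha <- max(q_new)
    q_new <- q_new / alpha
    p_new <- p_new * alpha
    php <- p_new > 1
    n_clamped <- n_clamped + sum(php)
    p_new[php] <- 1
    delta <- max(max(abs(p_new - p)), if (all(is.na(q))) Inf else max(abs(q_new - q)))
    p <- p_new; q <- q_new
    if (trace_loglik) ll <- c(ll, capture_loglik(p, q, y))
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(p = p, q = q, loglik = ll, iterations = it,
                 converged = converged, non_identifiable = FALSE,
                 n_clamped = n_clamped),
            class = "capture_estimate")
}

#' @export
print.capture_estimate <- function(x, ...) {
  cat(sprintf("capture_estimate: %d regions, %d cells; %d iterations (%s)\n",
              length(x$p), length(x$q), x$iterations,
              if (x$non_identifiable) "non-identifiable"
              else if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Bernoulli log likelihood of the zero-adjusted open/capture model
#'
#' \eqn{\log L(p, q | y) = \sum_{j,c} [ y_{jc} \log(p_j q_c) +
#' (1 - y_{jc}) \log(1 - p_j q_c) ]}, with the \eqn{0 \log 0 := 0} convention
#' at boundary products.
#'
#' @param p Per-region open probabilities in [0, 1].
#' @param q Per-cell capture rates in [0, 1].
#' @param y Binary J x C matrix.
#' @return Scalar log likelihood.
#' @export
capture_loglik <- function(p, q, y) {
  y <- binarize(y)
  stopifnot(length(p) == nrow(y), length(q) == ncol(y))
  pq <- outer(p, q)
  yd <- as.matrix(y)
  t1 <- ifelse(yd == 1, ifelse(pq > 0, log(pq), -Inf), 0)
  t0 <- ifelse(yd == 0, ifelse(pq < 1, log1p(-pq), -Inf), 0)
  ## 0*log(0) terms: y == 1 with pq == 0 is a genuine impossibility (-Inf);
  ## y == 0 with pq == 1 likewise
  sum(t1) + sum(t0)
}
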