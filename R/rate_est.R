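## Insertion-rate estimation from observed PIC counts.
##
## Both estimators correct for per-cell capture: the moment estimator inverts
## the expected observed count, the MLE maximizes the capture-thinned
## ssPoisson likelihood.  Estimation assumes diploid cells by default (total
## count is the sum over two alleles with a shared rate).

## diploid pmf truncated where the tail mass drops below `tail`; used by the
## likelihood so its length adapts to lambda rather than to a fixed cap
.diploid_pmf_trunc <- function(lam, L_p, s1, s2, tail = 1e-10, diploid = TRUE) {
  p <- sspoisson_params(lam, L_p, s1, s2)
  pv <- if (diploid) .diploid_pmf_vec(p) else .sspois_pmf_vec(p)
  cs <- cumsum(pv)
  keep <- which(cs < 1 - tail)
  n <- if (length(keep)) min(length(pv), max(keep) + 2L) else min(length(pv), 2L)
  pv[seq_len(n)]
}

#' Log likelihood of observed PIC counts at a given insertion rate
#'
#' \eqn{LL(\lambda | w_i, q_i) = \sum_i \log P_\lambda(W_o = w_i)}, with the
#' observed-count pmf obtained by thinning the (diploid) ssPoisson pmf with
#' each cell's capture rate.
#'
#' @param lam Insertion rate (>= 0).
#' @param w Integer vector of observed PIC counts (one per cell).
#' @param q Per-cell capture rates in (0, 1].
#' @param L_p,s1,s2 Region length and fragment-size window (bp).
#' @param diploid Model counts as the sum over two alleles (default TRUE).
#' @return Scalar log likelihood.
#' @export
pic_loglik <- function(lam, w, q, L_p = 500, s1 = 25, s2 = 600, diploid = TRUE) {
  stopifnot(length(w) == length(q), all(q > 0 & q <= 1), all(w >= 0))
  w <- as.integer(w)
  if (lam <= 0) {
    ## degenerate at zero counts
    return(if (all(w == 0L)) 0 else -Inf)
  }
  pd <- .diploid_pmf_trunc(lam, L_p, s1, s2, diploid = diploid)
  if (length(pd) <= max(w)) pd <- c(pd, numeric(max(w) + 1L - length(pd)))
  observed_loglik_cpp(w, as.numeric(q), pd)
}

## monotone-increasing range of the expected count in lambda; beyond roughly
## L_p/s1 the size filter dominates and the mean turns over, so moment
## inversion is restricted to the increasing branch
.moment_cap <- function(L_p, s1) max(5, L_p / s1)

#' Moment estimator of the insertion rate
#'
#' Computes the missing-corrected mean count
#' \eqn{\bar{\bar w} = (\sum_i w_i / q_i) / c} and inverts the expected
#' observed-count curve \eqn{E[W'_s](\lambda)} by monotone root-finding.
#'
#' @inheritParams pic_loglik
#' @return Estimated insertion rate (scalar).  Returns 0 for all-zero counts;
#'   if the corrected mean exceeds the achievable expectation on the monotone
#'   range the estimate is capped with a warning.
#' @export
moment_estimate <- function(w, q, L_p = 500, s1 = 25, s2 = 600, diploid = TRUE) {
  stopifnot(length(w) == length(q), all(q > 0 & q <= 1), all(w >= 0))
  wbar <- mean(w / q)
  if (wbar <= 0) return(0)
  cap <- .moment_cap(L_p, s1)
  f <- function(l) .expected_pic(l, L_p, s1, s2, diploid) - wbar
  if (f(cap) < 0) {
    warning("corrected mean count exceeds the achievable expectation; estimate capped")
    return(cap)
  }
  uniroot(f, lower = 1e-10, upper = cap, tol = 1e-9)$root
}

#' Maximum likelihood estimator of the insertion rate
#'
#' Bounded one-dimensional optimization of \code{\link{pic_loglik}} on the
#' log-rate scale, bracketed around the moment estimate (expanding to the
#' full working range \eqn{[10^{-4}, 50]} when the maximum lands on an edge).
#'
#' @inheritParams pic_loglik
#' @param tol Convergence tolerance on log lambda.
#' @return List with elements \code{lambda}, \code{loglik} and
#'   \code{boundary} (TRUE when the estimate sits at the degenerate zero-count
#'   boundary or the upper cap).
#' @export
mle_estimate <- function(w, q, L_p = 500, s1 = 25, s2 = 600, diploid = TRUE,
                         tol = 1e-6) {
  stopifnot(length(w) == length(q), all(q > 0 & q <= 1), all(w >= 0))
  w <- as.integer(w)
  if (all(w == 0L))
    return(list(lambda = 0, loglik = 0, boundary = TRUE))
  lo_all <- log(1e-4); hi_all <- log(50)
  mom <- moment_estimate(w, q, L_p, s1, s2, diploid)
  mom <- min(max(mom, 1e-3), 45)
  lo <- max(lo_all, log(mom / 20)); hi <- min(hi_all, log(mom * 20))
  nll <- function(x) -pic_loglik(exp(x), w, q, L_p, s1, s2, diploid)
  repeat {
    opt <- optimize(nll, c(lo, hi), tol = tol)
    at_lo <- opt$minimum - lo < 2 * tol && lo > lo_all + 1e-12
    at_hi <- hi - opt$minimum < 2 * tol && hi < hi_all - 1e-12
    if (at_lo) { lo <- max(lo_all, lo - 2); next }
    if (at_hi) { hi <- min(hi_all, hi + 2); next }
    break
  }
  lam <- exp(opt$minimum)
  list(lambda = lam, loglik = -opt$objective,
       boundary = opt$minimum <= lo_all + 2 * tol || opt$minimum >= hi_all - 2 * tol)
}

#' Poisson baseline estimator of the insertion rate
#'
#' Fits a plain Poisson mean to the missing-corrected counts and applies the
#' twofold correction from fragments to insertions (each fragment is bounded
#' by two insertions): \eqn{\hat\lambda = 2 \bar{\bar w}} on the insertion
#' scale, divided by the number of alleles when \code{diploid} so that the
#' result is comparable to the per-allele ssPoisson estimates.
#'
#' @inheritParams pic_loglik
#' @return Estimated insertion rate (scalar).
#' @export
poisson_baseline <- function(w, q, diploid = FALSE) {
  stopifnot(length(w) == length(q), all(q > 0 & q <= 1), all(w >= 0))
  wbar <- mean(w / q)
  2 * wbar / (if (diploid) 2 else 1)
}
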