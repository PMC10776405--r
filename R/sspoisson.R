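#' @useDynLib picount, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dpois dbinom qpois pchisq p.adjust optimize uniroot
#'   rbinom runif quantile wilcox.test
NULL

#' Parameters of the size-filtered signed Poisson (ssPoisson) family
#'
#' Bundles the insertion rate with the experimental constants that govern
#' size selection: the region width and the minimum/maximum amplifiable
#' fragment length.
#'
#' @param lam Insertion rate per region per allele (expected number of Tn5
#'   insertions); must be >= 0.
#' @param L_p Region (peak) length in bp.
#' @param s1 Minimum amplifiable/mappable fragment length in bp (default 25,
#'   the post-overhang-correction lower limit used by standard pipelines).
#' @param s2 Maximum fragment length in bp (default 600; ATAC libraries show
#'   a scarcity of fragments beyond this length, indicating size selection).
#' @return An object of class \code{sspoisson_params}.
#' @export
sspoisson_params <- function(lam, L_p = 500, s1 = 25, s2 = 600) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("'lam' must be a single non-negative number")
  if (!(L_p > 0)) stop("'L_p' must be positive")
  if (!(s1 > 0 && s2 > s1)) stop("need 0 < s1 < s2")
  structure(list(lam = lam, L_p = L_p, s1 = s1, s2 = s2),
            class = "sspoisson_params")
}

#' @export
print.sspoisson_params <- function(x, ...) {
  cat(sprintf("ssPoisson parameters: lambda = %g, L_p = %g bp, s1 = %g bp, s2 = %g bp\n",
              x$lam, x$L_p, x$s1, x$s2))
  invisible(x)
}

## Truncation rule for the infinite series: sum the latent Poisson insertion
## count up to its 1 - 1e-12 quantile (hard cap 1000).  Beyond that point the
## neglected mass is < 1e-12, so normalization holds to well within 1e-8.
.pois_trunc <- function(lam, tail = 1e-12, cap = 1000L) {
  if (lam <= 0) return(0L)
  min(cap, as.integer(qpois(1 - tail, lam)) + 2L)
}

## Full pmf vector of the signed Poisson distribution (amplifiable insertion
## pairs W) on 0..N.  Given n insertions the number of amplifiable pairs is
## Binomial(n - 1, 1/2): each of the n - 1 adjacent gaps independently has a
## viable Tn5 primer configuration with probability 1/2.
.signed_pmf_vec <- function(lam) {
  N <- .pois_trunc(lam)
  if (N == 0L) return(1)
  n <- 0:N
  pn <- dpois(n, lam)
  sizes <- pmax(n - 1L, 0L)
  M <- max(sizes)
  ## rows m = 0..M, cols n
  mat <- vapply(seq_along(n),
                function(i) dbinom(0:M, sizes[i], 0.5),
                numeric(M + 1L))
  ## n = 0 has no insertions hence zero pairs; dbinom(., size = 0, .) already
  ## puts all mass at m = 0, which is the correct limit.
  as.vector(mat %*% pn)
}

#' Signed Poisson probability mass function
#'
#' Distribution of the number of PCR-amplifiable insertion pairs in a region,
#' given Poisson(\code{lam}) Tn5 insertions and the requirement that the two
#' transposase adapter ends facing each gap match (probability 1/2 per gap,
#' independently).
#'
#' @param m Vector of non-negative integer counts.
#' @param lam Insertion rate (>= 0).
#' @return \code{P(W = m)} for each element of \code{m}.
#' @export
pmf_signed_poisson <- function(m, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("'lam' must be a single non-negative number")
  if (any(m < 0) || any(m != floor(m))) stop("'m' must be non-negative integers")
  pv <- .signed_pmf_vec(lam)
  out <- numeric(length(m))
  inside <- m < length(pv)
  out[inside] <- pv[m[inside] + 1L]
  out
}

#' Mean and variance of the signed Poisson distribution
#'
#' Closed forms: mean \eqn{(\lambda - 1 + e^{-\lambda})/2} and variance
#' \eqn{(2\lambda + 2e^{-\lambda} - 2\lambda e^{-\lambda} - e^{-2\lambda} - 1)/4}.
#' The primer-configuration requirement yields a mean below the Poisson mean
#' and a variance exceeding the mean (overdispersion).
#'
#' @param lam Insertion rate (>= 0).
#' @return Named numeric vector with elements \code{mean} and \code{variance}.
#' @export
signed_poisson_moments <- function(lam) {
  if (any(lam < 0)) stop("'lam' must be non-negative")
  m <- (lam - 1 + exp(-lam)) / 2
  v <- (2 * lam + 2 * exp(-lam) - 2 * lam * exp(-lam) - exp(-2 * lam) - 1) / 4
  c(mean = m, variance = v)
}

#' Per-fragment retention probability under size selection (exponential
#' approximation)
#'
#' Constant-rate approximation to the probability that an amplifiable pair
#' survives the fragment-length window \code{[s1, s2]}:
#' \eqn{(e^{-s_1\lambda/L_p} - e^{-s_2\lambda/L_p}) / (1 - e^{-\lambda})},
#' clamped into [0, 1].  The unclamped ratio exceeds 1 for small \eqn{\lambda}
#' with the default constants (its \eqn{\lambda \to 0} limit is
#' \eqn{(s_2 - s_1)/L_p}), so clamping is required for a valid thinning
#' probability.
#'
#' @param params An \code{\link{sspoisson_params}} object.
#' @param clamp Clamp the ratio into [0, 1] (default TRUE).
#' @return Retention probability (scalar).
#' @export
sspoisson_retention <- function(params, clamp = TRUE) {
  lam <- params$lam
  if (lam <= 0) return(1)
  num <- exp(-params$s1 * lam / params$L_p) - exp(-params$s2 * lam / params$L_p)
  r <- num / (1 - exp(-lam))
  if (clamp) r <- min(1, max(0, r))
  r
}

## P(adjacent-insertion gap >= s) for n distinct uniform insertion loci on a
## region of L discrete positions: C(L - s + 1, n) / C(L, n)  (0 when the n
## loci cannot all fit).  Exact for the per-bp Bernoulli mechanism; the
## continuous-spacing limit (1 - s/L)^(n-1) overstates survival noticeably
## at the default s1 = 25.
.gap_survival <- function(n, s, L) {
  out <- exp(lchoose(L - s + 1, n) - lchoose(L, n))
  out[L - s + 1 < n] <- 0
  out
}

## exact pmf of T = number of adjacent gaps >= s among n distinct uniform
## insertion loci on L discrete positions.  Any j specific gaps are jointly
## >= s with probability C(L - j(s-1), n)/C(L, n) (contract each long gap by
## s - 1 positions); inclusion-exclusion then gives P(T = t) by
## exchangeability.  Tiny negative values from cancellation are clamped.
.gap_count_pmf <- function(n, s, L) {
  nb <- n - 1L
  jj <- 0:nb
  Nj <- exp(lchoose(L - jj * (s - 1), n) - lchoose(L, n))
  Nj[L - jj * (s - 1) < n] <- 0
  pt <- vapply(0:nb, function(t) {
    i <- 0:(nb - t)
    choose(nb, t) * sum((-1)^i * choose(nb - t, i) * Nj[t + i + 1L])
  }, numeric(1))
  pt[pt < 0] <- 0
  pt / sum(pt)
}

## cache of lambda-independent conditional pmf matrices, keyed by the
## size-selection constants
.pic_cache <- new.env(parent = emptyenv())

## matrix M[k + 1, n + 1] = P(W_s = k | X = n) for n = 0..Nmax.  Given n, the
## number T of gaps passing the lower size bound follows the exact
## inclusion-exclusion distribution (gap lengths are dependent: they share
## the region) and W_s | T ~ Binomial(T, 1/2).  For n - 1 > 30 (alternating
## sum loses precision) or an active upper bound (s2 < L_p - 1) the
## independent-thinning approximation with the marginal survival is used.
.cond_pair_pmf_matrix <- function(s1, s2, L, Nmax) {
  key <- sprintf("%g:%g:%g", s1, s2, L)
  M <- .pic_cache[[key]]
  if (!is.null(M) && ncol(M) >= Nmax + 1L) return(M)
  upper_active <- min(s2, L) < L - 1
  M <- matrix(0, nrow = Nmax + 1L, ncol = Nmax + 1L)
  M[1L, 1L] <- 1
  if (Nmax >= 1L) M[1L, 2L] <- 1
  for (n in seq_len(Nmax)[-1L]) {
    nb <- n - 1L
    if (!upper_active && nb <= 30L) {
      pt <- .gap_count_pmf(n, s1, L)
      wn <- numeric(Nmax + 1L)
      for (t in 0:nb)
        wn[1:(t + 1L)] <- wn[1:(t + 1L)] + pt[t + 1L] * dbinom(0:t, t, 0.5)
    } else {
      rn <- .gap_survival(n, s1, L) - .gap_survival(n, min(s2, L) + 1, L)
      wn <- dbinom(0:Nmax, nb, 0.5 * rn)
    }
    M[, n + 1L] <- wn
  }
  .pic_cache[[key]] <- M
  M
}

.sspois_pmf_vec <- function(params,
                            variant = c("spacing", "exponential", "printed")) {
  variant <- match.arg(variant)
  lam <- params$lam
  if (lam <= 0) return(1)
  if (variant == "spacing") {
    ## stratify by the latent insertion count n: each of the n - 1 adjacent
    ## gaps is amplifiable with probability 1/2 (independent primer
    ## configurations) and must fall in the size window.  The conditional
    ## pmf given n does not depend on lambda, so it is cached per
    ## (s1, s2, L_p) and the mixture is a matrix-vector product.
    N <- .pois_trunc(lam)
    M <- .cond_pair_pmf_matrix(params$s1, params$s2, params$L_p, N)
    return(as.vector(M[seq_len(N + 1L), seq_len(N + 1L)] %*% dpois(0:N, lam)))
  }
  pw <- .signed_pmf_vec(lam)
  M <- length(pw) - 1L
  if (variant == "exponential") {
    r <- sspoisson_retention(params)
    mat <- vapply(0:M, function(m) dbinom(0:M, m, r), numeric(M + 1L))
  } else {
    ## literal second factor 1 - (A + B)/D; not complementary to the first,
    ## so the result need not normalize (kept for comparison only)
    A <- exp(-params$s1 * lam / params$L_p)
    B <- exp(-params$s2 * lam / params$L_p)
    D <- 1 - exp(-lam)
    a <- (A - B) / D
    b <- 1 - (A + B) / D
    mat <- vapply(0:M, function(m) {
      k <- 0:M
      out <- choose(m, k) * a^k * b^(m - k)
      out[k > m] <- 0
      out
    }, numeric(M + 1L))
  }
  as.vector(mat %*% pw)
}

#' Size-filtered signed Poisson (ssPoisson) probability mass function
#'
#' Distribution of observed size-selected fragment (paired-insertion) counts:
#' amplifiable pairs of the signed Poisson process are thinned by the
#' probability that the inter-insertion distance falls inside the
#' \code{[s1, s2]} window.
#'
#' Three variants are provided, all normalized except the last:
#' \describe{
#'   \item{\code{"spacing"} (default)}{thins within each latent
#'     insertion-count stratum with the exact uniform-spacing survival
#'     probability \eqn{r_n = C(L_p - s_1 + 1, n)/C(L_p, n) -
#'     C(L_p - \min(s_2, L_p), n)/C(L_p, n)}; this is the distribution the
#'     fragment-generation mechanism actually follows and is used throughout
#'     estimation and testing.}
#'   \item{\code{"exponential"}}{constant per-pair retention
#'     \code{\link{sspoisson_retention}} (the exponential-spacing
#'     approximation) with complementary failure probability so the pmf
#'     normalizes.}
#'   \item{\code{"printed"}}{the literal series with the non-complementary
#'     failure factor \eqn{1 - (A+B)/D}; does not normalize in general and is
#'     retained for comparison only.}
#' }
#'
#' @param k Vector of non-negative integer counts.
#' @param params An \code{\link{sspoisson_params}} object.
#' @param variant \code{"spacing"} (default), \code{"exponential"} or
#'   \code{"printed"}.
#' @return \code{P(W_s = k)} for each element of \code{k}.
#' @export
pmf_sspoisson <- function(k, params,
                          variant = c("spacing", "exponential", "printed")) {
  if (any(k < 0) || any(k != floor(k))) stop("'k' must be non-negative integers")
  pv <- .sspois_pmf_vec(params, variant)
  out <- numeric(length(k))
  inside <- k < length(pv)
  out[inside] <- pv[k[inside] + 1L]
  out
}

## convolution of a pmf vector with itself (diploid sum of two iid alleles)
.self_convolve <- function(p) {
  K <- length(p)
  out <- numeric(2L * K - 1L)
  for (i in seq_len(K)) {
    idx <- i:(i + K - 1L)
    out[idx] <- out[idx] + p[i] * p
  }
  out
}

.diploid_pmf_vec <- function(params, variant = "spacing") {
  .self_convolve(.sspois_pmf_vec(params, variant))
}

#' Diploid paired-insertion count pmf
#'
#' Total PIC count over the two alleles of a diploid cell, assuming both
#' alleles share the same insertion rate and insert independently: the
#' convolution of two independent ssPoisson variables,
#' \eqn{P(W' = r) = \sum_k P(W_{s,1} = k) P(W_{s,2} = r - k)}.
#'
#' @param r Vector of non-negative integer counts.
#' @param params An \code{\link{sspoisson_params}} object (per-allele rate).
#' @return \code{P(W' = r)} for each element of \code{r}.
#' @export
pmf_diploid <- function(r, params) {
  if (any(r < 0) || any(r != floor(r))) stop("'r' must be non-negative integers")
  pv <- .diploid_pmf_vec(params)
  out <- numeric(length(r))
  inside <- r < length(pv)
  out[inside] <- pv[r[inside] + 1L]
  out
}

## binomial thinning of a pmf vector by capture rate q
.thin_pmf_vec <- function(p, q) {
  K <- length(p) - 1L
  mat <- vapply(0:K, function(k) dbinom(0:K, k, q), numeric(K + 1L))
  as.vector(mat %*% p)
}

#' Observed-count pmf under capture thinning
#'
#' Distribution of the PIC count actually observed in sequencing: each of the
#' cell's diploid fragments is captured independently with the per-cell
#' capture rate \code{q} (binomial thinning of \code{\link{pmf_diploid}}).
#'
#' @param t Vector of non-negative integer counts.
#' @param params An \code{\link{sspoisson_params}} object.
#' @param q Capture rate in (0, 1].
#' @return \code{P(W_o = t)} for each element of \code{t}.
#' @export
pmf_observed <- function(t, params, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
    stop("'q' must be in (0, 1]")
  if (any(t < 0) || any(t != floor(t))) stop("'t' must be non-negative integers")
  pv <- .thin_pmf_vec(.diploid_pmf_vec(params), q)
  out <- numeric(length(t))
  inside <- t < length(pv)
  out[inside] <- pv[t[inside] + 1L]
  out
}

#' Expected observed PIC count
#'
#' \eqn{E[W_o] = q\,E[W'_s]}, where \eqn{E[W'_s]} is obtained by truncated
#' summation of the diploid pmf.  Linear in the capture rate.
#'
#' @param params An \code{\link{sspoisson_params}} object.
#' @param q Capture rate in (0, 1].
#' @param diploid Sum over two alleles (default TRUE).
#' @return Expected observed count (scalar).
#' @export
expected_observed <- function(params, q, diploid = TRUE) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
    stop("'q' must be in (0, 1]")
  pv <- if (diploid) .diploid_pmf_vec(params) else .sspois_pmf_vec(params)
  q * sum((seq_along(pv) - 1) * pv)
}

## expected PIC count (per cell, before capture) under the default spacing
## variant: E[W_s] = sum_n Pois(n; lam) (n-1)/2 r_n; doubled for diploid.
## Agrees with truncated summation of the pmf to ~1e-12.
.expected_pic <- function(lam, L_p = 500, s1 = 25, s2 = 600, diploid = TRUE) {
  if (lam <= 0) return(0)
  N <- .pois_trunc(lam)
  nn <- 0:N
  rn <- .gap_survival(nn, s1, L_p) -
    .gap_survival(nn, min(s2, L_p) + 1, L_p)
  rn[nn < 2L] <- 1
  e <- sum(dpois(nn, lam) * pmax(nn - 1, 0) / 2 * rn)
  (if (diploid) 2 else 1) * e
}
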