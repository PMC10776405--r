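test_that("zero insertion rate degenerates every pmf at zero", {
  p0 <- sspoisson_params(0)
  expect_equal(pmf_signed_poisson(0:3, 0), c(1, 0, 0, 0))
  expect_equal(pmf_sspoisson(0:3, p0), c(1, 0, 0, 0))
  expect_equal(pmf_diploid(0:3, p0), c(1, 0, 0, 0))
  expect_equal(pmf_observed(0:3, p0, q = 1), c(1, 0, 0, 0))
  expect_equal(signed_poisson_moments(0), c(mean = 0, variance = 0))
})

test_that("pmfs are non-negative and normalize after truncation", {
  for (lam in c(0.1, 1, 2, 2.5)) {
    p <- sspoisson_params(lam)
    for (pv in list(picount:::.signed_pmf_vec(lam),
                    picount:::.sspois_pmf_vec(p),
                    picount:::.sspois_pmf_vec(p, "exponential"),
                    picount:::.diploid_pmf_vec(p),
                    picount:::.thin_pmf_vec(picount:::.diploid_pmf_vec(p), 0.4))) {
      expect_true(all(pv >= 0))
      expect_equal(sum(pv), 1, tolerance = 1e-8)
    }
  }
})

test_that("closed-form signed Poisson moments match direct summation of the pmf", {
  for (lam in c(0.3, 1, 2.5, 6)) {
    pv <- picount:::.signed_pmf_vec(lam)
    k <- seq_along(pv) - 1
    mu <- sum(k * pv)
    v <- sum(k^2 * pv) - mu^2
    mom <- signed_poisson_moments(lam)
    expect_equal(unname(mom["mean"]), mu, tolerance = 1e-9)
    expect_equal(unname(mom["variance"]), v, tolerance = 1e-9)
  }
  # frozen spot values at lam = 1 (independently: direct summation above)
  expect_equal(unname(signed_poisson_moments(1)["mean"]), 0.18394, tolerance = 1e-4)
  expect_equal(unname(signed_poisson_moments(1)["variance"]), 0.21617, tolerance = 1e-4)
})

test_that("primer pairing lowers the mean below Poisson and overdisperses", {
  lam <- seq(0.1, 10, by = 0.3)
  mom <- sapply(lam, signed_poisson_moments)
  expect_true(all(mom["mean", ] < lam))
  expect_true(all(mom["variance", ] > mom["mean", ]))
})

test_that("the exponential retention ratio exceeds one at small rates and is clamped", {
  p <- sspoisson_params(0.01)
  raw <- sspoisson_retention(p, clamp = FALSE)
  expect_gt(raw, 1)                       # limit (s2 - s1)/L_p = 1.15
  expect_equal(sspoisson_retention(p), 1)
  expect_lt(sspoisson_retention(sspoisson_params(3)), 1)
})

test_that("without a size filter the spacing variant collapses to the signed Poisson", {
  for (lam in c(0.5, 2)) {
    p <- sspoisson_params(lam, L_p = 500, s1 = 1, s2 = 600)
    a <- picount:::.sspois_pmf_vec(p)
    b <- picount:::.signed_pmf_vec(lam)
    n <- max(length(a), length(b))
    expect_equal(c(a, numeric(n - length(a))), c(b, numeric(n - length(b))),
                 tolerance = 1e-12)
  }
})

test_that("the printed variant reproduces the literal series and differs from the default", {
  p <- sspoisson_params(2, L_p = 500, s1 = 25, s2 = 600)
  lam <- 2
  A <- exp(-25 * lam / 500); B <- exp(-600 * lam / 500); D <- 1 - exp(-lam)
  pw <- picount:::.signed_pmf_vec(lam)
  lit <- sapply(0:4, function(k) {
    m <- k:(length(pw) - 1)
    sum(choose(m, k) * ((A - B) / D)^k * (1 - (A + B) / D)^(m - k) * pw[m + 1])
  })
  expect_equal(pmf_sspoisson(0:4, p, variant = "printed"), lit, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pmf_sspoisson(0:4, p, variant = "printed"),
                                pmf_sspoisson(0:4, p))))
})

test_that("diploid pmf equals the brute-force double-loop convolution", {
  p <- sspoisson_params(1.2)
  ps <- picount:::.sspois_pmf_vec(p)
  K <- length(ps) - 1
  brute <- sapply(0:(2 * K), function(r) {
    tot <- 0
    for (k in 0:r)
      if (k <= K && (r - k) <= K) tot <- tot + ps[k + 1] * ps[r - k + 1]
    tot
  })
  expect_equal(pmf_diploid(0:(2 * K), p), brute, tolerance = 1e-12)
  expect_equal(pmf_diploid(0, p), pmf_sspoisson(0, p)^2)
})

test_that("capture thinning is the identity at q = 1 and linear in expectation", {
  p <- sspoisson_params(1.5)
  K <- 0:12
  expect_equal(pmf_observed(K, p, q = 1), pmf_diploid(K, p), tolerance = 1e-10)
  expect_equal(expected_observed(p, q = 0.5), 0.5 * expected_observed(p, q = 1),
               tolerance = 1e-10)
  expect_error(pmf_observed(0, p, q = 0), "q")
  expect_error(pmf_observed(0, p, q = 1.2), "q")
  expect_error(pmf_signed_poisson(0, -1), "lam")
})

test_that("expected PIC count increases with the insertion rate over the working range", {
  lam <- c(0.01, 0.05, seq(0.1, 10, by = 0.1))
  e <- sapply(lam, picount:::.expected_pic)
  expect_true(all(diff(e) > 0))
})

test_that("the dependence-exact gap-count distribution matches brute-force enumeration", {
  L <- 30L; n <- 4L; s <- 5L
  cfg <- utils::combn(L, n)
  tt <- apply(cfg, 2, function(x) sum(diff(x) >= s))
  brute <- tabulate(tt + 1, nbins = n) / ncol(cfg)
  expect_equal(picount:::.gap_count_pmf(n, s, L), brute, tolerance = 1e-12)
})
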