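test_that("mean response reduces to its analytic special cases", {
  p0 <- model_params(T = 2, N = 0, s = 5, r = 0.1, B = 1, q = 0)
  expect_equal(mean_response(p0, 0), 1)              # dose 0: background only
  expect_equal(mean_response(p0, 0.5), 2.0)          # pure linear TE

  # gamma-type parameters with B derived from r via the background constraints;
  # expected value recomputed inline from the defining formula
  p <- model_params(T = 2.77, N = 0.62, s = 38.66, r = 0.047)
  B_expect <- ((3.279 - 1) * q_approx(0.047) + 3.279) /
    (1 + q_approx(0.047) * 1.047)
  expect_equal(p$B, B_expect)
  expect_equal(mean_response(p, 0.05),
               B_expect + 0.62 * (1 - exp(-38.66 * 0.05)) + 2.77 * 0.05,
               tolerance = 1e-12)
  expect_error(mean_response(p, -0.1), "non-negative")
})

test_that("mean response is monotone non-decreasing in dose", {
  set.seed(11)
  for (i in 1:20) {
    p <- model_params(T = runif(1, 0, 10), N = runif(1, 0, 5),
                      s = runif(1, 0, 60), r = runif(1, 0, 0.3))
    d <- sort(runif(30, 0, 3))
    expect_true(all(diff(mean_response(p, d)) >= -1e-12))
  }
})

test_that("excess yield vanishes at dose 0 and matches the WNB mean difference", {
  p <- model_params(T = 2.77, N = 1.34, s = 38.66, r = 0.047)
  expect_equal(excess_yield(p, 0), 0)

  # q = 0: proportionality constant is 1
  pq0 <- model_params(T = 2, N = 1, s = 10, r = 0.1, B = 1, q = 0)
  expect_equal(excess_yield(pq0, 0.3), 1 * (1 - exp(-3)) + 0.6)

  # identity: mu_rad(D) = wnb_mean(M(D)) - wnb_mean(M(0)) on a dose grid
  for (d in c(0.01, 0.05, 0.2, 1, 2.5)) {
    expect_equal(excess_yield(p, d),
                 wnb_mean(mean_response(p, d), p$r, p$q) -
                   wnb_mean(p$B, p$r, p$q),
                 tolerance = 1e-10)
  }
  expect_true(all(excess_yield(p, seq(0, 3, by = 0.1)) >= 0))
})

test_that("variance/mean ratio has the correct limits and special cases", {
  # q = 0: plain negative binomial dispersion 1 + rM
  pq0 <- model_params(T = 1, N = 1, s = 1, r = 0.3, B = 1, q = 0)
  expect_equal(variance_to_mean(pq0, 2.5), 1 + 0.3 * 2.5)

  # small-M limit 1/(1+q)
  p <- model_params(T = 1, N = 1, s = 1, r = 0.1, B = 1, q = 1)
  expect_equal(variance_to_mean(p, 1e-8), 1 / (1 + 1), tolerance = 1e-4)
  p2 <- model_params(T = 1, N = 1, s = 1, r = 0.2, B = 1, q = 0.5)
  expect_equal(variance_to_mean(p2, 1e-8), 1 / 1.5, tolerance = 1e-4)

  # overdispersion at large M whenever r > 0
  expect_gt(variance_to_mean(p2, 50), 1)
  expect_error(variance_to_mean(p2, 0), "positive")

  # cross-check against brute-force moments of the pmf
  m <- wnb_sum_moments(2, 0.2, 0.5)
  expect_equal(variance_to_mean(model_params(T = 1, N = 1, s = 1, r = 0.2,
                                             B = 1, q = 0.5), 2),
               m$var / m$mean, tolerance = 1e-8)
})

test_that("dose/fluence conversion is dimensionally correct and round-trips", {
  expect_equal(dose_to_fluence(1, 0), 0)
  # 1 keV/um beam at 0.1602 Gy deposits exactly one ion per um^2
  expect_equal(dose_to_fluence(1, 0.1602), 1.0)
  # Fe ions, LET 148: ~0.0422 ions/um^2 per Gy
  expect_equal(dose_to_fluence(148, 1), 1 / (0.1602 * 148), tolerance = 1e-12)
  expect_equal(dose_to_fluence(148, 1), 0.0422, tolerance = 1e-3)
  expect_error(dose_to_fluence(0, 1), "positive")

  set.seed(5)
  f <- runif(20, 0, 10); let <- runif(20, 0.2, 150)
  expect_equal(dose_to_fluence(let, fluence_to_dose(let, f)), f)
})

test_that("the default dose grid is 50 log-spaced points from 1 mGy to 2.54 Gy", {
  g <- dose_grid()
  expect_length(g, 50L)
  expect_equal(g[1], 0.001)
  expect_equal(g[50], 2.54)
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 49), tolerance = 1e-12)
})
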