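test_that("response derivative matches its limits and a finite-difference oracle", {
  p <- apc_study_params()$Fe
  cc <- (p$q * p$r + p$q + 1) / (1 + p$q)
  expect_equal(response_derivative(p, 0), (p$N * p$s + p$T) * cc)
  expect_equal(response_derivative(p, 1e6), p$T * cc, tolerance = 1e-9)

  h <- 1e-6
  for (d in c(0.01, 0.05, 0.3, 1, 2)) {
    fd <- (excess_yield(p, d + h) - excess_yield(p, d - h)) / (2 * h)
    expect_equal(response_derivative(p, d), fd, tolerance = 1e-6)
  }
  # decreasing toward the TE asymptote
  g <- seq(0, 2, by = 0.1)
  expect_true(all(diff(response_derivative(p, g)) <= 1e-12))
})

test_that("inverse response round-trips over four decades of effect", {
  p <- apc_study_params()
  for (ion in names(p)) {
    for (v in 10^seq(-3, 1, by = 0.5)) {
      d <- inverse_response(p[[ion]], v)
      expect_equal(excess_yield(p[[ion]], d), v, tolerance = 1e-9)
    }
  }
  expect_equal(inverse_response(p$Fe, 0), 0)
  expect_error(inverse_response(p$Fe, -1), "non-negative")
})

test_that("inverse response has the linear closed form when N = 0 and a bisect fallback", {
  lin <- model_params(T = 3, N = 0, s = 38.66, r = 0.1)
  v <- 0.7
  expect_equal(inverse_response(lin, v),
               v * (1 + lin$q) / (3 * (1 + lin$q * (1 + lin$r))),
               tolerance = 1e-12)
  p <- apc_study_params()$Si
  expect_equal(inverse_response(p, 2, method = "bisect"),
               inverse_response(p, 2), tolerance = 1e-8)
})

test_that("mixture specification derives fractions that sum to one", {
  mix <- mars_mixture()
  expect_equal(mix$total_dose, 0.519)
  expect_equal(sum(mix$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(mix$fractions[["H"]]), 0.311 / 0.519, tolerance = 1e-12)
  expect_error(mixture_spec(apc_study_params(), c(Xx = 0.1)), "missing parameters")
})

test_that("IEA reduces to the single-component response", {
  p <- apc_study_params()
  for (ion in c("He", "Si")) {
    mix1 <- mixture_spec(p, setNames(0.3, ion))
    expect_equal(iea_predict(mix1, 0.3), excess_yield(p[[ion]], 0.3),
                 tolerance = 1e-7)
    expect_equal(iea_predict(mix1, 0.05), excess_yield(p[[ion]], 0.05),
                 tolerance = 1e-7)
  }
})

test_that("IEA equals SEA when all components share one linear response", {
  lin <- function() model_params(T = 2.5, N = 0, s = 1, r = 0.05)
  params <- list(a = lin(), b = lin(), c = lin())
  mix <- mixture_spec(params, c(a = 0.1, b = 0.2, c = 0.3))
  expect_equal(iea_predict(mix), sea_predict(mix), tolerance = 1e-7)
})

test_that("IEA is permutation invariant and bounded by the component responses", {
  p <- apc_study_params()
  doses <- c(H = 0.311, He = 0.109, C = 0.029, O = 0.029, Si = 0.022, Fe = 0.019)
  fwd <- mixture_spec(p, doses)
  rev <- mixture_spec(p, rev(doses))
  expect_equal(iea_predict(fwd), iea_predict(rev), tolerance = 1e-7)
  expect_equal(sea_predict(fwd), sea_predict(rev), tolerance = 1e-12)

  # the mixture response lies within the range of individual ion responses,
  # while SEA overshoots the most effective component along the dose ray
  for (D in c(0.1, 0.3, 0.519)) {
    each <- vapply(names(doses), function(i) excess_yield(p[[i]], D), numeric(1))
    iea <- iea_predict(fwd, D)
    expect_gte(iea, min(each))
    expect_lte(iea, max(each))
  }
})

test_that("SEA exceeds IEA for the concave fitted responses", {
  mix <- mars_mixture()
  for (D in c(0.05, 0.2, 0.519)) {
    sea_D <- sum(vapply(seq_along(mix$components), function(j)
      excess_yield(mix$params[[j]], mix$fractions[[j]] * D), numeric(1)))
    expect_gt(sea_D, iea_predict(mix, D))
  }
})

test_that("mixture report carries both predictions and their ratio", {
  rep <- mixture_report(mars_mixture())
  expect_named(rep, c("total_dose_gy", "iea", "sea", "sea_over_iea"))
  expect_equal(rep$sea_over_iea, rep$sea / rep$iea)
  expect_gt(rep$sea_over_iea, 1)
})
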