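test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-100, 2, 10), 200 + 4 + 12 / 7)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_error(aicc(-100, 9, 10), "exceed")
})

test_that("sharing schemes expand free vectors to per-type parameters", {
  sch <- default_scheme()
  expect_equal(length(tentemix:::scheme_layout(sch)), 14L)

  truth <- study_truth(sch)
  pars <- params_from_free(sch, truth)
  expect_equal(pars$gamma$T, pars$H$T)    # shared lowLET T group
  expect_equal(pars$gamma$r, pars$O$r)
  expect_equal(pars$Si$T, 8.52)
  expect_equal(pars$Fe$s, 38.66)          # s common to all
  ref <- apc_study_params()
  for (ty in names(pars)) {
    expect_equal(unclass(pars[[ty]]), unclass(ref[[ty]]), tolerance = 1e-12)
  }
})

test_that("log likelihood is additive and matches a hand-computed single record", {
  # one mouse with zero tumours at M = 1, r = 1, q = 0: pmf = (1+1)^(-1) = 0.5
  expect_equal(dwnb(0, 1, 1, 0, log = TRUE), log(0.5))

  # additivity over records on a realistic dataset
  sch <- default_scheme()
  truth <- study_truth(sch)
  d <- generate_dataset(apc_study_design(), apc_study_params(), seed = 5)
  ll_all <- wnb_log_likelihood(d, sch, truth)
  ll_sum <- sum(vapply(seq_len(nrow(d)), function(i)
    wnb_log_likelihood(d[i, , drop = FALSE], sch, truth), numeric(1)))
  expect_equal(ll_all, ll_sum, tolerance = 1e-8)

  # generating parameters beat strongly perturbed ones on large data
  ll_perturbed <- wnb_log_likelihood(d, sch, truth * 1.5)
  expect_gt(ll_all, ll_perturbed)
  ll_down <- wnb_log_likelihood(d, sch, truth * 0.5)
  expect_gt(ll_all, ll_down)
})

test_that("the analytic likelihood gradient matches finite differences", {
  sch <- default_scheme()
  truth <- study_truth(sch)
  d <- generate_dataset(apc_study_design(), apc_study_params(), seed = 2)
  g <- tentemix:::.ll_grad_context(d, sch)(truth)
  llf <- tentemix:::.ll_context(d, sch)
  gn <- vapply(seq_along(truth), function(i) {
    h <- 1e-6 * max(abs(truth[i]), 1e-3)
    up <- truth; up[i] <- up[i] + h
    dn <- truth; dn[i] <- dn[i] - h
    (llf(up) - llf(dn)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), gn, tolerance = 1e-4)
})

test_that("fitting is deterministic, respects constraints, and recovers truth on a small design", {
  d <- generate_dataset(small_design(60L), apc_study_params(), seed = 21)
  sch <- small_scheme()
  fit1 <- fit_wnb_model(d, sch, n_starts = 8, seed = 4)
  fit2 <- fit_wnb_model(d, sch, n_starts = 8, seed = 4)
  expect_identical(fit1$free, fit2$free)
  expect_identical(fit1$logLik, fit2$logLik)

  # all parameters non-negative; particle T at least the gamma T
  expect_true(all(fit1$free >= 0))
  expect_gte(fit1$params$Fe$T, fit1$params$gamma$T - 1e-10)
  expect_true(is.finite(fit1$logLik))
  expect_equal(fit1$AICc, aicc(fit1$logLik, fit1$n_free, nrow(d)))

  # rough recovery on a moderate-size design: fitted T within a factor of 2
  expect_gt(fit1$params$Fe$T, 4.74 / 2)
  expect_lt(fit1$params$Fe$T, 4.74 * 2)
})

test_that("two-stage constraint mode freezes the reference bound", {
  d <- generate_dataset(small_design(50L), apc_study_params(), seed = 31)
  fit <- fit_wnb_model(d, small_scheme(), n_starts = 6, seed = 9,
                       t_constraint = "two_stage")
  expect_false(is.null(fit$t_floor))
  expect_gte(fit$params$Fe$T, fit$t_floor - 1e-8)
})

test_that("relaxing sharing constraints never lowers the maximized likelihood", {
  d <- generate_dataset(small_design(50L), apc_study_params(), seed = 13)
  types <- c("gamma", "Fe")
  shared <- sharing_scheme(types, T = "by_type", N = "common",
                           s = "common", r = "common")
  free_sch <- sharing_scheme(types, T = "by_type", N = "by_type",
                             s = "common", r = "by_type")
  cmp <- compare_schemes(d, list(shared = shared, free = free_sch),
                         n_starts = 8, seed = 2)
  expect_equal(nrow(cmp), 2L)
  expect_true(!is.unsorted(cmp$AICc))
  fits <- attr(cmp, "fits")
  expect_gte(fits$free$logLik, fits$shared$logLik - 1e-4)
  expect_gt(fits$free$n_free, fits$shared$n_free)
})

test_that("AICc selects per-type N when the generating N values differ strongly", {
  # generating truth: He N = 0.3 vs Fe N = 3.34 under a common everything else
  truth <- list(gamma = model_params(T = 2.77, N = 0.3, s = 38.66, r = 0.047),
                Fe = model_params(T = 2.77, N = 3.34, s = 38.66, r = 0.047))
  des <- small_design(80L)
  d <- generate_dataset(des, truth, seed = 17)
  types <- c("gamma", "Fe")
  n_common <- sharing_scheme(types, T = "common", N = "common",
                             s = "common", r = "common")
  n_free <- sharing_scheme(types, T = "common", N = "by_type",
                           s = "common", r = "common")
  cmp <- compare_schemes(d, list(pooledN = n_common, perTypeN = n_free),
                         n_starts = 8, seed = 3)
  expect_equal(cmp$scheme[1], "perTypeN")
})
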