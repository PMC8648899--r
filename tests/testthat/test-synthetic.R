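test_that("the packaged design matches the study arm structure", {
  d <- apc_study_design()
  totals <- vapply(d, function(a) sum(a$groups$n_mice), numeric(1))
  expect_equal(unname(totals[c("control", "H", "He", "C", "O", "Si", "Fe", "gamma")]),
               c(68, 40, 92, 60, 66, 136, 90, 127))
  expect_equal(sum(totals), 679)

  expect_equal(d$Fe$let, 148)
  expect_equal(range(d$Fe$groups$dose_gy), c(0.05, 1.6))
  expect_equal(d$H$let, 0.22)
  expect_equal(range(d$H$groups$dose_gy), c(0.5, 1.2))
  # the 5 cGy group is present where that dose was tested
  for (a in c("gamma", "He", "O", "Si", "Fe"))
    expect_true(0.05 %in% d[[a]]$groups$dose_gy)
  expect_equal(d$control$groups$dose_gy, 0)
})

test_that("the packaged parameter fixture carries the fitted values and sharing", {
  p <- apc_study_params()
  expect_equal(p$Si$T, 8.52)
  expect_equal(p$gamma$T, p$H$T)
  expect_equal(p$gamma$r, 0.047)
  expect_true(all(vapply(p, function(x) x$s, numeric(1)) == 38.66))
  # B and q derive from r: types sharing r share B and q
  expect_equal(p$gamma$B, p$C$B)
  expect_equal(p$Si$q, q_approx(0.208))
})

test_that("dataset generation is deterministic and has the design's shape", {
  des <- apc_study_design()
  d1 <- generate_dataset(des, apc_study_params(), seed = 3)
  d2 <- generate_dataset(des, apc_study_params(), seed = 3)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 679L)
  expect_true(all(d1$tumors >= 0))
  expect_error(generate_dataset(des, apc_study_params()[c("gamma", "H")],
                                seed = 1),
               "no true parameters")
})

test_that("simulated group means track the closed-form mean at large n", {
  p <- apc_study_params()
  big <- list(gamma = list(type = radiation_type("gamma", NA, 0.3),
                           name = "gamma", energy = NA, let = 0.3,
                           groups = data.frame(dose_gy = c(0.05, 0.5),
                                               n_mice = 20000L)))
  class(big) <- "experiment_design"
  d <- generate_dataset(big, p, seed = 12)
  for (dose in c(0.05, 0.5)) {
    x <- d$tumors[d$dose_gy == dose]
    M <- mean_response(p$gamma, dose)
    mu <- wnb_mean(M, p$gamma$r, p$gamma$q)
    se <- sqrt(wnb_variance(M, p$gamma$r, p$gamma$q) / length(x))
    expect_lt(abs(mean(x) - mu), 4 * se)
  }
})

test_that("control-arm moments converge to the background-constrained values", {
  p <- apc_study_params()
  big <- list(control = list(type = NULL, name = "control", energy = NA,
                             let = NA,
                             groups = data.frame(dose_gy = 0, n_mice = 50000L)))
  class(big) <- "experiment_design"
  d <- generate_dataset(big, p, seed = 8)
  # implied moments at the gamma group's (B, q, r)
  mu <- background_mean(p$gamma$B, p$gamma$q, p$gamma$r)
  v <- background_variance(p$gamma$B, p$gamma$q, p$gamma$r)
  expect_equal(mu, 3.279, tolerance = 1e-12)   # exact by construction
  expect_equal(v, 2.625, tolerance = 0.05)     # approximant accuracy
  expect_lt(abs(mean(d$tumors) - mu), 4 * sqrt(v / nrow(d)))
  expect_lt(abs(var(d$tumors) - v), 4 * v * sqrt(2 / nrow(d)))
})

test_that("simulated arms reproduce the dispersion crossover", {
  p <- apc_study_params()
  des <- list(gamma = list(type = NULL, name = "gamma", energy = NA, let = 0.3,
                           groups = data.frame(dose_gy = 0.05, n_mice = 5000L)),
              Si = list(type = NULL, name = "Si", energy = 300, let = 69,
                        groups = data.frame(dose_gy = 1.4, n_mice = 5000L)))
  class(des) <- "experiment_design"
  d <- generate_dataset(des, p, seed = 14)
  low <- d$tumors[d$radiation == "gamma"]
  high <- d$tumors[d$radiation == "Si"]
  expect_lt(var(low) / mean(low), 1)    # underdispersed at low dose
  expect_gt(var(high) / mean(high), 1)  # overdispersed for high-dose Si
})
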