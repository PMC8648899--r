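# shared fixtures for the test suite

# free-parameter vector of the packaged study fit, in the default scheme's
# layout (used as simulation truth)
study_truth <- function(scheme = default_scheme()) {
  p <- apc_study_params()
  setNames(c(p$gamma$T, p$Si$T, p$Fe$T,
             p$gamma$N, p$H$N, p$He$N, p$C$N, p$O$N, p$Si$N, p$Fe$N,
             p$gamma$s,
             p$gamma$r, p$Si$r, p$Fe$r),
           c("T:lowLET", "T:Si", "T:Fe",
             "N:gamma", "N:H", "N:He", "N:C", "N:O", "N:Si", "N:Fe",
             "s:all", "r:lowLET", "r:Si", "r:Fe"))
}

# a small two-arm design for fast fitting tests
small_design <- function(n_per_group = 40L) {
  design <- apc_study_design()[c("control", "gamma", "Fe")]
  design$control$groups$n_mice <- n_per_group
  design$gamma$groups <- data.frame(dose_gy = c(0.05, 0.5, 2.0),
                                    n_mice = n_per_group)
  design$Fe$groups <- data.frame(dose_gy = c(0.05, 0.4, 1.6),
                                 n_mice = n_per_group)
  class(design) <- "experiment_design"
  design
}

small_scheme <- function() {
  sharing_scheme(c("gamma", "Fe"), T = "by_type", N = "by_type",
                 s = "common", r = "by_type")
}

# brute-force WNB moments by direct summation of the pmf (independent of the
# closed forms under test)
wnb_sum_moments <- function(M, r, q, kmax = 4000L) {
  k <- 0:kmax
  p <- dwnb(k, M, r, q)
  stopifnot(sum(p) > 1 - 1e-10)
  mu <- sum(k * p)
  list(total = sum(p), mean = mu, var = sum(k^2 * p) - mu^2)
}
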