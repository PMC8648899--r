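#' Monte Carlo cloud for a generic likelihood
#'
#' Core rejection sampler behind [sample_cloud()]: proposes random parameter
#' vectors around a maximum-likelihood optimum and retains those whose log
#' likelihood lies within \code{delta_ll} of the maximum, i.e. inside the
#' corresponding likelihood-ratio confidence region.  Proposals are
#' independent per-parameter Gaussian steps on the optimizer scale (log
#' scale for positive parameters, hence multiplicative log-normal
#' perturbations of the natural parameters) taken from the last retained
#' vector, so the walk traverses the whole region including correlated
#' ridges; the step size is adapted in batches to keep the acceptance rate
#' between roughly 10% and 40%.
#'
#' @param loglik function mapping a parameter vector to a scalar log
#'   likelihood.
#' @param start parameter vector at (or near) the optimum.
#' @param n_min minimum number of retained vectors.
#' @param delta_ll likelihood drop defining the region; the default 1.92 is
#'   half the 95% chi-squared quantile with one degree of freedom (the
#'   profile-likelihood convention).  Use
#'   \code{qchisq(0.95, df = length(start))/2} for a joint region.
#' @param seed integer seed.
#' @param lower,upper box constraints for proposals.
#' @param scale initial proposal standard deviation.
#' @param prop_chol optional matrix mapping a standard-normal vector to a
#'   correlated step (e.g. a Cholesky-type factor of the inverse Hessian at
#'   the optimum); shapes proposals to the local geometry of the likelihood
#'   so the walk mixes along flat or correlated directions.
#' @param max_batches proposal budget: at most \code{max_batches} batches of
#'   \code{batch} proposals before giving up.
#' @param batch proposals per adaptation batch.
#' @return List with matrix \code{par} (retained vectors, the start vector
#'   first), \code{ll}, \code{ll_max}, \code{delta_ll}, \code{acceptance}.
#' @export
likelihood_cloud <- function(loglik, start, n_min = 1000L, delta_ll = 1.92,
                             seed = 1L, lower = -Inf, upper = Inf,
                             scale = 0.05, max_batches = 2000L, batch = 200L,
                             prop_chol = NULL, walk_inflate = 1) {
  stopifnot(n_min >= 1L, delta_ll >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- length(start)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  ll_max <- loglik(start)
  if (!is.finite(ll_max)) stop("log likelihood not finite at the start vector")
  keep_par <- list(start)
  keep_ll <- ll_max
  n_prop <- 0L; n_acc <- 0L
  # random walk over the acceptance region: proposals step from the last
  # retained vector, which lets the sampler follow correlated likelihood
  # ridges that a star pattern centred on the optimum would miss
  # The walk moves within an inflated region (walk_inflate * delta_ll) so it
  # can mix across curved, banana-shaped level sets, but only vectors inside
  # the delta_ll region are retained as cloud members.
  current <- start
  walk_delta <- walk_inflate * delta_ll
  step <- if (is.null(prop_chol)) function() rnorm(p, 0, scale)
          else function() scale * as.numeric(prop_chol %*% rnorm(p))
  do_batch <- function(nb) {
    acc_b <- 0L
    for (i in seq_len(nb)) {
      prop <- pmin(pmax(current + step(), lower), upper)
      ll <- loglik(prop)
      if (is.finite(ll) && ll >= ll_max - walk_delta) {
        if (ll > ll_max) ll_max <<- ll    # found a better optimum; tighten
        current <<- prop
        acc_b <- acc_b + 1L
        if (ll >= ll_max - delta_ll) {
          keep_par[[length(keep_par) + 1L]] <<- prop
          keep_ll <<- c(keep_ll, ll)
        }
      }
    }
    n_prop <<- n_prop + nb; n_acc <<- n_acc + acc_b
    acc_b / nb
  }
  # tune the proposal scale into the 10-40% acceptance band first, so that
  # the retained set explores the whole region rather than a neighbourhood
  # of the optimum
  in_band <- 0L
  for (b in seq_len(100L)) {
    rate <- do_batch(50L)
    if (rate < 0.10) { scale <- scale * 0.7; in_band <- 0L }
    else if (rate > 0.40) { scale <- scale * 1.3; in_band <- 0L }
    else { in_band <- in_band + 1L; if (in_band >= 2L) break }
  }
  while (length(keep_par) - 1L < n_min && n_prop < max_batches * batch) {
    rate <- do_batch(batch)
    if (rate < 0.10) scale <- scale * 0.7
    else if (rate > 0.40) scale <- scale * 1.3
  }
  if (length(keep_par) - 1L < n_min)
    stop(sprintf(paste0("cloud sampling exhausted its proposal budget: ",
                        "%d accepted of %d proposed (acceptance %.2f%%, ",
                        "final scale %.3g)"),
                 length(keep_par) - 1L, n_prop,
                 100 * (length(keep_par) - 1L) / n_prop, scale))
  keep <- keep_ll >= ll_max - delta_ll   # re-filter if ll_max moved
  par <- do.call(rbind, keep_par)[keep, , drop = FALSE]
  list(par = par, ll = keep_ll[keep], ll_max = ll_max, delta_ll = delta_ll,
       acceptance = n_acc / n_prop)
}

# Profile-likelihood boundary points: for each optimizer-scale coordinate,
# find the two values where the profile log likelihood (maximized over the
# remaining coordinates) has dropped by delta_ll, and return the full
# inner-optimized vectors there.  These are exact extreme members of the
# likelihood region along each coordinate, so cloud min/max intervals match
# profile intervals instead of under-reaching them.
.profile_boundary_points <- function(obj, lay, theta_hat, delta_ll,
                                     inner_maxit = 100L) {
  p <- length(theta_hat)
  ll_max <- obj$loglik(theta_hat)
  members <- list()
  for (i in seq_len(p)) {
    rest0 <- theta_hat[-i]
    prof <- function(v, rest_start) {
      nl <- function(tr) {
        th <- theta_hat; th[i] <- v; th[-i] <- tr
        obj$negll(th)
      }
      ng <- function(tr) {
        th <- theta_hat; th[i] <- v; th[-i] <- tr
        obj$neggr(th)[-i]
      }
      o <- tryCatch(
        optim(rest_start, nl, gr = ng, method = "L-BFGS-B",
              lower = lay$lower[-i], upper = lay$upper[-i],
              control = list(maxit = inner_maxit, factr = 1e10)),
        error = function(e) NULL)
      if (is.null(o)) return(NULL)
      list(ll = -o$value, rest = o$par)
    }
    for (dir in c(-1, 1)) {
      bound <- if (dir < 0) lay$lower[i] else lay$upper[i]
      rest <- rest0
      v_in <- theta_hat[i]; v_out <- NA_real_
      h <- 0.25
      repeat {
        v <- theta_hat[i] + dir * h
        if ((dir < 0 && v <= bound) || (dir > 0 && v >= bound)) v <- bound
        pr <- prof(v, rest)
        if (is.null(pr)) break
        rest <- pr$rest
        if (ll_max - pr$ll < delta_ll) {
          v_in <- v
          members[[length(members) + 1L]] <- {
            th <- theta_hat; th[i] <- v; th[-i] <- rest; th
          }
          if (v == bound) break      # region extends to the box bound
          h <- h * 2
        } else {
          v_out <- v
          break
        }
      }
      if (!is.na(v_out)) {
        # polish the crossing with a few bisection steps, keeping the
        # innermost vector that still satisfies the threshold
        for (k in 1:5) {
          v <- (v_in + v_out) / 2
          pr <- prof(v, rest)
          if (is.null(pr)) break
          rest <- pr$rest
          if (ll_max - pr$ll < delta_ll) {
            v_in <- v
            members[[length(members) + 1L]] <- {
              th <- theta_hat; th[i] <- v; th[-i] <- rest; th
            }
          } else v_out <- v
        }
      }
    }
  }
  members
}

#' Likelihood-region parameter cloud for a fitted model
#'
#' Generates random free-parameter combinations whose joint log likelihood
#' on \code{data} lies within \code{delta_ll} of the fitted maximum.  The
#' retained set approximates the 95% confidence region used for all
#' confidence envelopes: the minimum and maximum of any functional over the
#' cloud are its interval estimates.  Proposals are made on the fit's
#' internal (log / constrained) scale, so every member respects the
#' non-negativity and particle-T constraints by construction.
#'
#' @param data the fitted [tumor_data()] dataset.
#' @param scheme the [sharing_scheme()] used for the fit.
#' @param fit the [fit_wnb_model()] result.
#' @param n_min minimum cloud size.
#' @param seed integer seed.
#' @param delta_ll acceptance threshold; see [likelihood_cloud()].
#' @param scale initial proposal scale on the log-parameter axis.
#' @param profile logical; when \code{TRUE} (default) the cloud is augmented
#'   with the profile-likelihood boundary points of every free parameter
#'   (the exact extreme region members along each coordinate), so that
#'   per-parameter min/max intervals coincide with profile intervals rather
#'   than under-reaching them from a finite random sample.
#' @return An object of class \code{"parameter_cloud"}: matrix \code{free}
#'   of natural-scale free vectors (best fit in row 1), their \code{ll},
#'   \code{ll_max}, \code{delta_ll}, \code{acceptance}, the scheme and seed.
#' @export
sample_cloud <- function(data, scheme, fit, n_min = 1000L, seed = 1L,
                         delta_ll = 1.92, scale = 0.5, profile = TRUE) {
  stopifnot(inherits(fit, "wnb_fit"))
  lay <- .opt_layout(scheme, fit$t_constraint)
  theta_hat <- .free_to_theta(fit$free, lay)
  obj <- .theta_objective(data, scheme, lay, fit$mu_bac)
  # proposal shaping: inverse curvature of the log likelihood at the
  # optimum, from central differences of the analytic gradient
  p <- length(theta_hat)
  H <- matrix(0, p, p)
  h <- 1e-4
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    H[i, ] <- (obj$neggr(theta_hat + ei) - obj$neggr(theta_hat - ei)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  if (any(!is.finite(H))) H <- diag(p)   # fall back to unshaped steps
  ev <- eigen(H, symmetric = TRUE)
  # floor the spectrum: flat likelihood directions (e.g. a saturation rate
  # only informed below the lowest tested dose) get a wide but finite step
  lam <- pmax(ev$values, max(abs(ev$values)) * 1e-4)
  prop_chol <- ev$vectors %*% diag(1 / sqrt(lam), p)
  cl <- likelihood_cloud(obj$loglik, theta_hat, n_min = n_min,
                         delta_ll = delta_ll, seed = seed,
                         lower = lay$lower, upper = lay$upper, scale = scale,
                         prop_chol = prop_chol)
  if (profile) {
    extra <- .profile_boundary_points(obj, lay, theta_hat, delta_ll)
    keep <- vapply(extra, function(th) obj$loglik(th) >= cl$ll_max - delta_ll,
                   logical(1))
    if (any(keep)) {
      cl$par <- rbind(cl$par, do.call(rbind, extra[keep]))
      cl$ll <- c(cl$ll, vapply(extra[keep], obj$loglik, numeric(1)))
    }
  }
  free <- t(apply(cl$par, 1, .theta_to_free, lay = lay))
  colnames(free) <- lay$names
  out <- list(free = free, ll = cl$ll, ll_max = cl$ll_max,
              delta_ll = delta_ll, acceptance = cl$acceptance,
              scheme = scheme, mu_bac = fit$mu_bac, seed = seed)
  class(out) <- "parameter_cloud"
  out
}

#' @export
print.parameter_cloud <- function(x, ...) {
  cat(sprintf(paste0("likelihood-region parameter cloud: %d members, ",
                     "delta LL = %.3g, acceptance %.1f%%\n"),
              nrow(x$free), x$delta_ll, 100 * x$acceptance))
  invisible(x)
}

#' Confidence envelope of a dose-dependent functional
#'
#' Evaluates a scalar functional (excess yield, RBE, RER, an IEA prediction,
#' a single parameter, ...) of the per-type model parameters for every cloud
#' member at every grid dose and returns the per-dose minimum and maximum
#' --- the Monte Carlo 95% confidence envelope.  Members for which the
#' functional fails are skipped and counted.
#'
#' @param cloud a [sample_cloud()] result.
#' @param functional \code{function(params, dose)} where \code{params} is
#'   the named per-type list produced by [params_from_free()].
#' @param grid dose grid in Gy (default [dose_grid()]).
#' @return Data frame with columns \code{dose_gy}, \code{lo}, \code{hi} and
#'   attribute \code{"n_failed"}.
#' @examples
#' \donttest{
#' env <- ci_envelope(cloud, function(p, d) excess_yield(p$Fe, d))
#' }
#' @export
ci_envelope <- function(cloud, functional, grid = dose_grid()) {
  stopifnot(inherits(cloud, "parameter_cloud"))
  n <- nrow(cloud$free)
  stopifnot(n >= 1L)
  vals <- matrix(NA_real_, n, length(grid))
  for (j in seq_len(n)) {
    vals[j, ] <- tryCatch({
      pars <- params_from_free(cloud$scheme, cloud$free[j, ],
                               mu_bac = cloud$mu_bac)
      vapply(grid, function(d) functional(pars, d), numeric(1))
    }, error = function(e) rep(NA_real_, length(grid)))
  }
  ok <- stats::complete.cases(vals)
  if (!any(ok)) stop("functional failed for every cloud member")
  out <- data.frame(dose_gy = grid,
                    lo = apply(vals[ok, , drop = FALSE], 2, min),
                    hi = apply(vals[ok, , drop = FALSE], 2, max))
  attr(out, "n_failed") <- sum(!ok)
  out
}
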