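#' Parameter-sharing scheme across radiation types
#'
#' Defines, for each of the free parameters \code{T}, \code{N}, \code{s} and
#' \code{r}, a partition of the radiation types into groups sharing one
#' value.  Each component may be \code{"common"} (one group for all types),
#' \code{"by_type"} (one group per type), or a named character vector mapping
#' every type to a group label.
#'
#' @param types character vector of radiation type names (excluding the
#'   control arm, which follows the reference type).
#' @param T,N,s,r group specifications as described above.
#' @param reference_type the type whose derived \code{B} the control animals
#'   use, and whose \code{T} group anchors the particle-T inequality
#'   constraint.
#' @return An object of class \code{"sharing_scheme"}.
#' @seealso [default_scheme()] for the selected scheme of the mouse study.
#' @export
sharing_scheme <- function(types, T = "by_type", N = "by_type",
                           s = "common", r = "by_type",
                           reference_type = "gamma") {
  norm <- function(x) {
    if (length(x) == 1L && x == "common") return(setNames(rep("all", length(types)), types))
    if (length(x) == 1L && x == "by_type") return(setNames(types, types))
    if (!all(types %in% names(x))) stop("every type needs a group label")
    x[types]
  }
  if (!reference_type %in% types) reference_type <- types[1]
  out <- list(types = types,
              groups = list(T = norm(T), N = norm(N), s = norm(s), r = norm(r)),
              reference_type = reference_type)
  class(out) <- "sharing_scheme"
  out
}

#' The selected sharing scheme of the mouse study
#'
#' \code{s} common to all radiation types; \code{T} and \code{r} common to
#' gamma, H, He, C and O ("lowLET" group) and separate for Si and Fe;
#' \code{N} separate for every type.  14 free parameters.
#'
#' @param types radiation type names; the default is the full study.
#' @return A [sharing_scheme()].
#' @export
default_scheme <- function(types = c("gamma", "H", "He", "C", "O", "Si", "Fe")) {
  low <- intersect(types, c("gamma", "H", "He", "C", "O"))
  grp <- setNames(ifelse(types %in% low, "lowLET", types), types)
  sharing_scheme(types, T = grp, N = "by_type", s = "common", r = grp)
}

# Free-parameter layout: one entry per (parameter, group), in the fixed order
# T, N, s, r with groups in order of first appearance among scheme$types.
scheme_layout <- function(scheme) {
  unlist(lapply(c("T", "N", "s", "r"), function(p) {
    paste(p, unique(unname(scheme$groups[[p]])), sep = ":")
  }))
}

#' Expand a free-parameter vector into per-type model parameters
#'
#' Maps a named free vector (layout \code{"T:group"}, \code{"N:group"},
#' \code{"s:group"}, \code{"r:group"}; see \code{scheme_layout}) to one
#' [model_params()] per radiation type, with \code{B} and \code{q} derived
#' from each type's group \code{r} through the background constraints.
#'
#' @param scheme a [sharing_scheme()].
#' @param free named numeric vector of free parameter values (>= 0).
#' @param mu_bac background mean for the B/q derivation.
#' @return Named list of [model_params()], one per type in the scheme.
#' @export
params_from_free <- function(scheme, free, mu_bac = 3.279) {
  layout <- scheme_layout(scheme)
  if (is.null(names(free))) names(free) <- layout
  stopifnot(setequal(names(free), layout))
  pick <- function(p, type) free[[paste(p, scheme$groups[[p]][[type]], sep = ":")]]
  out <- lapply(scheme$types, function(ty)
    model_params(T = pick("T", ty), N = pick("N", ty),
                 s = pick("s", ty), r = pick("r", ty), mu_bac = mu_bac))
  setNames(out, scheme$types)
}

# unchecked vectorized WNB log pmf (argument validation is the caller's job);
# same math as dwnb()
.dwnb_log <- function(k, M, r, q) {
  lw <- log1p(k * q / M) - log1p(q)
  lp <- numeric(length(k))
  pois <- r < 1e-8
  if (any(pois)) {
    i <- pois
    lp[i] <- dpois(k[i], M[i], log = TRUE) + lw[i]
  }
  if (!all(pois)) {
    i <- !pois
    kk <- k[i]; m <- M[i]; rr <- r[i]
    lp[i] <- lgamma(kk + 1 / rr) - lgamma(kk + 1) - lgamma(1 / rr) +
      kk * (log(rr) + log(m) - log1p(rr * m)) - log1p(rr * m) / rr + lw[i]
  }
  lp
}

# Precomputed likelihood closure: maps each mouse to the free-vector slots of
# its type's T, N, s, r groups once, so each evaluation is a handful of
# vectorized operations over the whole dataset.  Control animals follow the
# reference type with M = B.
.ll_context <- function(data, scheme, mu_bac = 3.279) {
  layout <- scheme_layout(scheme)
  is_ctrl <- data$radiation == "control"
  eff_type <- ifelse(is_ctrl, scheme$reference_type, data$radiation)
  unknown <- setdiff(unique(eff_type), scheme$types)
  if (length(unknown))
    stop("dataset contains unknown radiation type(s): ",
         paste(unknown, collapse = ", "))
  idx <- lapply(setNames(nm = c("T", "N", "s", "r")), function(p)
    match(paste(p, scheme$groups[[p]][eff_type], sep = ":"), layout))
  dose <- data$dose_gy
  k <- data$tumors
  function(free) {
    if (any(!is.finite(free)) || any(free < 0)) return(-Inf)
    rv <- free[idx$r]
    qv <- q_approx(rv)
    Bv <- ((mu_bac - 1) * qv + mu_bac) / (1 + qv * (1 + rv))
    if (any(Bv < 0)) return(-Inf)
    M <- Bv + ifelse(is_ctrl, 0,
                     free[idx$N] * (1 - exp(-free[idx$s] * dose)) +
                       free[idx$T] * dose)
    if (any(M <= 0)) return(-Inf)
    ll <- sum(.dwnb_log(k, M, rv, qv))
    if (is.finite(ll)) ll else -Inf
  }
}

# Analytic gradient of the joint log likelihood with respect to the natural
# free vector.  Per-mouse partials of the WNB log pmf in (M, r, q) are chained
# through M(D; T, N, s) and through the background derivations q(r), B(r).
# Only the r >= 1e-8 branch is differentiated; the optimizer keeps r >= 1e-6.
.ll_grad_context <- function(data, scheme, mu_bac = 3.279) {
  layout <- scheme_layout(scheme)
  is_ctrl <- data$radiation == "control"
  eff_type <- ifelse(is_ctrl, scheme$reference_type, data$radiation)
  idx <- lapply(setNames(nm = c("T", "N", "s", "r")), function(p)
    match(paste(p, scheme$groups[[p]][eff_type], sep = ":"), layout))
  dose <- data$dose_gy
  k <- data$tumors
  accum <- function(g, i, val) {
    s <- rowsum(val, i)
    j <- as.integer(rownames(s))
    g[j] <- g[j] + s[, 1]
    g
  }
  function(free) {
    rv <- free[idx$r]; qv <- q_approx(rv)
    N1 <- (mu_bac - 1) * qv + mu_bac
    D1 <- 1 + qv * (1 + rv)
    Bv <- N1 / D1
    E <- exp(-free[idx$s] * dose)
    M <- Bv + ifelse(is_ctrl, 0,
                     free[idx$N] * (1 - E) + free[idx$T] * dose)
    one_rM <- 1 + rv * M
    # partials of the log pmf in its three arguments
    dM <- k / M - k * rv / one_rM - 1 / one_rM - k * qv / (M * (M + k * qv))
    dq <- k / (M + k * qv) - 1 / (1 + qv)
    dr <- (digamma(1 / rv) - digamma(k + 1 / rv)) / rv^2 + k / rv -
      k * M / one_rM - M / (rv * one_rM) + log1p(rv * M) / rv^2
    # chain through the background constraints: q(r) and B(q(r), r)
    h <- 1.33 + 26.85 * rv - 20.95 * rv^2 + 1843.14 * rv^3
    # exp(h - exp(h)/500) underflows cleanly to 0 where exp(h) overflows
    dqdr <- exp(h - exp(h) / 500) * (26.85 - 2 * 20.95 * rv + 3 * 1843.14 * rv^2)
    dBdq <- ((mu_bac - 1) * D1 - N1 * (1 + rv)) / D1^2
    dBdr <- -N1 * qv / D1^2
    g_r <- dr + dq * dqdr + dM * (dBdq * dqdr + dBdr)
    nc <- !is_ctrl
    g <- numeric(length(layout))
    g <- accum(g, idx$r, g_r)
    g <- accum(g, idx$T[nc], (dM * dose)[nc])
    g <- accum(g, idx$N[nc], (dM * (1 - E))[nc])
    g <- accum(g, idx$s[nc], (dM * free[idx$N] * dose * E)[nc])
    names(g) <- layout
    g
  }
}

#' Joint log likelihood of a tumour dataset
#'
#' Sum over animals of the WNB log pmf at \code{M = mean_response(params,
#' dose)}, with per-type parameters expanded from the free vector via
#' [params_from_free()].  Control animals (\code{radiation == "control"})
#' contribute through \code{M = B} of the reference type.  Parameter
#' combinations yielding a non-finite log pmf return \code{-Inf}.
#'
#' @inheritParams params_from_free
#' @param data a [tumor_data()] data frame.
#' @return Scalar log likelihood (possibly \code{-Inf}).
#' @export
wnb_log_likelihood <- function(data, scheme, free, mu_bac = 3.279) {
  layout <- scheme_layout(scheme)
  if (is.null(names(free))) names(free) <- layout
  stopifnot(setequal(names(free), layout))
  .ll_context(data, scheme, mu_bac)(unname(free[layout]))
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2LL + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param LL maximized log likelihood.
#' @param k_params number of free parameters.
#' @param n_obs number of observations; must exceed \code{k_params + 1}.
#' @return Scalar AICc.
#' @export
aicc <- function(LL, k_params, n_obs) {
  if (n_obs <= k_params + 1) stop("n_obs must exceed k_params + 1")
  -2 * LL + 2 * k_params + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

# --- internal optimizer plumbing -------------------------------------------
#
# The optimizer works on log-scale parameters.  With t_constraint = "joint"
# the T value of every non-reference group is stored as log(delta) with
# T_group = T_ref + delta, which enforces T_particle >= T_gamma smoothly in
# a single joint fit.  "two_stage" first fits the reference type alone and
# freezes the bound; "none" drops the inequality.

.opt_layout <- function(scheme, t_constraint) {
  layout <- scheme_layout(scheme)
  ref_grp <- scheme$groups$T[[scheme$reference_type]]
  is_T <- startsWith(layout, "T:")
  delta <- is_T & layout != paste0("T:", ref_grp) & t_constraint == "joint"
  is_r <- startsWith(layout, "r:")
  lower <- ifelse(is_r, log(1e-6), ifelse(delta, log(1e-12), log(1e-8)))
  upper <- ifelse(is_r, log(10), log(1e4))
  list(names = layout, delta = delta, ref_T = paste0("T:", ref_grp),
       lower = lower, upper = upper)
}

.theta_to_free <- function(theta, lay) {
  v <- exp(theta)
  names(v) <- lay$names
  if (any(lay$delta)) v[lay$delta] <- v[lay$delta] + v[[lay$ref_T]]
  v
}

.free_to_theta <- function(free, lay) {
  v <- free[lay$names]
  if (any(lay$delta))
    v[lay$delta] <- pmax(v[lay$delta] - v[[lay$ref_T]], 1e-12)
  pmin(pmax(log(v), lay$lower), lay$upper)
}

.random_theta <- function(lay) {
  is_r <- startsWith(lay$names, "r:")
  # log-uniform inits: [1e-3, 1e2] for T, N, s (and T-deltas); [1e-3, 1] for r
  lo <- ifelse(is_r, log(1e-3), log(1e-3))
  hi <- ifelse(is_r, log(1), log(1e2))
  runif(length(lay$names), lo, hi)
}

# objective and analytic gradient on the optimizer (log/delta) scale
.theta_objective <- function(data, scheme, lay, mu_bac = 3.279) {
  llfun <- .ll_context(data, scheme, mu_bac)
  grfun <- .ll_grad_context(data, scheme, mu_bac)
  list(
    llfun = llfun,
    loglik = function(theta) llfun(.theta_to_free(theta, lay)),
    negll = function(theta) {
      ll <- llfun(.theta_to_free(theta, lay))
      if (!is.finite(ll)) 1e12 else -ll
    },
    neggr = function(theta) {
      g <- grfun(.theta_to_free(theta, lay))
      if (any(!is.finite(g))) return(numeric(length(theta)))
      if (any(lay$delta)) g[lay$ref_T] <- g[lay$ref_T] + sum(g[lay$delta])
      unname(-g * exp(theta))
    })
}

#' Constrained maximum-likelihood fit of the TE+NTE/WNB model
#'
#' Jointly fits all radiation types in \code{data} under a sharing scheme by
#' multi-start constrained maximization of [wnb_log_likelihood()].
#' Constraints: all parameters non-negative (log-scale optimization with
#' \code{r >= 1e-6}), and --- unless \code{t_constraint = "none"} --- the
#' \code{T} of every particle group at least as large as the reference
#' (gamma) group's \code{T}.  With \code{t_constraint = "joint"} the
#' inequality is enforced within one simultaneous fit by reparameterising
#' particle \code{T} as \code{T_gamma + delta}; with \code{"two_stage"} the
#' reference type is fitted alone first and its \code{T} frozen as the bound.
#'
#' @inheritParams wnb_log_likelihood
#' @param n_starts number of random initializations (log-uniform over
#'   documented ranges); the best converged attempt is returned.
#' @param seed integer seed making the whole multi-start run reproducible.
#' @param t_constraint \code{"joint"}, \code{"two_stage"} or \code{"none"}.
#' @param reltol convergence tolerance on the log likelihood.
#' @return An object of class \code{"wnb_fit"}: per-type \code{params}, the
#'   free vector \code{free}, \code{logLik}, \code{n_free}, \code{n_obs},
#'   \code{AICc}, convergence metadata and the scheme.
#' @examples
#' \donttest{
#' dat <- simulate_study(seed = 7)
#' fit <- fit_wnb_model(dat, default_scheme(), n_starts = 10, seed = 1)
#' fit$params$Si$T
#' }
#' @export
fit_wnb_model <- function(data, scheme, n_starts = 2000L, seed = 1L,
                          t_constraint = c("joint", "two_stage", "none"),
                          mu_bac = 3.279, reltol = 1e-10) {
  t_constraint <- match.arg(t_constraint)
  stopifnot(n_starts >= 1L)
  types_in_data <- setdiff(unique(data$radiation), "control")
  missing <- setdiff(types_in_data, scheme$types)
  if (length(missing))
    stop("scheme lacks radiation type(s): ", paste(missing, collapse = ", "))

  if (t_constraint == "two_stage") {
    ref <- scheme$reference_type
    sub <- data[data$radiation %in% c(ref, "control"), , drop = FALSE]
    ref_scheme <- sharing_scheme(ref, T = "common", N = "common",
                                 s = "common", r = "common",
                                 reference_type = ref)
    ref_fit <- fit_wnb_model(sub, ref_scheme, n_starts = max(10L, n_starts %/% 4L),
                             seed = seed + 1L, t_constraint = "none",
                             mu_bac = mu_bac, reltol = reltol)
    t_floor <- ref_fit$params[[ref]]$T
  } else t_floor <- NULL

  lay <- .opt_layout(scheme, t_constraint)
  if (!is.null(t_floor)) {
    # freeze the bound: particle-group T lower-bounded by the gamma-only fit
    is_T <- startsWith(lay$names, "T:") & lay$names != lay$ref_T
    lay$lower[is_T] <- log(max(t_floor, 1e-8))
  }

  obj <- .theta_objective(data, scheme, lay, mu_bac)
  negll <- obj$negll
  run <- function(theta0, maxit, factr) tryCatch(
    optim(theta0, negll, gr = obj$neggr, method = "L-BFGS-B",
          lower = lay$lower, upper = lay$upper,
          control = list(maxit = maxit, factr = factr)),
    error = function(e) NULL)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # screen all starts cheaply, then polish the leaders to full tolerance
  screened <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    theta0 <- pmin(pmax(.random_theta(lay), lay$lower), lay$upper)
    screened[[i]] <- run(theta0, maxit = 150L, factr = 1e10)
  }
  vals <- vapply(screened, function(x)
    if (is.null(x) || !is.finite(x$value)) Inf else x$value, numeric(1))
  n_conv <- sum(vals < 1e12)
  if (n_conv == 0L)
    stop("all ", n_starts, " starts failed to converge; check the data and scheme")
  best <- NULL
  for (i in head(order(vals), 3L)) {
    if (!is.finite(vals[i]) || vals[i] >= 1e12) next
    res <- run(screened[[i]]$par, maxit = 1000L,
               factr = reltol / .Machine$double.eps)
    if (is.null(res)) res <- screened[[i]]
    if (is.null(best) || res$value < best$value) best <- res
  }

  free <- .theta_to_free(best$par, lay)
  out <- list(params = params_from_free(scheme, free, mu_bac = mu_bac),
              free = free,
              logLik = -best$value,
              n_free = length(free),
              n_obs = nrow(data),
              AICc = aicc(-best$value, length(free), nrow(data)),
              scheme = scheme,
              t_constraint = t_constraint,
              t_floor = t_floor,
              mu_bac = mu_bac,
              n_starts = n_starts,
              n_converged = n_conv,
              seed = seed,
              convergence = best$convergence)
  class(out) <- "wnb_fit"
  out
}

#' @export
print.wnb_fit <- function(x, ...) {
  cat(sprintf("TE+NTE/WNB fit: LL = %.4f, %d free parameters, %d mice, AICc = %.2f\n",
              x$logLik, x$n_free, x$n_obs, x$AICc))
  cat(sprintf("multi-start: %d/%d converged (seed %d); T constraint: %s\n",
              x$n_converged, x$n_starts, x$seed, x$t_constraint))
  print(fit_report(x))
  invisible(x)
}

#' Parameter table for a fit
#'
#' One row per radiation type with the fitted \code{T}, \code{N}, \code{r},
#' the shared \code{s}, and the derived \code{B} and \code{q}; optionally
#' written as a delimited text file.
#'
#' @param fit a [fit_wnb_model()] result.
#' @param cloud optional [sample_cloud()] result; when supplied, per-type
#'   95% CI columns (min/max over the cloud) are added.
#' @param path optional output file.
#' @return A data frame (invisibly when written to \code{path}).
#' @export
fit_report <- function(fit, cloud = NULL, path = NULL) {
  stopifnot(inherits(fit, "wnb_fit"))
  tab <- do.call(rbind, lapply(names(fit$params), function(ty) {
    p <- fit$params[[ty]]
    data.frame(radiation = ty, T = p$T, N = p$N, s = p$s, r = p$r,
               B = p$B, q = p$q)
  }))
  if (!is.null(cloud)) {
    for (par in c("T", "N", "r")) {
      lo <- hi <- numeric(nrow(tab))
      for (i in seq_len(nrow(tab))) {
        vals <- vapply(seq_len(nrow(cloud$free)), function(j)
          fit_param_of(fit$scheme, cloud$free[j, ], par, tab$radiation[i]),
          numeric(1))
        lo[i] <- min(vals); hi[i] <- max(vals)
      }
      tab[[paste0(par, "_lo")]] <- lo
      tab[[paste0(par, "_hi")]] <- hi
    }
  }
  if (!is.null(path)) {
    write.table(format(tab, digits = 6), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

# value of one named parameter for one radiation type, from a free vector
fit_param_of <- function(scheme, free, par, type) {
  free[[paste(par, scheme$groups[[par]][[type]], sep = ":")]]
}

#' Fit several sharing schemes and rank them by AICc
#'
#' @inheritParams fit_wnb_model
#' @param schemes named list of [sharing_scheme()] objects.
#' @return Data frame (scheme, n_free, logLik, AICc) sorted by ascending
#'   AICc, with the fits attached as attribute \code{"fits"}.
#' @export
compare_schemes <- function(data, schemes, n_starts = 50L, seed = 1L, ...) {
  stopifnot(length(schemes) >= 2L)
  if (is.null(names(schemes)))
    names(schemes) <- paste0("scheme", seq_along(schemes))
  fits <- lapply(seq_along(schemes), function(i)
    fit_wnb_model(data, schemes[[i]], n_starts = n_starts, seed = seed + i, ...))
  tab <- data.frame(scheme = names(schemes),
                    n_free = vapply(fits, `[[`, numeric(1), "n_free"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    AICc = vapply(fits, `[[`, numeric(1), "AICc"))
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- setNames(fits, names(schemes))[ord]
  tab
}
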