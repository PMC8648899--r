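#' The weighted negative binomial (WNB) count distribution
#'
#' Probability mass function, moments and random generation for the weighted
#' negative binomial distribution of tumour counts per animal.  The WNB is a
#' standard negative binomial with mean \code{M} and dispersion \code{r},
#' reweighted by the factor \eqn{(M + kq)/(M(1+q))}:
#' \deqn{P(k) = \frac{(1+rM)^{-Y} r^k M^{k-1} \Gamma(Y)\,(M + kq)}
#'                   {\Gamma(1+k)\,\Gamma(1/r)\,(1+q)}, \quad Y = k + 1/r.}
#' The weight makes small counts less likely relative to the plain negative
#' binomial, so the distribution is underdispersed (\eqn{V/\mu = 1/(1+q)}) at
#' small \code{M} and overdispersed at large \code{M} when \code{r > 0}.
#'
#' The mean has the closed form \eqn{\mu = [M + q(1 + M(1+r))]/(1+q)}
#' (\code{wnb_mean}); the variance is \eqn{\mu} times the ratio returned by
#' [variance_to_mean()] (\code{wnb_variance}).
#'
#' All computation is in log space via \code{lgamma}; the \eqn{M^{k-1}} factor
#' at \code{k = 0} is cancelled against \eqn{(M + kq)} analytically, so small
#' \code{M} is safe.  At \code{r = 0} (more precisely \code{r < 1e-8}, where
#' the large-\code{1/r} gamma differences lose precision) the analytic Poisson
#' limit is used: a Poisson pmf carrying the same weight factor.
#'
#' @param x vector of non-negative integer counts.
#' @param M latent mean intensity (> 0).
#' @param r overdispersion parameter (>= 0).
#' @param q underdispersion weight parameter (>= 0).
#' @param log logical; return log probabilities?
#' @param n number of draws.
#' @param seed optional integer; when supplied the RNG is seeded locally so
#'   the same seed always yields the same sample.
#' @return \code{dwnb}: (log) probabilities; \code{wnb_mean},
#'   \code{wnb_variance}: numeric scalars; \code{rwnb}: integer vector of
#'   length \code{n}.
#' @examples
#' dwnb(0:5, M = 1, r = 1, q = 0)        # geometric special case
#' wnb_mean(2.5, 0.2, 0.8)
#' rwnb(5, M = 3, r = 0.1, q = 2, seed = 1)
#' @name wnb
NULL

.check_wnb <- function(M, r, q) {
  if (any(!is.finite(M)) || any(M <= 0)) stop("M must be positive and finite")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be non-negative")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be non-negative")
}

#' @rdname wnb
#' @export
dwnb <- function(x, M, r, q, log = FALSE) {
  .check_wnb(M, r, q)
  if (any(x < 0) || any(x != floor(x))) stop("x must be non-negative integers")
  n <- max(length(x), length(M), length(r), length(q))
  x <- rep_len(x, n); M <- rep_len(M, n)
  r <- rep_len(r, n); q <- rep_len(q, n)
  lw <- log1p(x * q / M) - log1p(q)     # weight (M + kq)/(M(1+q)), k=0 safe
  lp <- numeric(n)
  pois <- r < 1e-8
  if (any(pois)) {
    i <- pois
    lp[i] <- dpois(x[i], M[i], log = TRUE) + lw[i]
  }
  if (any(!pois)) {
    i <- !pois
    k <- x[i]; m <- M[i]; rr <- r[i]
    lp[i] <- lgamma(k + 1 / rr) - lgamma(k + 1) - lgamma(1 / rr) +
      k * (log(rr) + log(m) - log1p(rr * m)) - log1p(rr * m) / rr + lw[i]
  }
  if (log) lp else exp(lp)
}

#' @rdname wnb
#' @export
wnb_mean <- function(M, r, q) {
  .check_wnb(M, r, q)
  (M + q * (1 + M * (1 + r))) / (1 + q)
}

#' @rdname wnb
#' @export
wnb_variance <- function(M, r, q) {
  .check_wnb(M, r, q)
  wnb_mean(M, r, q) *
    (1 + r * M) * (q + M * (1 + q^2 * (1 + r) + 2 * q * (1 + r))) /
    ((1 + q) * (q + M * (1 + q * (1 + r))))
}

# pmf table up to the point where the cumulative mass exceeds 1 - tail_tol;
# support is grown geometrically with a hard cap.
.wnb_pmf_table <- function(M, r, q, tail_tol = 1e-12, k_cap = 1e6) {
  upper <- max(32, ceiling(4 * wnb_mean(M, r, q)))
  repeat {
    p <- dwnb(0:upper, M, r, q)
    if (sum(p) > 1 - tail_tol || upper >= k_cap) break
    upper <- min(k_cap, upper * 2L)
  }
  p
}

#' @rdname wnb
#' @export
rwnb <- function(n, M, r, q, seed = NULL) {
  stopifnot(n >= 1)
  .check_wnb(M, r, q)
  stopifnot(length(M) == 1L, length(r) == 1L, length(q) == 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cdf <- cumsum(.wnb_pmf_table(M, r, q))
  findInterval(runif(n), cdf)   # inverse-CDF draw; support 0..length(cdf)
}
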