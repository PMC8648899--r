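#' Principal branch of the Lambert W function
#'
#' Solves \eqn{w e^w = x} for \eqn{w \ge -1} (the principal branch W0),
#' defined for \eqn{x \ge -1/e}.  Uses an asymptotic or series initial guess
#' followed by Halley iteration; convergence is quadratic-plus and capped at
#' 80 iterations.  Only the non-negative-argument regime arises in this
#' model family (the W argument of the inverse dose response is a product of
#' non-negative quantities), but the full principal domain is supported.
#'
#' @param x numeric vector, each element >= -1/e.
#' @param tol absolute tolerance on \eqn{w e^w - x} scaled by \code{1 + |x|}.
#' @return Numeric vector of W0 values.
#' @examples
#' lambert_w0(1)           # the omega constant, ~0.567143
#' lambert_w0(exp(1))      # exactly 1
#' @export
lambert_w0 <- function(x, tol = 1e-13) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) {
      if (is.nan(xi)) return(NaN)
      if (xi == Inf) return(Inf)
      stop("x must be finite or +Inf")
    }
    if (xi < -exp(-1) - 1e-15) stop("x below -1/e: outside the principal branch")
    if (xi < -exp(-1)) xi <- -exp(-1)
    if (xi == 0) return(0)
    w <- if (xi > exp(1)) {            # asymptotic: log x - log log x + ...
      l1 <- log(xi); l2 <- log(l1)
      l1 - l2 + l2 / l1
    } else if (xi > -0.25) {
      xi * (1 - xi)                    # near-zero series start
    } else {
      # near the branch point -1/e: w ~ -1 + sqrt(2(e x + 1))
      -1 + sqrt(max(2 * (exp(1) * xi + 1), 0))
    }
    for (i in 1:80) {
      ew <- exp(w)
      f <- w * ew - xi
      if (abs(f) <= tol * (1 + abs(xi))) break
      # Halley step
      wp1 <- w + 1
      w <- w - f / (ew * wp1 - (w + 2) * f / (2 * wp1))
    }
    w
  }, numeric(1))
}
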