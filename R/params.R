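#' Radiation type descriptor
#'
#' @param name short label, e.g. \code{"Fe"}; must be unique within a study.
#' @param energy beam energy in MeV/nucleon (informational; the model depends
#'   only on dose and type).
#' @param let linear energy transfer in keV/um; must be positive.
#' @return An object of class \code{"radiation_type"}.
#' @examples
#' radiation_type("Fe", energy = 1000, let = 148)
#' @export
radiation_type <- function(name, energy = NA_real_, let) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(let), length(let) == 1L, is.finite(let), let > 0)
  structure(list(name = name, energy = as.numeric(energy), let = as.numeric(let)),
            class = "radiation_type")
}

#' Model parameter set for one radiation type
#'
#' Bundles the six parameters of the TE+NTE / WNB model.  In the fitted model
#' only \code{T}, \code{N}, \code{s} and \code{r} are free; \code{q} and
#' \code{B} are derived from \code{r} and the observed background mean via the
#' background-moment constraints ([q_approx()], [b_approx()]).  Supply
#' \code{B} and/or \code{q} explicitly to override the derivation.
#'
#' @param T TE slope, tumours per Gy (>= 0).
#' @param N NTE plateau, tumours (>= 0).
#' @param s NTE saturation rate, 1/Gy (>= 0).
#' @param r overdispersion parameter (>= 0).
#' @param B background mean parameter; derived from \code{r} when \code{NULL}.
#' @param q underdispersion weight; derived from \code{r} when \code{NULL}.
#' @param mu_bac observed background mean used for the derivation.
#' @return An object of class \code{"model_params"} (a named list).
#' @examples
#' p <- model_params(T = 2.77, N = 0.62, s = 38.66, r = 0.047)
#' p$B  # derived from r through the background constraints
#' @export
model_params <- function(T, N, s, r, B = NULL, q = NULL, mu_bac = 3.279) {
  vals <- c(T = T, N = N, s = s, r = r)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  if (is.null(q)) q <- q_approx(r)
  if (is.null(B)) B <- b_solution(mu_bac, q, r)
  stopifnot(is.finite(B), B >= 0, is.finite(q), q >= 0)
  structure(list(B = B, N = N, T = T, s = s, r = r, q = q),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("TE+NTE/WNB model parameters:\n")
  print(round(unlist(x), 5))
  invisible(x)
}

#' @export
print.radiation_type <- function(x, ...) {
  cat(sprintf("radiation type %s: %s MeV/n, LET %.3g keV/um\n",
              x$name, format(x$energy), x$let))
  invisible(x)
}
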