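#' Draws from the generalised inverse Gaussian distribution
#'
#' Samples from the density proportional to
#' `x^(lambda - 1) * exp(-(psi * x + chi / x) / 2)` on `x > 0`. This is the
#' full-conditional family of the company frailties: combining the
#' `Z^M exp(-D1 Z - D2 / Z)` likelihood kernel with the
#' `Gamma(1/xi, 1/xi)` prior gives `lambda = M + 1/xi`, `chi = 2 D2`,
#' `psi = 2 (D1 + 1/xi)`.
#'
#' When `chi = 0` the distribution degenerates to a gamma with shape
#' `lambda` (requiring `lambda > 0`) and rate `psi / 2`. Draws use R's
#' global random number stream, so results are reproducible under
#' [set.seed()]. The sampler is exact (rejection from a three-piece
#' log-concave envelope on the log scale).
#'
#' @param n Number of draws.
#' @param lambda Real order parameter (recycled).
#' @param chi Non-negative (recycled).
#' @param psi Positive (recycled).
#' @return Numeric vector of `n` positive draws.
#' @export
#' @examples
#' set.seed(1)
#' mean(rgig(1e4, lambda = -1/2, chi = 2, psi = 3))
#' # closed form: sqrt(chi/psi) * besselK(w, lambda+1) / besselK(w, lambda)
gig_mean <- function(lambda, chi, psi) {
  if (chi == 0) return(2 * lambda / psi)
  w <- sqrt(chi * psi)
  sqrt(chi / psi) * besselK(w, lambda + 1) / besselK(w, lambda)
}

#' @rdname gig_mean
#' @export
rgig <- function(n, lambda, chi, psi) {
  if (any(!is.finite(lambda)) || any(!is.finite(chi)) || any(!is.finite(psi))) {
    abort("non-finite GIG parameters")
  }
  if (any(psi <= 0)) abort("`psi` must be positive")
  if (any(chi < 0)) abort("`chi` must be non-negative")
  if (any(chi == 0 & rep_len(lambda, max(length(lambda), length(chi))) <= 0)) {
    abort("`chi` = 0 requires `lambda` > 0 (gamma limit)")
  }
  .rgig_cpp(as.integer(n), as.numeric(lambda), as.numeric(chi),
            as.numeric(psi))
}

#' @rdname gig_mean
#' @param x Positive evaluation points.
#' @param log Return the log-density.
#' @export
dgig <- function(x, lambda, chi, psi, log = FALSE) {
  if (chi == 0) {
    return(stats::dgamma(x, shape = lambda, rate = psi / 2, log = log))
  }
  w <- sqrt(chi * psi)
  lc <- (lambda / 2) * (log(psi) - log(chi)) -
    log(2) - log(besselK(w, lambda, expon.scaled = TRUE)) + w
  out <- lc + (lambda - 1) * log(x) - (psi * x + chi / x) / 2
  if (log) out else exp(out)
}
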