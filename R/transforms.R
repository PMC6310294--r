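#' Dempster-Lerner scale transformation for heritability
#'
#' Converts heritability of an all-or-none trait between the observed
#' (0/1) scale and the underlying normal liability scale. With incidence
#' `p` (the proportion of 1s) and `z = dnorm(qnorm(1 - p))` the height of
#' the standard normal density at the corresponding threshold,
#'
#' \deqn{h^2_{liab} = h^2_{obs} \cdot p(1-p)/z^2}
#'
#' and `liability_to_observed()` is the exact inverse. The transformation
#' is defined on a normal liability; applying it to a logit-model estimate
#' involves a (documented) link-shape approximation. At `p = 0.5` the
#' multiplier `p(1-p)/z^2` equals `pi/2`. Values are returned unclipped;
#' reporting code may clip to `[0, 1]` with a warning.
#'
#' @param h2_obs,h2_liab heritability on the observed / liability scale.
#' @param p incidence, strictly inside (0, 1). Vectorised.
#' @return Transformed heritability (numeric).
#' @examples
#' observed_to_liability(0.10, 0.5) # 0.10 * pi/2
#' @export
observed_to_liability <- function(h2_obs, p) {
  check_incidence(p)
  z <- stats::dnorm(stats::qnorm(1 - p))
  h2_obs * p * (1 - p) / z^2
}

#' @rdname observed_to_liability
#' @export
liability_to_observed <- function(h2_liab, p) {
  check_incidence(p)
  z <- stats::dnorm(stats::qnorm(1 - p))
  h2_liab * z^2 / (p * (1 - p))
}

check_incidence <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("incidence p must lie strictly inside (0, 1)")
  }
  invisible(p)
}
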