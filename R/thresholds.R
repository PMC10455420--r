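#' Net reproductive rates and bifurcation values
#'
#' Two dimensionless thresholds govern the fate of the borer:
#' \deqn{B_0 = \frac{\phi\omega}{\mu(\theta+\omega)}}
#' is the net reproductive rate of the borer in the absence of the
#' predator, and
#' \deqn{\Psi_0 = \frac{\phi\omega}{(k\alpha+\mu)(k\delta+\theta+\omega)}}
#' is the net reproductive rate with the ant population at its carrying
#' capacity. Whenever `k > 0` and at least one predation rate is positive,
#' `Psi0 < B0`. Solving each threshold `= 1` for the adult death rate `mu`
#' gives the two transcritical bifurcation values
#' \deqn{\mu^* = \frac{\phi\omega}{k\delta+\theta+\omega} - k\alpha, \qquad
#'       \mu^{**} = \frac{\phi\omega}{\theta+\omega},}
#' with `mu_star < mu_double_star` under the same condition. The borer is
#' eradicated with the predator present when `mu >= mu_star`, and even
#' without predation when `mu > mu_double_star`.
#'
#' `mu_star` can be negative when `k * alpha` exceeds
#' `phi*omega/(k*delta+theta+omega)`; it is reported verbatim, meaning
#' predation alone eradicates the pest for every `mu > 0`.
#'
#' @param params A [cbb_params] object (or a named list/one-row data frame
#'   with the ten parameters).
#' @return `cbb_thresholds()` returns a one-row tibble with columns
#'   `B0`, `Psi0`, `mu_star`, `mu_double_star`; the scalar helpers return
#'   bare numbers.
#' @examples
#' p <- cbb_baseline_params(mu = 0.03)
#' cbb_thresholds(p)
#' @export
cbb_thresholds <- function(params) {
  params <- as_cbb_params(params)
  tibble::tibble(
    B0 = cbb_B0(params),
    Psi0 = cbb_Psi0(params),
    mu_star = cbb_mu_star(params),
    mu_double_star = cbb_mu_double_star(params)
  )
}

#' @rdname cbb_thresholds
#' @export
cbb_B0 <- function(params) {
  params <- as_cbb_params(params)
  with(params, phi * omega / (mu * (theta + omega)))
}

#' @rdname cbb_thresholds
#' @export
cbb_Psi0 <- function(params) {
  params <- as_cbb_params(params)
  denom <- with(params, (k * alpha + mu) * (k * delta + theta + omega))
  if (denom == 0) stop("Psi0 undefined: zero denominator", call. = FALSE)
  params$phi * params$omega / denom
}

#' @rdname cbb_thresholds
#' @export
cbb_mu_star <- function(params) {
  params <- as_cbb_params(params)
  with(params, phi * omega / (k * delta + theta + omega) - k * alpha)
}

#' @rdname cbb_thresholds
#' @export
cbb_mu_double_star <- function(params) {
  params <- as_cbb_params(params)
  with(params, phi * omega / (theta + omega))
}
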