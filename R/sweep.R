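#' Management scenario sweep over predation rates
#'
#' For each candidate pair of predation rates `(alpha, delta)` this
#' computes the eradication threshold `mu_star` and translates it into an
#' operational target: the minimum number of adult borers that must die
#' daily from factors other than predation (traps, insecticide, natural
#' death) for the pest to be eradicated. The count is
#' `ceiling(A_max * mu_star)`, where `A_max = omega * q / mu_ref` is the
#' adult bound of the invariant region at a reference death rate — the
#' ceiling matches the "at least this many" reading of the threshold.
#' When `mu_star <= 0`, predation alone eradicates the pest and the
#' required count is 0. Raising either predation rate lowers both
#' `mu_star` and the required count.
#'
#' @param pairs A data frame with numeric columns `alpha` and `delta`
#'   (both `>= 0`).
#' @param params_base A [cbb_params] object supplying all other
#'   parameters.
#' @param mu_ref Reference adult death rate defining `A_max`; the default
#'   0.03 is the lowest adult mortality considered in the package's
#'   baseline scenarios.
#' @return A tibble of class `"cbb_sweep"` with columns
#'   `alpha, delta, mu_star, required_deaths`; `mu_ref` and `A_max` are
#'   attached as attributes. Plot with [ggplot2::autoplot()].
#' @examples
#' pairs <- expand.grid(alpha = c(0.01, 0.011), delta = c(0.01, 0.011))
#' predation_sweep(pairs, cbb_baseline_params())
#' @export
predation_sweep <- function(pairs, params_base, mu_ref = 0.03) {
  params_base <- as_cbb_params(params_base)
  pairs <- as.data.frame(pairs)
  if (!all(c("alpha", "delta") %in% names(pairs)) || nrow(pairs) == 0) {
    stop("pairs must be a non-empty data frame with columns alpha and delta", call. = FALSE)
  }
  if (any(!is.finite(pairs$alpha)) || any(!is.finite(pairs$delta)) ||
    any(pairs$alpha < 0) || any(pairs$delta < 0)) {
    stop("predation rates must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(mu_ref) || mu_ref <= 0) stop("mu_ref must be > 0", call. = FALSE)
  amax <- a_max(params_base, mu = mu_ref)
  out <- purrr::map2_dfr(pairs$alpha, pairs$delta, function(a, d) {
    p <- params_base
    p$alpha <- a
    p$delta <- d
    ms <- cbb_mu_star(p)
    tibble::tibble(
      alpha = a, delta = d, mu_star = ms,
      required_deaths = if (ms > 0) as.integer(ceiling(amax * ms)) else 0L
    )
  })
  structure(out,
    class = c("cbb_sweep", class(out)),
    mu_ref = mu_ref, a_max = amax
  )
}

#' Adult mortality required without any predation
#'
#' The no-predation analogue of the sweep: eradication without ants
#' requires `mu > mu_double_star`, i.e. the daily death of
#' `ceiling(A_max * mu_double_star)` adult borers from other causes —
#' far more than with predators present, which is the case for
#' integrated management.
#'
#' @param params A [cbb_params] object.
#' @param mu_ref Reference death rate defining `A_max = omega * q / mu_ref`.
#' @return An integer count of required daily adult deaths.
#' @examples
#' no_predation_requirement(cbb_baseline_params()) # 3372
#' @export
no_predation_requirement <- function(params, mu_ref = 0.03) {
  params <- as_cbb_params(params)
  mds <- cbb_mu_double_star(params)
  if (mds <= 0) {
    return(0L)
  }
  as.integer(ceiling(a_max(params, mu = mu_ref) * mds))
}
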