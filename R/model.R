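#' Vector field of the borer-ant model
#'
#' Right-hand side of the three-dimensional system
#' \deqn{A' = \omega I - \mu A - \alpha A H}
#' \deqn{I' = \phi A (1 - I/q) - \omega I - \theta I - \delta I H}
#' \deqn{H' = (r + \epsilon\alpha A + \epsilon\delta I)\, H (1 - H/k)}
#' where `A` is the adult borer population, `I` the immature borer
#' population and `H` the ant population. Oviposition is regulated by the
#' logistic factor `1 - I/q`; predation on both stages follows mass action;
#' the ants grow logistically with a growth rate boosted by converted prey
#' biomass.
#'
#' @param state Numeric vector `c(A, I, H)` of non-negative populations
#'   (names optional).
#' @param params A [cbb_params] object.
#' @return Named numeric vector `c(dA, dI, dH)` of per-day rates.
#' @examples
#' p <- cbb_baseline_params(mu = 0.03)
#' cbb_rhs(c(A = 10, I = 20, H = 1), p)
#' @export
cbb_rhs <- function(state, params) {
  params <- as_cbb_params(params)
  state <- check_state(state)
  A <- state[[1]]
  I <- state[[2]]
  H <- state[[3]]
  with(params, c(
    dA = omega * I - mu * A - alpha * A * H,
    dI = phi * A * (1 - I / q) - omega * I - theta * I - delta * I * H,
    dH = (r + epsilon * alpha * A + epsilon * delta * I) * H * (1 - H / k)
  ))
}

#' Jacobian matrix of the borer-ant vector field
#'
#' Analytic 3x3 Jacobian of [cbb_rhs] evaluated at a state.
#'
#' @inheritParams cbb_rhs
#' @return A 3x3 numeric matrix with dimnames `A, I, H`; the state it was
#'   evaluated at is attached as attribute `"state"`.
#' @examples
#' p <- cbb_baseline_params(mu = 0.03)
#' cbb_jacobian(c(0, 0, 0), p)
#' @export
cbb_jacobian <- function(state, params) {
  params <- as_cbb_params(params)
  state <- check_state(state)
  A <- state[[1]]
  I <- state[[2]]
  H <- state[[3]]
  J <- with(params, matrix(
    c(
      -mu - alpha * H, omega, -alpha * A,
      phi * (1 - I / q), -phi * A / q - omega - theta - delta * H, -delta * I,
      epsilon * alpha * H * (1 - H / k), epsilon * delta * H * (1 - H / k),
      (r + epsilon * alpha * A + epsilon * delta * I) * (1 - 2 * H / k)
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "I", "H"), c("A", "I", "H"))
  ))
  attr(J, "state") <- state
  J
}

#' Planar vector field on the ant-free plane
#'
#' The restriction of the full system to `H = 0`: a two-dimensional
#' borer-only model
#' \deqn{A' = \omega I - \mu A, \quad I' = \phi A (1 - I/q) - \omega I - \theta I.}
#'
#' @param state Numeric vector `c(A, I)` of non-negative populations.
#' @param params A [cbb_params] object.
#' @return Named numeric vector `c(dA, dI)`.
#' @export
cbb_reduced_rhs <- function(state, params) {
  params <- as_cbb_params(params)
  if (length(state) != 2L || !is.numeric(state) || !all(is.finite(state))) {
    stop("state must be a finite numeric vector c(A, I)", call. = FALSE)
  }
  if (any(state < 0)) stop("populations must be non-negative", call. = FALSE)
  full <- cbb_rhs(c(state[[1]], state[[2]], 0), params)
  c(dA = full[["dA"]], dI = full[["dI"]])
}

#' Upper bound of the adult population in the invariant region
#'
#' The box \eqn{\Omega = [0, \omega q/\mu] \times [0, q] \times [0, k]} is
#' positively invariant: trajectories starting inside never leave it. This
#' helper returns the adult bound \eqn{\omega q / \mu}.
#'
#' @param params A [cbb_params] object.
#' @param mu Optional override of the adult death rate used in the bound
#'   (the bound is often quoted at a reference `mu` while `mu` itself is
#'   varied); defaults to `params$mu`.
#' @return The adult upper bound (individuals).
#' @examples
#' a_max(cbb_baseline_params(mu = 0.03)) # 3966.67
#' @export
a_max <- function(params, mu = NULL) {
  params <- as_cbb_params(params)
  mu <- if (is.null(mu)) params$mu else mu
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("mu must be a positive finite scalar", call. = FALSE)
  }
  params$omega * params$q / mu
}

#' Bounds of the positively invariant region
#'
#' @param params A [cbb_params] object.
#' @return A tibble with one row per state variable and columns
#'   `var`, `lower`, `upper` describing the invariant box.
#' @export
omega_region <- function(params) {
  params <- as_cbb_params(params)
  tibble::tibble(
    var = c("A", "I", "H"),
    lower = 0,
    upper = c(a_max(params), params$q, params$k)
  )
}

# internal: validate a 3-state
check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 3L || !all(is.finite(state))) {
    stop("state must be a finite numeric vector c(A, I, H)", call. = FALSE)
  }
  if (any(state < 0)) stop("populations must be non-negative", call. = FALSE)
  state
}
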