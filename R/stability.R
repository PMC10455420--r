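#' Eigenvalues of the Jacobian at a named equilibrium
#'
#' `cbb_eigen_closed_form()` evaluates the closed-form eigenvalue
#' expressions at one of the equilibria; `cbb_eigen_numeric()` computes
#' the eigenvalues of the analytic Jacobian numerically and matches each
#' to its closed-form label by nearest value (not by magnitude sorting),
#' so the two routes stay directly comparable. All eigenvalues of this
#' system are real: every radicand in the closed forms is positive.
#'
#' Closed forms, with \eqn{\Lambda = k\alpha+\mu} and
#' \eqn{D = k\delta+\theta+\omega}:
#' * `E1`: \eqn{\lambda_1 = r}, \eqn{\lambda_{2,3} =
#'   -\tfrac12[(\theta+\mu+\omega) \pm \sqrt{(\theta-\mu+\omega)^2+4\phi\omega}]};
#' * `E2` (needs \eqn{B_0 \ge 1}): \eqn{\lambda_1 =
#'   q\epsilon(\theta+\omega)(\alpha\omega+\delta\mu)(B_0-1)/(\phi\omega)+r},
#'   \eqn{\lambda_{2,3} = -[\mu^2+\phi\omega \pm
#'   \sqrt{(\mu^2-\phi\omega)^2+4\mu^3(\theta+\omega)}]/(2\mu)};
#' * `E3`: \eqn{\lambda_1 = -r}, \eqn{\lambda_{2,3} = -\tfrac12[\Delta \pm
#'   \sqrt{(k\alpha+\mu-k\delta-\theta-\omega)^2+4\phi\omega}]} with
#'   \eqn{\Delta = k\alpha+k\delta+\theta+\mu+\omega};
#' * `E4` (needs \eqn{\Psi_0 \ge 1}): \eqn{\lambda_1 =
#'   -[q\epsilon D(\alpha\omega+k\alpha\delta+\delta\mu)(\Psi_0-1)/(\phi\omega)+r]},
#'   \eqn{\lambda_{2,3} = -[\Lambda^2+\phi\omega \pm
#'   \sqrt{(\Lambda^2-\phi\omega)^2+4D\Lambda^3}]/(2\Lambda)};
#' * `E1_reduced` / `E2_reduced`: the planar blocks of `E1` / `E2`
#'   (\eqn{\lambda_{2,3}} above, relabelled \eqn{\lambda_{1,2}}).
#'
#' @param label One of `"E1"`, `"E2"`, `"E3"`, `"E4"`, `"E1_reduced"`,
#'   `"E2_reduced"`.
#' @param params A [cbb_params] object.
#' @return A tibble with columns `label`, `eigenvalue` (`"lambda1"`, ...),
#'   `value`, `method`; the intermediates `Lambda` and `Delta` are attached
#'   as attributes.
#' @examples
#' p <- cbb_baseline_params(mu = 0.03)
#' cbb_eigen_closed_form("E1", p)
#' cbb_eigen_numeric("E4", p)
#' @export
cbb_eigen_closed_form <- function(label, params) {
  params <- as_cbb_params(params)
  label <- match.arg(label, c("E1", "E2", "E3", "E4", "E1_reduced", "E2_reduced"))
  check_sense(label, params)
  lam <- with(params, switch(label,
    E1 = c(r, eig_pair(theta + mu + omega, (theta - mu + omega)^2 + 4 * phi * omega)),
    E2 = {
      B0 <- cbb_B0(params)
      c(
        q * epsilon * (theta + omega) * (alpha * omega + delta * mu) * (B0 - 1) / (phi * omega) + r,
        eig_pair((mu^2 + phi * omega) / mu, ((mu^2 - phi * omega)^2 + 4 * mu^3 * (theta + omega)) / mu^2)
      )
    },
    E3 = {
      Delta <- k * alpha + k * delta + theta + mu + omega
      c(-r, eig_pair(Delta, (k * alpha + mu - k * delta - theta - omega)^2 + 4 * phi * omega))
    },
    E4 = {
      Psi0 <- cbb_Psi0(params)
      Lambda <- k * alpha + mu
      D <- k * delta + theta + omega
      c(
        -(q * epsilon * D * (alpha * omega + k * alpha * delta + delta * mu) * (Psi0 - 1) / (phi * omega) + r),
        eig_pair((Lambda^2 + phi * omega) / Lambda, ((Lambda^2 - phi * omega)^2 + 4 * D * Lambda^3) / Lambda^2)
      )
    },
    E1_reduced = eig_pair(theta + mu + omega, (theta - mu + omega)^2 + 4 * phi * omega),
    E2_reduced = eig_pair(
      (mu^2 + phi * omega) / mu,
      ((mu^2 - phi * omega)^2 + 4 * mu^3 * (theta + omega)) / mu^2
    )
  ))
  eigen_tbl(label, lam, "closed_form", params)
}

# the recurring pair -(s +/- sqrt(rad))/2, ordered (minus-root, plus-root):
# first element is the always-negative one, second the sign-indefinite one
eig_pair <- function(s, rad) {
  c(-(s + sqrt(rad)) / 2, -(s - sqrt(rad)) / 2)
}

#' @rdname cbb_eigen_closed_form
#' @export
cbb_eigen_numeric <- function(label, params) {
  params <- as_cbb_params(params)
  label <- match.arg(label, c("E1", "E2", "E3", "E4", "E1_reduced", "E2_reduced"))
  check_sense(label, params)
  reduced <- grepl("_reduced$", label)
  if (reduced) {
    eq <- cbb_reduced_equilibria(params)
    co <- eq[eq$label == label, ]
    J <- cbb_jacobian(c(max(co$A, 0), max(co$I, 0), 0), params)[1:2, 1:2]
  } else {
    eq <- cbb_equilibria(params)
    co <- eq[eq$label == label, ]
    J <- cbb_jacobian(c(max(co$A, 0), max(co$I, 0), co$H), params)
  }
  ev <- eigen(J, only.values = TRUE)$values
  if (is.complex(ev)) ev <- Re(ev) # radicands are positive; imaginary parts are noise
  closed <- cbb_eigen_closed_form(label, params)$value
  # match numeric eigenvalues to the closed-form labelling by nearest value
  ord <- rep(NA_integer_, length(closed))
  avail <- seq_along(ev)
  for (i in seq_along(closed)) {
    j <- avail[which.min(abs(ev[avail] - closed[i]))]
    ord[i] <- j
    avail <- setdiff(avail, j)
  }
  eigen_tbl(label, ev[ord], "numeric", params)
}

eigen_tbl <- function(label, lam, method, params) {
  out <- tibble::tibble(
    label = label,
    eigenvalue = paste0("lambda", seq_along(lam)),
    value = unname(lam),
    method = method
  )
  attr(out, "Lambda") <- params$k * params$alpha + params$mu
  attr(out, "Delta") <- with(params, k * alpha + k * delta + theta + mu + omega)
  out
}

check_sense <- function(label, params) {
  if (label %in% c("E2", "E2_reduced") && cbb_B0(params) < 1 - 1e-9) {
    stop(label, " has no biological sense (B0 < 1)", call. = FALSE)
  }
  if (label == "E4" && cbb_Psi0(params) < 1 - 1e-9) {
    stop("E4 has no biological sense (Psi0 < 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Stability classification of all equilibria
#'
#' Classifies the four equilibria as a function of the adult death rate
#' `mu` relative to the bifurcation values `mu_star` and `mu_double_star`
#' (equivalently, the thresholds `Psi0` and `B0` relative to 1):
#'
#' 1. `mu < mu_star` (`1 < Psi0 < B0`): E1, E2, E3 unstable saddles; the
#'    coexistence equilibrium E4 is locally asymptotically stable.
#' 2. `mu = mu_star` (`Psi0 = 1`): E4 collides with E3 (nonhyperbolic,
#'    attracting through the transcritical bifurcation); E1, E2 unstable.
#' 3. `mu_star < mu < mu_double_star` (`Psi0 < 1 < B0`): E3 locally
#'    asymptotically stable (borer eradicated, ants at capacity); E4 loses
#'    biological sense; E1, E2 unstable.
#' 4. `mu = mu_double_star` (`B0 = 1`): E2 collides with E1, which is
#'    nonhyperbolic but still unstable (shown by the direct Lyapunov
#'    method, see [lyapunov_instability_demo]); E3 locally asymptotically
#'    stable.
#' 5. `mu > mu_double_star` (`B0 < 1`): E2 and E4 lose biological sense;
#'    E1 unstable; E3 locally asymptotically stable.
#'
#' E1 is unstable in every case: the pest-and-predator-free state is never
#' an attractor because the ant population always invades.
#'
#' @param params A [cbb_params] object.
#' @param tol Relative tolerance on `|threshold - 1|` used to detect the
#'   collision cases 2 and 4.
#' @return A tibble with one row per equilibrium: `label`, `A`, `I`, `H`,
#'   `biological_sense`, `verdict` (one of
#'   `"locally_asymptotically_stable"`, `"unstable_saddle"`, `"unstable"`,
#'   `"nonhyperbolic"`, `"no_biological_sense"`), `stable` (logical; `NA`
#'   when without biological sense), `collided_with`, `case` (1-5) and
#'   `governing_condition`.
#' @examples
#' cbb_classify(cbb_baseline_params(mu = 0.5))
#' @export
cbb_classify <- function(params, tol = 1e-9) {
  params <- as_cbb_params(params)
  th <- cbb_thresholds(params)
  eq <- cbb_equilibria(params, tol = tol)
  case <- if (abs(th$Psi0 - 1) <= tol) {
    2L
  } else if (abs(th$B0 - 1) <= tol) {
    4L
  } else if (th$Psi0 > 1) 1L else if (th$B0 > 1) 3L else 5L

  v <- switch(case,
    `1` = c("unstable_saddle", "unstable_saddle", "unstable_saddle", "locally_asymptotically_stable"),
    `2` = c("unstable_saddle", "unstable_saddle", "nonhyperbolic", "nonhyperbolic"),
    `3` = c("unstable_saddle", "unstable_saddle", "locally_asymptotically_stable", "no_biological_sense"),
    `4` = c("nonhyperbolic", "nonhyperbolic", "locally_asymptotically_stable", "no_biological_sense"),
    `5` = c("unstable_saddle", "no_biological_sense", "locally_asymptotically_stable", "no_biological_sense")
  )
  s <- switch(case,
    `1` = c(FALSE, FALSE, FALSE, TRUE),
    `2` = c(FALSE, FALSE, TRUE, TRUE),
    `3` = c(FALSE, FALSE, TRUE, NA),
    `4` = c(FALSE, FALSE, TRUE, NA),
    `5` = c(FALSE, NA, TRUE, NA)
  )
  cond <- switch(case,
    `1` = "mu < mu_star (1 < Psi0 < B0): coexistence attractor E4",
    `2` = "mu = mu_star (Psi0 = 1): transcritical collision E4 = E3, attracting",
    `3` = "mu_star < mu < mu_double_star (Psi0 < 1 < B0): borer eradicated, E3 attracting",
    `4` = "mu = mu_double_star (B0 = 1): E2 collides with E1; E1 unstable by Lyapunov direct method",
    `5` = "mu > mu_double_star (B0 < 1): borer eradicated even without predation"
  )
  dplyr::mutate(eq,
    verdict = v, stable = s, case = case, governing_condition = cond,
    exists_distinct = NULL
  )
}
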