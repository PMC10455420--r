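#' Closed-form equilibria of the borer-ant model
#'
#' The system has four equilibria:
#' * `E1 = (0, 0, 0)` — total extinction;
#' * `E2 = (q*omega/mu * (B0-1)/B0, q*(B0-1)/B0, 0)` — borer persists,
#'   no ants; biologically admissible only when `B0 >= 1`;
#' * `E3 = (0, 0, k)` — borer eradicated, ants at carrying capacity;
#' * `E4 = (q*omega/(k*alpha+mu) * (Psi0-1)/Psi0, q*(Psi0-1)/Psi0, k)` —
#'   coexistence with ants at capacity; admissible only when `Psi0 >= 1`.
#'
#' `E2` collides with `E1` as `B0` passes 1 (equivalently `mu` passes
#' `mu_double_star`), and `E4` collides with `E3` as `Psi0` passes 1
#' (`mu` passes `mu_star`); collisions are flagged within `tol`.
#'
#' @param params A [cbb_params] object.
#' @param tol Collision tolerance on `|threshold - 1|`. Thresholds are
#'   closed-form, so the default only absorbs floating-point noise.
#' @return A tibble with columns `label`, `A`, `I`, `H`,
#'   `biological_sense` (all components non-negative), `exists_distinct`
#'   (`FALSE` when collided with another equilibrium) and `collided_with`
#'   (`NA` or the partner label).
#' @examples
#' cbb_equilibria(cbb_baseline_params(mu = 0.03))
#' @export
cbb_equilibria <- function(params, tol = 1e-9) {
  params <- as_cbb_params(params)
  B0 <- cbb_B0(params)
  Psi0 <- cbb_Psi0(params)
  e2_collide <- abs(B0 - 1) <= tol
  e4_collide <- abs(Psi0 - 1) <= tol
  with(params, tibble::tibble(
    label = c("E1", "E2", "E3", "E4"),
    A = c(0, q * omega / mu * (B0 - 1) / B0, 0, q * omega / (k * alpha + mu) * (Psi0 - 1) / Psi0),
    I = c(0, q * (B0 - 1) / B0, 0, q * (Psi0 - 1) / Psi0),
    H = c(0, 0, k, k),
    biological_sense = c(TRUE, B0 >= 1 || e2_collide, TRUE, Psi0 >= 1 || e4_collide),
    exists_distinct = c(!e2_collide, !e2_collide, !e4_collide, !e4_collide),
    collided_with = c(
      if (e2_collide) "E2" else NA_character_,
      if (e2_collide) "E1" else NA_character_,
      if (e4_collide) "E4" else NA_character_,
      if (e4_collide) "E3" else NA_character_
    )
  ))
}

#' Equilibria of the ant-free planar system
#'
#' On the plane `H = 0` the dynamics reduce to a two-dimensional
#' borer-only model with equilibria `(0, 0)` and the first two coordinates
#' of `E2`; the latter collides with the origin when `B0 = 1`
#' (`mu = mu_double_star`).
#'
#' @inheritParams cbb_equilibria
#' @return A tibble with columns `label` (`"E1_reduced"`, `"E2_reduced"`),
#'   `A`, `I`, `biological_sense`, `exists_distinct`, `collided_with`.
#' @export
cbb_reduced_equilibria <- function(params, tol = 1e-9) {
  params <- as_cbb_params(params)
  B0 <- cbb_B0(params)
  collide <- abs(B0 - 1) <= tol
  with(params, tibble::tibble(
    label = c("E1_reduced", "E2_reduced"),
    A = c(0, q * omega / mu * (B0 - 1) / B0),
    I = c(0, q * (B0 - 1) / B0),
    biological_sense = c(TRUE, B0 >= 1 || collide),
    exists_distinct = !collide,
    collided_with = if (collide) c("E2_reduced", "E1_reduced") else NA_character_
  ))
}

#' Numerically search for equilibria of the full system
#'
#' Independent check on the closed forms: runs a derivative-free nonlinear
#' root finder (Broyden's method, [pracma::fsolve]) on the vector field
#' from random starts inside the invariant region, keeps converged roots,
#' and clusters them. The system also has mathematically valid roots with
#' negative components (on the plane `r + eps*alpha*A + eps*delta*I = 0`);
#' the `in_region` column distinguishes biological roots, which should all
#' coincide with one of the closed-form equilibria.
#'
#' @param params A [cbb_params] object.
#' @param n_starts Number of random starts.
#' @param seed Integer seed for start sampling.
#' @param cluster_tol Roots closer than this (relative to scale) are merged.
#' @return A tibble with columns `A`, `I`, `H`, `residual`, `in_region`.
#' @export
find_equilibria_numeric <- function(params, n_starts = 50, seed = 1,
                                    cluster_tol = 1e-6) {
  params <- as_cbb_params(params)
  starts <- sample_states_in_omega(params, n = n_starts, seed = seed)
  f <- function(x) unname(rhs_raw(x[1], x[2], x[3], params))
  roots <- purrr::map(seq_len(nrow(starts)), function(i) {
    x0 <- as.numeric(starts[i, c("A", "I", "H")])
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(f, x0, tol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(sol)) {
      return(NULL)
    }
    x <- as.numeric(sol$x)
    # polish with Newton steps on a finite-difference Jacobian: Broyden can
    # stop short near degenerate (colliding) equilibria
    for (it in 1:10) {
      fx <- f(x)
      if (max(abs(fx)) <= 1e-12 * (1 + max(abs(x)))) break
      step <- tryCatch(solve(pracma::jacobian(f, x), fx), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      x <- x - step
    }
    if (max(abs(f(x))) > 1e-9 * (1 + max(abs(x)))) {
      return(NULL)
    }
    x
  })
  roots <- purrr::compact(roots)
  if (length(roots) == 0) {
    return(tibble::tibble(
      A = numeric(), I = numeric(), H = numeric(),
      residual = numeric(), in_region = logical()
    ))
  }
  scale <- 1 + max(a_max(params), params$q, params$k)
  kept <- list()
  for (x in roots) {
    dup <- any(vapply(kept, function(y) max(abs(x - y)) <= cluster_tol * scale, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- x
  }
  m <- do.call(rbind, kept)
  reg <- omega_region(params)
  # roundoff-level slack only: wider margins would misfile the spurious
  # negative-component roots on the plane r + eps*alpha*A + eps*delta*I = 0
  slack <- 1e-9 * scale
  tibble::tibble(
    A = m[, 1], I = m[, 2], H = m[, 3],
    residual = vapply(kept, function(x) max(abs(f(x))), numeric(1)),
    in_region = m[, 1] >= -slack & m[, 1] <= reg$upper[1] + slack &
      m[, 2] >= -slack & m[, 2] <= reg$upper[2] + slack &
      m[, 3] >= -slack & m[, 3] <= reg$upper[3] + slack
  )
}

# internal: rhs without state validation (solvers may step slightly negative)
rhs_raw <- function(A, I, H, p) {
  c(
    dA = p$omega * I - p$mu * A - p$alpha * A * H,
    dI = p$phi * A * (1 - I / p$q) - p$omega * I - p$theta * I - p$delta * I * H,
    dH = (p$r + p$epsilon * p$alpha * A + p$epsilon * p$delta * I) * H * (1 - H / p$k)
  )
}
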