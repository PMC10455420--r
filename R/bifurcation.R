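#' Sotomayor certificate for the transcritical bifurcations
#'
#' Certifies the two transcritical bifurcations of the model by checking
#' Sotomayor's conditions (case ii) at the bifurcation value:
#'
#' * the full system at `E3 = (0, 0, k)` as `mu` crosses `mu_star`
#'   (coexistence equilibrium E4 passes through E3 and exchanges
#'   stability), and
#' * the ant-free planar system at the origin as `mu` crosses
#'   `mu_double_star` (the borer-persistence equilibrium passes through
#'   extinction).
#'
#' With `v` and `w` the right/left null eigenvectors of the Jacobian
#' (normalized so the second component is 1, keeping the scalars
#' comparable to their closed forms), the three scalars are
#' `c1 = w' f_mu`, `c2 = w' Df_mu v` and `c3 = w' D^2 f (v, v)`. A
#' transcritical bifurcation requires `c1 = 0`, `c2 != 0`, `c3 != 0`.
#' Closed forms, with `D = k*delta + theta + omega`:
#' `c2 = -D^2/(phi*omega)`, `c3 = -2 D / q` at `E3`, and the same with
#' `D` replaced by `theta + omega` in the planar case. Each scalar is also
#' recomputed by nested central differences of the vector field; the two
#' routes must agree (the field is polynomial of degree three, so the
#' differences are exact up to roundoff).
#'
#' @param equilibrium `"E3"` (full system at `mu_star`) or `"E1_reduced"`
#'   (planar system at `mu_double_star`).
#' @param params A [cbb_params] object; its `mu` is replaced by `mu_bif`.
#' @param mu_bif Candidate bifurcation value; defaults to the closed-form
#'   `mu_star` or `mu_double_star`. A precondition error is raised if the
#'   designated eigenvalue is not (near) zero there.
#' @param tol Tolerance for `|c1| = 0` and the nonzero checks.
#' @return An object of class `"cbb_sotomayor"`: a list with the
#'   equilibrium label, `mu_bif`, eigenvectors `v`, `w`, closed-form and
#'   numeric `c1, c2, c3`, and `verdict` (`"transcritical"` or
#'   `"inconclusive"`). Has [generics::tidy] and print methods.
#' @examples
#' sotomayor_check("E3", cbb_baseline_params())
#' @export
sotomayor_check <- function(equilibrium = c("E3", "E1_reduced"), params,
                            mu_bif = NULL, tol = 1e-8) {
  equilibrium <- match.arg(equilibrium)
  params <- as_cbb_params(params)
  if (is.null(mu_bif)) {
    mu_bif <- if (equilibrium == "E3") cbb_mu_star(params) else cbb_mu_double_star(params)
  }
  if (mu_bif <= 0) {
    stop("candidate bifurcation value is not positive (mu_star = ", mu_bif,
      "): eradication is predicted for all mu > 0",
      call. = FALSE
    )
  }
  p <- params
  p$mu <- mu_bif

  if (equilibrium == "E3") {
    D <- with(p, k * delta + theta + omega)
    x0 <- c(0, 0, p$k)
    v <- c(D / p$phi, 1, 0)
    w <- c(D / p$omega, 1, 0)
    lam <- cbb_eigen_closed_form("E3", p)$value
    f <- function(x, mu) {
      pp <- p
      pp$mu <- mu
      rhs_raw(x[1], x[2], x[3], pp)
    }
    c2_cf <- -D^2 / (p$phi * p$omega)
    c3_cf <- -2 * D / p$q
  } else {
    D <- with(p, theta + omega)
    x0 <- c(0, 0)
    v <- c(D / p$phi, 1)
    w <- c(D / p$omega, 1)
    lam <- cbb_eigen_closed_form("E1_reduced", p)$value
    f <- function(x, mu) {
      c(
        p$omega * x[2] - mu * x[1],
        p$phi * x[1] * (1 - x[2] / p$q) - p$omega * x[2] - p$theta * x[2]
      )
    }
    c2_cf <- -D^2 / (p$phi * p$omega)
    c3_cf <- -2 * D / p$q
  }
  J <- if (equilibrium == "E3") cbb_jacobian(x0, p) else cbb_jacobian(c(x0, 0), p)[1:2, 1:2]
  if (min(abs(lam)) > 1e-8 * (1 + max(abs(J)))) {
    stop("no near-zero eigenvalue at mu_bif = ", mu_bif, "; not a bifurcation candidate", call. = FALSE)
  }

  # nested central differences; f is cubic, so these are exact to roundoff
  h <- 1e-4 * (1 + max(abs(x0)))
  hm <- 1e-4 * (1 + abs(mu_bif))
  f_mu <- function(x) (f(x, mu_bif + hm) - f(x, mu_bif - hm)) / (2 * hm)
  c1_num <- sum(w * f_mu(x0))
  c2_num <- sum(w * (f_mu(x0 + h * v) - f_mu(x0 - h * v)) / (2 * h))
  c3_num <- sum(w * (f(x0 + h * v, mu_bif) - 2 * f(x0, mu_bif) + f(x0 - h * v, mu_bif)) / h^2)
  c1_cf <- 0

  verdict <- if (abs(c1_num - c1_cf) <= tol && abs(c2_num) > tol && abs(c3_num) > tol) {
    "transcritical"
  } else {
    "inconclusive"
  }
  structure(
    list(
      equilibrium = equilibrium, mu_bif = mu_bif, v = v, w = w,
      c1 = c1_cf, c2 = c2_cf, c3 = c3_cf,
      c1_numeric = c1_num, c2_numeric = c2_num, c3_numeric = c3_num,
      verdict = verdict
    ),
    class = "cbb_sotomayor"
  )
}

#' @export
print.cbb_sotomayor <- function(x, ...) {
  cat(sprintf(
    "<cbb_sotomayor> %s at mu = %.6g: %s\n  c1 = %g, c2 = %.6g, c3 = %.6g\n",
    x$equilibrium, x$mu_bif, x$verdict, x$c1, x$c2, x$c3
  ))
  invisible(x)
}

#' @rdname sotomayor_check
#' @param x A `cbb_sotomayor` object.
#' @param ... Unused.
#' @export
tidy.cbb_sotomayor <- function(x, ...) {
  tibble::tibble(
    term = c("c1", "c2", "c3"),
    closed_form = c(x$c1, x$c2, x$c3),
    numeric = c(x$c1_numeric, x$c2_numeric, x$c3_numeric)
  )
}

#' Demonstrate instability of the extinction equilibrium by Lyapunov's direct method
#'
#' At the origin the linearization always has the positive eigenvalue `r`,
#' but when `B0 = 1` a second eigenvalue vanishes and the equilibrium is
#' nonhyperbolic. The scalar function `V(A, I, H) = H` still certifies
#' instability: inside the ball `S` of radius `rho/2` around the origin,
#' with `rho = min(r / (epsilon * sqrt(alpha^2 + delta^2)), k)` (the first
#' term is the distance from the origin to the plane
#' `r + eps*alpha*A + eps*delta*I = 0`), the derivative of `V` along
#' trajectories with `H > 0` is strictly positive, so every such
#' trajectory leaves `S` in finite time. This function samples starts in
#' `{H > 0}` intersected with `S`, integrates them, and records the ant
#' population's monotone growth and the first exit time.
#'
#' @param params A [cbb_params] object.
#' @param n_starts Number of sampled starts.
#' @param seed Integer seed.
#' @param t_end Integration horizon (days); exit typically occurs on a
#'   `O(1/r)` timescale.
#' @return An object of class `"cbb_lyapunov"`: a list with `rho`, a
#'   tibble `starts` (`A0, I0, H0, escape_time, V_monotone, min_dVdt`),
#'   and the parameters used.
#' @examples
#' demo <- lyapunov_instability_demo(cbb_baseline_params(mu = 0.85), n_starts = 3, t_end = 2000)
#' demo$rho
#' @export
lyapunov_instability_demo <- function(params, n_starts = 20, seed = 20230675,
                                      t_end = 5000) {
  params <- as_cbb_params(params)
  rho <- lyapunov_rho(params)
  set.seed(seed %% .Machine$integer.max)
  # uniform in the positive-H part of the ball of radius rho/2
  pts <- matrix(stats::rnorm(3 * n_starts), ncol = 3)
  rad <- (rho / 2) * stats::runif(n_starts)^(1 / 3)
  pts <- abs(pts / sqrt(rowSums(pts^2))) * rad
  pts[pts[, 3] <= 0, 3] <- rho / 100 # guard: H must be strictly positive

  rows <- purrr::map(seq_len(n_starts), function(i) {
    y0 <- pts[i, ]
    traj <- cbb_simulate(params, y0,
      t_end = t_end,
      n_out = max(2000L, as.integer(t_end)), warn_outside = FALSE
    )
    norms <- sqrt(traj$A^2 + traj$I^2 + traj$H^2)
    inside <- norms < rho / 2
    out_idx <- which(!inside)
    escape <- if (length(out_idx) > 0) traj$time[out_idx[1]] else NA_real_
    in_idx <- if (length(out_idx) > 0) seq_len(out_idx[1]) else seq_along(norms)
    dV <- vapply(
      in_idx,
      function(j) rhs_raw(traj$A[j], traj$I[j], traj$H[j], params)[["dH"]],
      numeric(1)
    )
    tibble::tibble(
      A0 = y0[1], I0 = y0[2], H0 = y0[3],
      escape_time = escape,
      V_monotone = !is.unsorted(traj$H[in_idx]),
      min_dVdt = min(dV)
    )
  })
  structure(
    list(rho = rho, starts = dplyr::bind_rows(rows), params = params),
    class = "cbb_lyapunov"
  )
}

#' @rdname lyapunov_instability_demo
#' @export
lyapunov_rho <- function(params) {
  params <- as_cbb_params(params)
  with(params, {
    plane_dist <- if (alpha == 0 && delta == 0) Inf else r / (epsilon * sqrt(alpha^2 + delta^2))
    min(plane_dist, k)
  })
}

#' One-parameter bifurcation diagram in the adult death rate
#'
#' Sweeps `mu` over a grid (always augmented with the exact bifurcation
#' values `mu_star` and `mu_double_star` when they fall inside the range)
#' and records each equilibrium's coordinates, stability and biological
#' sense, reproducing the qualitative branch structure: E4 hands its
#' stability to E3 at `mu_star`, and E2 collapses into E1 at
#' `mu_double_star`.
#'
#' @param params A [cbb_params] object; its `mu` is ignored in favour of
#'   the grid.
#' @param mu_min,mu_max Positive grid range.
#' @param n_grid Number of grid points.
#' @return A tibble of class `"cbb_bifurcation"` with columns `mu`,
#'   `label`, `A`, `I`, `H`, `stable`, `biological_sense`, `case`;
#'   bifurcation values are attached as attribute `"bif_points"`. Plot
#'   with [ggplot2::autoplot()].
#' @examples
#' bd <- bifurcation_diagram(cbb_baseline_params(), 0.01, 1, n_grid = 50)
#' attr(bd, "bif_points")
#' @export
bifurcation_diagram <- function(params, mu_min = 0.01, mu_max = 1, n_grid = 200) {
  params <- as_cbb_params(params)
  stopifnot("need 0 < mu_min < mu_max" = mu_min > 0 && mu_min < mu_max)
  mu_star <- cbb_mu_star(params)
  mu_dstar <- cbb_mu_double_star(params)
  grid <- seq(mu_min, mu_max, length.out = n_grid)
  bifs <- c(mu_star = mu_star, mu_double_star = mu_dstar)
  inside <- bifs[bifs >= mu_min & bifs <= mu_max]
  if (length(inside) < length(bifs[bifs > 0])) {
    warning("grid range does not contain all bifurcation values (mu* = ",
      signif(mu_star, 6), ", mu** = ", signif(mu_dstar, 6), ")",
      call. = FALSE
    )
  }
  grid <- sort(unique(c(grid, unname(inside))))
  out <- purrr::map_dfr(grid, function(m) {
    p <- params
    p$mu <- m
    cl <- cbb_classify(p)
    tibble::tibble(
      mu = m, label = cl$label, A = cl$A, I = cl$I, H = cl$H,
      stable = cl$stable, biological_sense = cl$biological_sense,
      case = cl$case
    )
  })
  structure(out,
    class = c("cbb_bifurcation", class(out)),
    bif_points = bifs
  )
}
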