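#' Integrate the borer-ant model
#'
#' Adaptive-step numerical integration of the full system with
#' [deSolve::ode] (`lsoda`, which switches to a stiff integrator on
#' demand; the model is mildly stiff near `I = q` when the oviposition
#' rate is large). States are not clipped to non-negativity: the region
#' \eqn{\Omega} is positively invariant, so a solver defect surfaces in
#' [check_invariance] instead of being masked.
#'
#' @param params A [cbb_params] object.
#' @param y0 Initial state `c(A, I, H)`. A warning (not an error) is
#'   issued when it lies outside the invariant region.
#' @param t_end Integration horizon in days. The default suits the
#'   baseline parameters, whose slowest eigenvalue magnitudes are of
#'   order `1e-2` per day.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param n_out Number of equally spaced output times (including `t = 0`).
#' @param warn_outside Set `FALSE` to silence the outside-region warning.
#' @param maxsteps Maximum internal solver steps per output interval; the
#'   default accommodates fast transients under large rate constants.
#' @return A tibble of class `"cbb_trajectory"` with columns
#'   `time, A, I, H`; the parameters and solver settings are attached as
#'   attributes. Plot with [ggplot2::autoplot()]; summarize with
#'   [generics::glance()].
#' @examples
#' p <- cbb_baseline_params(mu = 0.5)
#' traj <- cbb_simulate(p, c(5, 1, 32), t_end = 2000)
#' glance(traj)
#' @export
cbb_simulate <- function(params, y0, t_end = 5000, rtol = 1e-8, atol = 1e-10,
                         n_out = 1001L, warn_outside = TRUE, maxsteps = 100000L) {
  params <- as_cbb_params(params)
  if (!is.numeric(y0) || length(y0) != 3L || !all(is.finite(y0))) {
    stop("y0 must be a finite numeric vector c(A, I, H)", call. = FALSE)
  }
  stopifnot("t_end must be > 0" = t_end > 0)
  reg <- omega_region(params)
  if (warn_outside && (any(y0 < 0) || any(y0 > reg$upper))) {
    warning("initial state lies outside the invariant region", call. = FALSE)
  }
  times <- seq(0, t_end, length.out = max(n_out, 2L))
  run <- function(method) {
    deSolve::ode(
      y = c(A = y0[[1]], I = y0[[2]], H = y0[[3]]),
      times = times,
      func = function(t, y, p) list(rhs_raw(y[[1]], y[[2]], y[[3]], p)),
      parms = params,
      method = method, rtol = rtol, atol = atol, maxsteps = maxsteps
    )
  }
  method <- "lsoda"
  sol <- tryCatch(suppressWarnings(run("lsoda")), error = function(e) NULL)
  if (is.null(sol) || attr(sol, "istate")[1] < 0) {
    # fully implicit fallback for strongly stiff parameter corners where
    # lsoda's step-size control gives up
    method <- "bdf"
    sol <- run("bdf")
  }
  diagn <- attributes(sol)[c("istate", "rstate")]
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed (", method, " istate = ", attr(sol, "istate")[1], ")", call. = FALSE)
  }
  out <- tibble::tibble(
    time = sol[, "time"], A = sol[, "A"], I = sol[, "I"], H = sol[, "H"]
  )
  structure(out,
    class = c("cbb_trajectory", class(out)),
    params = params,
    solver = list(method = method, rtol = rtol, atol = atol, istate = diagn$istate)
  )
}

#' One-row summary of a trajectory
#'
#' @param x A `cbb_trajectory` tibble from [cbb_simulate].
#' @param ... Unused.
#' @return A one-row tibble: time span, terminal state, solver settings.
#' @export
glance.cbb_trajectory <- function(x, ...) {
  n <- nrow(x)
  s <- attr(x, "solver")
  tibble::tibble(
    t_end = x$time[n], n_out = n,
    A_end = x$A[n], I_end = x$I[n], H_end = x$H[n],
    rtol = s$rtol, atol = s$atol
  )
}

#' Verify a trajectory stays inside the invariant region
#'
#' Checks every stored state against the box
#' \eqn{[0, \omega q/\mu] \times [0, q] \times [0, k]} with an additive
#' slack absorbing solver error.
#'
#' @param traj A `cbb_trajectory` from [cbb_simulate].
#' @param params Parameters defining the region; defaults to those the
#'   trajectory was produced with.
#' @param slack Additive tolerance on each bound.
#' @return A list with `ok` (logical) and `first_violation` (`NULL`, or a
#'   one-row tibble `time, var, value, bound` for the earliest violation).
#' @export
check_invariance <- function(traj, params = NULL, slack = 1e-6) {
  if (is.null(params)) params <- attr(traj, "params")
  params <- as_cbb_params(params)
  reg <- omega_region(params)
  long <- tidyr::pivot_longer(traj[, c("time", "A", "I", "H")],
    cols = c("A", "I", "H"), names_to = "var", values_to = "value"
  )
  long <- dplyr::left_join(long, reg, by = "var")
  bad <- dplyr::filter(long, .data$value < .data$lower - slack | .data$value > .data$upper + slack)
  if (nrow(bad) == 0) {
    return(list(ok = TRUE, first_violation = NULL))
  }
  first <- dplyr::slice_min(bad, .data$time, n = 1, with_ties = FALSE)
  list(
    ok = FALSE,
    first_violation = tibble::tibble(
      time = first$time, var = first$var, value = first$value,
      bound = ifelse(first$value < first$lower - slack, first$lower, first$upper)
    )
  )
}

#' Detect convergence of a trajectory to a predicted equilibrium
#'
#' Declares convergence to an equilibrium when the maximum Euclidean
#' distance to it over the trailing window of the trajectory is below
#' `tol`; using a window rather than the final state guards against slow
#' transients that merely pass near an equilibrium.
#'
#' @param traj A `cbb_trajectory`.
#' @param equilibria A tibble of candidate equilibria (columns
#'   `label, A, I, H`); defaults to the biologically admissible closed-form
#'   equilibria for the trajectory's parameters.
#' @param tol Absolute distance tolerance (populations are of order
#'   10-10^3 here, so the default is stringent).
#' @param window Trailing fraction of the time span used for the check.
#' @return A one-row tibble `target_label, terminal_distance, converged`;
#'   `target_label` is `NA` when no equilibrium qualifies (the distance
#'   reported is then to the nearest candidate).
#' @export
detect_convergence <- function(traj, equilibria = NULL, tol = 1e-3, window = 0.1) {
  if (is.null(equilibria)) {
    eq <- cbb_equilibria(as_cbb_params(attr(traj, "params")))
    equilibria <- dplyr::filter(eq, .data$biological_sense)
  }
  span <- diff(range(traj$time))
  if (window <= 0 || window > 1) stop("window must be a fraction in (0, 1]", call. = FALSE)
  t_from <- max(traj$time) - window * span
  tail <- dplyr::filter(traj, .data$time >= t_from)
  if (nrow(tail) < 2L) stop("trailing window contains too few points", call. = FALSE)
  dist <- vapply(
    seq_len(nrow(equilibria)),
    function(i) {
      max(sqrt((tail$A - equilibria$A[i])^2 +
        (tail$I - equilibria$I[i])^2 +
        (tail$H - equilibria$H[i])^2))
    },
    numeric(1)
  )
  best <- which.min(dist)
  tibble::tibble(
    target_label = if (dist[best] < tol) equilibria$label[best] else NA_character_,
    terminal_distance = dist[best],
    converged = dist[best] < tol
  )
}

#' Phase portraits on the invariant ant planes
#'
#' The planes `H = 0` (no ants) and `H = k` (ants at carrying capacity)
#' are invariant: trajectories starting on them stay on them. On `H = 0`
#' interior trajectories tend to the ant-free borer equilibrium when
#' `B0 > 1` (and to extinction when `B0 < 1`); on `H = k` they tend to the
#' coexistence equilibrium when `Psi0 > 1`.
#'
#' @param params A [cbb_params] object.
#' @param plane `"H0"` or `"Hk"`.
#' @param starts A data frame (or matrix) of initial states with columns
#'   `A, I`, and optionally `H`, which must then equal the plane level
#'   exactly (off-plane starts are an error).
#' @param t_end,rtol,atol,n_out Passed to [cbb_simulate].
#' @return A tibble with columns `start` (index), `time, A, I, H`.
#' @export
planar_portrait <- function(params, plane = c("H0", "Hk"), starts,
                            t_end = 5000, rtol = 1e-8, atol = 1e-10, n_out = 1001L) {
  params <- as_cbb_params(params)
  plane <- match.arg(plane)
  level <- if (plane == "H0") 0 else params$k
  starts <- as.data.frame(starts)
  if (!all(c("A", "I") %in% names(starts))) {
    stop("starts must have columns A and I", call. = FALSE)
  }
  if ("H" %in% names(starts) && any(starts$H != level)) {
    stop("starts must lie exactly on plane H = ", level, call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(starts)), function(i) {
    traj <- cbb_simulate(params, c(starts$A[i], starts$I[i], level),
      t_end = t_end, rtol = rtol, atol = atol, n_out = n_out
    )
    dplyr::mutate(tibble::as_tibble(traj), start = i, .before = 1)
  })
}
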