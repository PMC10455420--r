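#' Sampling ranges for synthetic parameter sets
#'
#' Default ranges for the synthetic parameter generator, centered on the
#' baseline illustrative values and wide enough to put the reproduction
#' thresholds on both sides of 1. Rate parameters spanning several
#' decades are drawn log-uniformly; `epsilon` and the capacities
#' uniformly. The ant capacity is drawn relative to `q` (a fraction in
#' `k_frac`), reflecting the premise that predatory ants are far fewer
#' than borers.
#'
#' @return A named list of `c(low, high)` ranges with elements
#'   `q`, `k_frac`, `r`, `alpha`, `delta`, `epsilon`, `theta`, `mu`,
#'   `phi`, `omega`.
#' @export
default_param_ranges <- function() {
  list(
    q = c(100, 5000),
    k_frac = c(1 / 50, 1 / 5),
    r = c(1e-3, 3),
    alpha = c(1e-3, 3),
    delta = c(1e-3, 3),
    epsilon = c(0.05, 1),
    theta = c(1e-3, 3),
    mu = c(1e-3, 3),
    phi = c(1e-3, 3),
    omega = c(1e-3, 3)
  )
}

# log-uniformly sampled parameters (the rest are uniform)
log_sampled <- c("r", "alpha", "delta", "theta", "mu", "phi", "omega")

#' Draw random valid parameter sets
#'
#' Seeded, reproducible draws of parameter sets satisfying all model
#' invariants. A master seed fans out to one substream per draw, so
#' increasing `n` extends the batch without reshuffling earlier draws.
#'
#' @param n Number of draws.
#' @param seed Integer master seed.
#' @param ranges Ranges as produced by [default_param_ranges].
#' @return A tibble of class `"cbb_param_batch"` with one row per draw
#'   and one column per parameter; convert row `i` to a parameter object
#'   with `as_cbb_params(batch[i, ])` implicitly by passing the row to
#'   any package function, or get a list via [param_list].
#' @examples
#' sample_params(3, seed = 1)
#' @export
sample_params <- function(n, seed = 1, ranges = default_param_ranges()) {
  stopifnot("n must be a positive integer" = n >= 1)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || rg[1] >= rg[2] || rg[1] <= 0) {
      stop("infeasible range for ", nm, " (need 0 < low < high)", call. = FALSE)
    }
  }
  rows <- purrr::map(seq_len(n), function(i) {
    set.seed(substream_seed(seed, i))
    draw <- function(nm) {
      rg <- ranges[[nm]]
      if (nm %in% log_sampled) {
        exp(stats::runif(1, log(rg[1]), log(rg[2])))
      } else {
        stats::runif(1, rg[1], rg[2])
      }
    }
    q <- draw("q")
    tibble::tibble(
      q = q,
      k = q * draw("k_frac"),
      r = draw("r"),
      alpha = draw("alpha"),
      delta = draw("delta"),
      epsilon = draw("epsilon"),
      theta = draw("theta"),
      mu = draw("mu"),
      phi = draw("phi"),
      omega = draw("omega")
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cbb_param_batch", class(out)), seed = seed)
}

#' @rdname sample_params
#' @param batch A `cbb_param_batch` tibble.
#' @return `param_list()` returns a list of [cbb_params] objects.
#' @export
param_list <- function(batch) {
  purrr::map(seq_len(nrow(batch)), function(i) as_cbb_params(as.list(batch[i, ])))
}

#' Draw random states inside the invariant region
#'
#' Uniform draws in the box
#' \eqn{[0, \omega q/\mu] \times [0, q] \times [0, k]}. With
#' `positive_H = TRUE` draws are restricted to `H > 0`, the open set
#' where the ant population invades and trajectories approach the
#' predicted attractor.
#'
#' @param params A [cbb_params] object.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param positive_H Restrict to strictly positive ant populations.
#' @return A tibble with columns `A`, `I`, `H`.
#' @export
sample_states_in_omega <- function(params, n, seed = 1, positive_H = FALSE) {
  params <- as_cbb_params(params)
  stopifnot("n must be a positive integer" = n >= 1)
  upper <- omega_region(params)$upper
  set.seed(substream_seed(seed, 0L))
  tibble::tibble(
    A = stats::runif(n, 0, upper[1]),
    I = stats::runif(n, 0, upper[2]),
    H = if (positive_H) {
      upper[3] * stats::runif(n)
    } else {
      stats::runif(n, 0, upper[3])
    }
  )
}

#' Parameters representative of each stability regime
#'
#' Returns the base parameter set with `mu` moved to a representative of
#' one of the five regimes of the classification: (1) coexistence,
#' `mu < mu_star`; (2) the exact collision `mu = mu_star`; (3) eradication
#' by combined control, `mu_star < mu < mu_double_star`; (4) the exact
#' collision `mu = mu_double_star`; (5) eradication without predation,
#' `mu > mu_double_star`. Cases 2 and 4 use the exact closed-form values.
#' Case 1 uses 0.03 (the baseline scenarios' smallest mortality) when
#' that is admissible, otherwise `mu_star / 2`.
#'
#' @param case Integer 1-5.
#' @param base A [cbb_params] object.
#' @return A [cbb_params] object with `mu` set for the regime.
#' @examples
#' cbb_Psi0(regime_params(2, cbb_baseline_params())) # exactly 1
#' @export
regime_params <- function(case, base) {
  base <- as_cbb_params(base)
  if (!case %in% 1:5) stop("case must be one of 1..5", call. = FALSE)
  ms <- cbb_mu_star(base)
  mds <- cbb_mu_double_star(base)
  mu <- switch(case,
    if (ms > 0.03) 0.03 else if (ms > 0) ms / 2 else stop("case 1 infeasible: mu_star <= 0", call. = FALSE),
    if (ms > 0) ms else stop("case 2 infeasible: mu_star <= 0", call. = FALSE),
    if (ms > 0) (ms + mds) / 2 else mds / 2,
    mds,
    2 * mds
  )
  p <- unclass(base)
  p$mu <- mu
  do.call(cbb_params, p)
}

# internal: deterministic substream seed below 2^31
substream_seed <- function(seed, i) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(i) * 9973) %% 2147483629)
}
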