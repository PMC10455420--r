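#' Model parameters for the borer-ant system
#'
#' Constructs and validates the ten-parameter set governing the
#' stage-structured borer-ant predator-prey model. All rates are per day;
#' populations are average counts (continuous, non-negative).
#'
#' @param q Carrying capacity of immature borers (individuals), `> 0`.
#' @param k Carrying capacity of the predatory ants (individuals), `> 0`.
#' @param r Intrinsic growth rate of the ants (1/day), `> 0`.
#' @param alpha Predation rate of ants on adult borers (1/(ant day)), `>= 0`.
#' @param delta Predation rate of ants on immature borers (1/(ant day)), `>= 0`.
#' @param epsilon Biomass conversion rate of predation into ant growth,
#'   dimensionless, in `(0, 1]`.
#' @param theta Natural death rate of immature borers (1/day), `> 0`.
#' @param mu Death rate of adult borers from factors other than predation
#'   (natural death, traps, insecticide; 1/day), `> 0`. `mu = 0` is rejected:
#'   adults always die of natural causes, and the adult bound of the
#'   invariant region, `omega * q / mu`, is undefined at zero.
#' @param phi Oviposition rate (eggs per adult per day), `> 0`.
#' @param omega Development rate from immature to adult stage (1/day), `> 0`.
#'
#' @return An object of class `"cbb_params"`: a named list of the ten
#'   validated parameters.
#' @examples
#' p <- cbb_params(
#'   q = 700, k = 35, r = 0.01, alpha = 0.01, delta = 0.01,
#'   epsilon = 0.2, theta = 0.23, mu = 0.03, phi = 2, omega = 0.17
#' )
#' p
#' @export
cbb_params <- function(q, k, r, alpha, delta, epsilon, theta, mu, phi, omega) {
  p <- list(
    q = q, k = k, r = r, alpha = alpha, delta = delta, epsilon = epsilon,
    theta = theta, mu = mu, phi = phi, omega = omega
  )
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    stop("all parameters must be finite numeric scalars; offending: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(
    "q must be > 0" = q > 0,
    "k must be > 0" = k > 0,
    "r must be > 0" = r > 0,
    "alpha must be >= 0" = alpha >= 0,
    "delta must be >= 0" = delta >= 0,
    "epsilon must be in (0, 1]" = epsilon > 0 && epsilon <= 1,
    "theta must be > 0" = theta > 0,
    "mu must be > 0" = mu > 0,
    "phi must be > 0" = phi > 0,
    "omega must be > 0" = omega > 0
  )
  structure(p, class = "cbb_params")
}

#' Baseline illustrative parameter set
#'
#' The parameter values used throughout the package's worked examples:
#' immature carrying capacity `q = 700`, ant carrying capacity `k = q/20`,
#' ant growth `r = 0.01`, predation rates `alpha = delta = 0.01`,
#' conversion `epsilon = 0.2`, immature death `theta = 0.23`, oviposition
#' `phi = 2` and maturation `omega = 0.17`. The adult death rate `mu` is
#' the management lever and must be supplied (it is the bifurcation
#' parameter of the analysis).
#'
#' @param mu Adult borer death rate from factors other than predation (1/day).
#' @return A [cbb_params] object.
#' @examples
#' cbb_baseline_params(mu = 0.03)
#' @export
cbb_baseline_params <- function(mu = 0.03) {
  cbb_params(
    q = 700, k = 700 / 20, r = 0.01, alpha = 0.01, delta = 0.01,
    epsilon = 0.2, theta = 0.23, mu = mu, phi = 2, omega = 0.17
  )
}

#' Read model parameters from a flat config file
#'
#' Accepts either JSON (an object with the ten parameter names as keys) or a
#' flat `key = value` file (one assignment per line, `#` comments allowed, as
#' in a flat TOML table). Keys must be exactly
#' `q, k, r, alpha, delta, epsilon, theta, mu, phi, omega`.
#'
#' @param path Path to the config file.
#' @return A validated [cbb_params] object.
#' @examples
#' cfg <- system.file("extdata", "baseline_params.json", package = "antborer")
#' read_cbb_params(cfg)
#' @export
read_cbb_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    lines <- trimws(sub("#.*$", "", txt))
    lines <- lines[nzchar(lines)]
    if (!all(grepl("=", lines, fixed = TRUE))) {
      stop("config must be JSON or flat 'key = value' lines", call. = FALSE)
    }
    keys <- trimws(sub("=.*$", "", lines))
    raw <- trimws(sub("^[^=]*=", "", lines))
    vals <- as.list(suppressWarnings(as.numeric(raw)))
    names(vals) <- keys
    if (anyNA(unlist(vals))) stop("non-numeric value in config", call. = FALSE)
  }
  expected <- c("q", "k", "r", "alpha", "delta", "epsilon", "theta", "mu", "phi", "omega")
  missing <- setdiff(expected, names(vals))
  extra <- setdiff(names(vals), expected)
  if (length(missing) > 0) stop("config missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(extra) > 0) stop("config has unknown keys: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(cbb_params, lapply(vals[expected], as.numeric))
}

#' @export
print.cbb_params <- function(x, ...) {
  cat("<cbb_params> borer-ant model parameters (rates per day)\n")
  cat(sprintf(
    "  q = %g, k = %g, r = %g, alpha = %g, delta = %g\n  epsilon = %g, theta = %g, mu = %g, phi = %g, omega = %g\n",
    x$q, x$k, x$r, x$alpha, x$delta, x$epsilon, x$theta, x$mu, x$phi, x$omega
  ))
  invisible(x)
}

#' Tidy a parameter set into a one-row tibble
#'
#' @param x A [cbb_params] object.
#' @param ... Unused.
#' @return A one-row tibble with one column per parameter.
#' @export
tidy.cbb_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

# internal: accept either a cbb_params or a bare named list/row and validate
as_cbb_params <- function(p) {
  if (inherits(p, "cbb_params")) {
    return(p)
  }
  p <- as.list(p)
  do.call(cbb_params, p[c(
    "q", "k", "r", "alpha", "delta", "epsilon",
    "theta", "mu", "phi", "omega"
  )])
}
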