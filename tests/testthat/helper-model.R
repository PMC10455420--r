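# shared fixtures: baseline parameters and a finite-difference Jacobian oracle

baseline <- function(mu = 0.03) cbb_baseline_params(mu = mu)

# central finite differences of the vector field, independent of cbb_jacobian
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    hj <- h * (1 + abs(state[j]))
    up <- dn <- state
    up[j] <- up[j] + hj
    dn[j] <- dn[j] - hj
    J[, j] <- (cbb_rhs(up, params) - cbb_rhs(dn, params)) / (2 * hj)
  }
  J
}

# coordinates of a labelled equilibrium as c(A, I, H)
eq_coords <- function(params, label) {
  eq <- cbb_equilibria(params)
  as.numeric(eq[eq$label == label, c("A", "I", "H")])
}
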