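test_that("closed-form eigenvalues at the origin match the planar trace/determinant oracle", {
  p <- baseline(0.03)
  # oracle: eigenvalues of the (A, I) block [[-mu, omega], [phi, -(omega+theta)]]
  # plus the decoupled ant eigenvalue r
  blk <- matrix(c(-0.03, 0.17, 2, -0.4), 2, byrow = TRUE)
  oracle <- sort(eigen(blk, only.values = TRUE)$values)
  got <- cbb_eigen_closed_form("E1", p)$value
  expect_equal(got[1], 0.01)
  expect_equal(sort(got[2:3]), oracle, tolerance = 1e-12)
  expect_equal(got, c(0.01, -0.82674, 0.39674), tolerance = 1e-4)
})

test_that("eigenvalue fixed points: -r at the ant-capacity equilibrium, zero modes at collisions", {
  for (mu in c(0.03, 0.2, 0.7)) {
    expect_equal(cbb_eigen_closed_form("E3", baseline(mu))$value[1], -0.01)
  }
  # E1 at mu = mu**: lambda2 = -(theta+mu+omega), lambda3 = 0
  p <- baseline(cbb_mu_double_star(baseline()))
  lam <- cbb_eigen_closed_form("E1", p)$value
  expect_equal(lam[2], -(0.23 + 0.85 + 0.17), tolerance = 1e-12)
  expect_equal(lam[3], 0, tolerance = 1e-12)
  # E3 at mu = mu*: one vanishing eigenvalue
  pstar <- baseline(cbb_mu_star(baseline()))
  lam3 <- cbb_eigen_numeric("E3", pstar)$value
  expect_lt(min(abs(lam3)), 1e-8)
})

test_that("closed-form and numeric eigenvalues agree at every admissible equilibrium", {
  for (mu in c(0.03, 0.5, 0.85)) {
    p <- baseline(mu)
    labels <- c("E1", "E3", "E1_reduced")
    if (cbb_B0(p) >= 1) labels <- c(labels, "E2", "E2_reduced")
    if (cbb_Psi0(p) >= 1) labels <- c(labels, "E4")
    for (lab in labels) {
      expect_equal(
        cbb_eigen_numeric(lab, p)$value,
        cbb_eigen_closed_form(lab, p)$value,
        tolerance = 1e-8
      )
    }
  }
  expect_error(cbb_eigen_closed_form("E4", baseline(0.5)), "biological sense")
  expect_error(cbb_eigen_closed_form("E2", baseline(1.5)), "biological sense")
})

test_that("eigenvalues are real and match closed forms across random parameter sets", {
  batch <- param_list(sample_params(200, seed = 17))
  for (p in batch) {
    eq <- cbb_equilibria(p)
    labels <- eq$label[eq$biological_sense]
    for (lab in labels) {
      co <- eq_coords(p, lab)
      ev <- eigen(cbb_jacobian(pmax(co, 0), p), only.values = TRUE)$values
      expect_lt(max(abs(Im(ev))), 1e-10)
      expect_equal(
        cbb_eigen_numeric(lab, p)$value,
        cbb_eigen_closed_form(lab, p)$value,
        tolerance = 1e-8
      )
    }
  }
})

test_that("classification reproduces the five mu regimes", {
  # coexistence: E4 attracting, everything else a saddle
  cl <- cbb_classify(baseline(0.03))
  expect_equal(cl$case[1], 1L)
  expect_equal(cl$verdict, c(
    "unstable_saddle", "unstable_saddle", "unstable_saddle",
    "locally_asymptotically_stable"
  ))
  # exact collision E4 = E3
  cl2 <- cbb_classify(baseline(cbb_mu_star(baseline())))
  expect_equal(cl2$case[1], 2L)
  expect_equal(cl2$verdict[3:4], c("nonhyperbolic", "nonhyperbolic"))
  expect_equal(cl2$collided_with[3:4], c("E4", "E3"))
  expect_true(all(cl2$stable[3:4]))
  # eradication with predation: E3 attracting, E4 gone
  cl3 <- cbb_classify(baseline(0.5))
  expect_equal(cl3$case[1], 3L)
  expect_equal(cl3$verdict[3], "locally_asymptotically_stable")
  expect_equal(cl3$verdict[4], "no_biological_sense")
  # exact collision E2 = E1, E1 still unstable (Lyapunov)
  cl4 <- cbb_classify(baseline(0.85))
  expect_equal(cl4$case[1], 4L)
  expect_equal(cl4$collided_with[1:2], c("E2", "E1"))
  expect_equal(cl4$verdict[1], "nonhyperbolic")
  expect_false(cl4$stable[1])
  expect_match(cl4$governing_condition[1], "Lyapunov")
  expect_equal(cl4$verdict[3], "locally_asymptotically_stable")
  # eradication without predation
  cl5 <- cbb_classify(baseline(1.5))
  expect_equal(cl5$case[1], 5L)
  expect_equal(cl5$verdict[2], "no_biological_sense")
  expect_equal(cl5$verdict[3], "locally_asymptotically_stable")
})

test_that("regime classification equals the raw eigenvalue-sign verdict in hyperbolic cases", {
  batch <- param_list(sample_params(60, seed = 29))
  for (p in batch) {
    cl <- cbb_classify(p)
    if (cl$case[1] %in% c(2L, 4L)) next
    for (i in seq_len(nrow(cl))) {
      if (!cl$biological_sense[i]) next
      lam <- cbb_eigen_numeric(cl$label[i], p)$value
      if (min(abs(lam)) < 1e-10 * (1 + max(abs(lam)))) next # grazing a collision
      expect_equal(all(lam < 0), cl$stable[i],
        info = paste(cl$label[i], "case", cl$case[1])
      )
    }
  }
})

test_that("E3 and E4 exchange stability across mu_star", {
  ms <- cbb_mu_star(baseline())
  below <- cbb_classify(baseline(ms - 1e-3))
  above <- cbb_classify(baseline(ms + 1e-3))
  expect_equal(below$verdict[below$label == "E4"], "locally_asymptotically_stable")
  expect_equal(below$verdict[below$label == "E3"], "unstable_saddle")
  expect_equal(above$verdict[above$label == "E3"], "locally_asymptotically_stable")
  expect_false(above$biological_sense[above$label == "E4"])
})
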