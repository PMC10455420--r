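test_that("the ant planes H = 0 and H = k are invariant under integration", {
  p <- baseline(0.03)
  tr0 <- cbb_simulate(p, c(100, 50, 0), t_end = 1000)
  expect_lt(max(abs(tr0$H)), 1e-10)
  trk <- cbb_simulate(p, c(100, 50, 35), t_end = 1000)
  expect_lt(max(abs(trk$H - 35)), 1e-10 * 35)
})

test_that("trajectories reach the attractor predicted for their regime", {
  p <- baseline(0.03)
  tr <- cbb_simulate(p, c(10, 20, 1), t_end = 5000)
  cv <- detect_convergence(tr)
  expect_true(cv$converged)
  expect_equal(cv$target_label, "E4")
  expect_equal(
    as.numeric(tr[nrow(tr), c("A", "I", "H")]),
    eq_coords(p, "E4"),
    tolerance = 1e-3
  )
  p5 <- baseline(0.5)
  tr5 <- cbb_simulate(p5, c(5, 1, 32), t_end = 5000)
  expect_equal(as.numeric(tr5[nrow(tr5), c("A", "I", "H")]), c(0, 0, 35), tolerance = 1e-3)
  expect_equal(detect_convergence(tr5)$target_label, "E3")
})

test_that("the borer-persistence equilibrium repels trajectories once ants invade", {
  # started almost on E2 with one ant, the flow leaves E2 and reaches E4
  p <- baseline(0.03)
  tr <- cbb_simulate(p, c(3800, 700, 1), t_end = 5000)
  expect_no_warning(cbb_simulate(p, c(3800, 700, 1), t_end = 1)) # inside the region
  cv <- detect_convergence(tr)
  expect_equal(cv$target_label, "E4")
})

test_that("at the exact bifurcation value trajectories settle on the collided equilibrium", {
  p <- regime_params(2, baseline())
  tr <- cbb_simulate(p, c(10, 20, 1), t_end = 5e6)
  cv <- detect_convergence(tr)
  expect_true(cv$converged)
  expect_equal(cv$target_label, "E3")
})

test_that("a constant trajectory at an equilibrium is detected with zero distance", {
  p <- baseline(0.5)
  tr <- cbb_simulate(p, c(0, 0, 35), t_end = 100)
  cv <- detect_convergence(tr)
  expect_equal(cv$target_label, "E3")
  expect_lt(cv$terminal_distance, 1e-12)
  expect_error(detect_convergence(tr, window = 2), "window")
})

test_that("trajectories starting in the invariant region never leave it", {
  batch <- param_list(sample_params(30, seed = 101))
  for (i in seq_along(batch)) {
    p <- batch[[i]]
    y0 <- as.numeric(sample_states_in_omega(p, 1, seed = i)[1, ])
    # solver error must sit well below the invariance slack
    tr <- cbb_simulate(p, y0, t_end = 200, n_out = 401, rtol = 1e-10, atol = 1e-12)
    chk <- check_invariance(tr, slack = 1e-6)
    expect_true(chk$ok)
  }
})

test_that("boundary faces push the flow into the region", {
  p <- baseline(0.03)
  # on the immature-capacity face the immature population must decrease
  expect_lt(cbb_rhs(c(100, 700, 10), p)[["dI"]], 0)
  tr <- cbb_simulate(p, c(100, 700, 10), t_end = 50, n_out = 201)
  expect_true(all(tr$I[-1] < 700))
  # on the adult bound the adult population cannot increase
  amax <- a_max(p)
  expect_lte(cbb_rhs(c(amax, 700, 0), p)[["dA"]], 0)
  expect_lt(cbb_rhs(c(amax, 350, 10), p)[["dA"]], 0)
  tr2 <- cbb_simulate(p, c(amax, 350, 10), t_end = 50, n_out = 201)
  expect_true(all(tr2$A[-1] <= amax))
})

test_that("solver tolerances are converged: tightening them barely moves the terminal state", {
  p <- baseline(0.5)
  t1 <- cbb_simulate(p, c(5, 1, 32), t_end = 2000)
  t2 <- cbb_simulate(p, c(5, 1, 32), t_end = 2000, rtol = 1e-9, atol = 1e-11)
  expect_lt(
    max(abs(as.numeric(t1[nrow(t1), -1]) - as.numeric(t2[nrow(t2), -1]))),
    1e-6
  )
})

test_that("planar portraits stay on their plane and reach the planar attractors", {
  p <- baseline(0.03)
  starts <- data.frame(A = c(50, 500), I = c(10, 300))
  pk <- planar_portrait(p, "Hk", starts, t_end = 5000)
  expect_true(all(abs(pk$H - 35) < 1e-8))
  ends <- dplyr::slice_tail(dplyr::group_by(pk, start), n = 1)
  expect_true(all(abs(ends$A - 50.66) < 0.01))
  expect_true(all(abs(ends$I - 113.24) < 0.01))
  p0 <- planar_portrait(p, "H0", starts, t_end = 5000)
  expect_true(all(p0$H == 0))
  e2 <- eq_coords(p, "E2")
  ends0 <- dplyr::slice_tail(dplyr::group_by(p0, start), n = 1)
  expect_true(all(abs(ends0$A - e2[1]) < 1e-2))
  # above mu** the planar flow collapses to the origin
  pe <- planar_portrait(baseline(1.2), "H0", data.frame(A = 50, I = 100), t_end = 5000)
  expect_equal(as.numeric(pe[nrow(pe), c("A", "I")]), c(0, 0), tolerance = 1e-6)
  expect_error(
    planar_portrait(p, "H0", data.frame(A = 1, I = 1, H = 5)),
    "exactly on plane"
  )
})
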