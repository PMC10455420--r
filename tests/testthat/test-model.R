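test_that("vector field vanishes at the origin and on the ant-capacity plane", {
  p <- baseline()
  expect_equal(unname(cbb_rhs(c(0, 0, 0), p)), c(0, 0, 0))
  # dH = 0 anywhere on H = k (the plane is invariant)
  for (s in list(c(10, 20, 35), c(0, 700, 35), c(3000, 1, 35))) {
    expect_equal(cbb_rhs(s, p)[["dH"]], 0)
  }
})

test_that("boundary derivative on the immature-capacity face matches -(omega+theta)q", {
  p <- baseline()
  d <- cbb_rhs(c(0, 700, 0), p)
  expect_equal(d[["dI"]], -(0.17 + 0.23) * 700) # -280
  expect_lt(d[["dI"]], 0)
})

test_that("vector field rejects invalid input", {
  p <- baseline()
  expect_error(cbb_rhs(c(1, 2), p), "state")
  expect_error(cbb_rhs(c(1, NA, 3), p), "state")
  expect_error(cbb_rhs(c(-1, 2, 3), p), "non-negative")
  expect_error(cbb_params(
    q = 700, k = 35, r = 0.01, alpha = 0.01, delta = 0.01,
    epsilon = 0.2, theta = 0.23, mu = 0, phi = 2, omega = 0.17
  ), "mu")
  expect_error(cbb_params(
    q = 700, k = 35, r = 0.01, alpha = 0.01, delta = 0.01,
    epsilon = 1.5, theta = 0.23, mu = 0.03, phi = 2, omega = 0.17
  ), "epsilon")
})

test_that("analytic Jacobian matches closed forms at corner equilibria", {
  p <- baseline()
  J0 <- cbb_jacobian(c(0, 0, 0), p)
  expect_equal(matrix(J0, 3), matrix(c(
    -0.03, 0.17, 0,
    2, -(0.17 + 0.23), 0,
    0, 0, 0.01
  ), 3, byrow = TRUE))
  Jk <- cbb_jacobian(c(0, 0, 35), p)
  expect_equal(Jk[3, 3], -0.01) # -(r) at H = k
  expect_equal(unname(Jk[3, 1:2]), c(0, 0))
})

test_that("analytic Jacobian agrees with finite differences on random interior states", {
  p <- baseline()
  set.seed(42)
  for (i in 1:100) {
    s <- c(runif(1, 1, 3000), runif(1, 1, 690), runif(1, 0.5, 34))
    expect_lt(max(abs(cbb_jacobian(s, p) - fd_jacobian(s, p))), 1e-6)
  }
  # and the mass-action entries are as expected at a spot-checked state
  s <- c(100, 200, 10)
  J <- cbb_jacobian(s, p)
  expect_equal(J[1, 3], -p$alpha * 100)
  expect_equal(J[2, 3], -p$delta * 200)
})

test_that("planar system is the exact H = 0 restriction of the full field", {
  p <- baseline()
  expect_equal(unname(cbb_reduced_rhs(c(0, 0), p)), c(0, 0))
  expect_equal(cbb_reduced_rhs(c(10, 20), p)[["dA"]], 0.17 * 20 - 0.03 * 10) # 3.1
  set.seed(7)
  for (i in 1:20) {
    s <- c(runif(1, 0, 3000), runif(1, 0, 700))
    expect_identical(
      unname(cbb_reduced_rhs(s, p)),
      unname(cbb_rhs(c(s, 0), p)[1:2])
    )
  }
})

test_that("adult bound of the invariant region is omega*q/mu and scales linearly in q", {
  p <- baseline()
  expect_equal(a_max(p), 0.17 * 700 / 0.03, tolerance = 1e-8) # 3966.67
  p1 <- cbb_params(
    q = 1, k = 0.5, r = 0.1, alpha = 0, delta = 0, epsilon = 0.5,
    theta = 0.1, mu = 0.17, phi = 1, omega = 0.17
  )
  expect_equal(a_max(p1), 1)
  p2 <- p1
  expect_equal(a_max(cbb_params(
    q = 2, k = 0.5, r = 0.1, alpha = 0, delta = 0, epsilon = 0.5,
    theta = 0.1, mu = 0.17, phi = 1, omega = 0.17
  )), 2 * a_max(p1))
  expect_error(a_max(p, mu = 0), "positive")
  expect_error(a_max(p, mu = -1), "positive")
})

test_that("vector field vanishes at every biologically admissible closed-form equilibrium", {
  for (mu in c(0.03, 0.1, 0.5, 0.85, 1.5)) {
    p <- baseline(mu)
    eq <- cbb_equilibria(p)
    eq <- eq[eq$biological_sense, ]
    for (i in seq_len(nrow(eq))) {
      co <- as.numeric(eq[i, c("A", "I", "H")])
      expect_lt(
        max(abs(cbb_rhs(pmax(co, 0), p))),
        1e-9 * (1 + max(abs(co)))
      )
    }
  }
})

test_that("config reader accepts JSON and flat key = value files and validates keys", {
  js <- system.file("extdata", "baseline_params.json", package = "antborer")
  fl <- system.file("extdata", "baseline_params.toml", package = "antborer")
  pj <- read_cbb_params(js)
  pf <- read_cbb_params(fl)
  expect_s3_class(pj, "cbb_params")
  expect_identical(unclass(pj), unclass(pf))
  expect_equal(pj$k, pj$q / 20)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"q": 700}', bad)
  expect_error(read_cbb_params(bad), "missing keys")
})
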