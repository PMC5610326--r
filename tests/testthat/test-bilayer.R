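# Horizontal bilayer region: decay exponents, junction solve, energy.

env0 <- environment_parameters()
ref <- get_lipid("reference")

test_that("characteristic exponents form a decaying conjugate pair", {
  q <- characteristic_roots(ref)
  expect_length(q, 2)
  expect_true(all(Re(q) > 0))
  expect_gt(abs(Im(q[1])), 1e-3)          # damped oscillatory, not pure decay
  expect_equal(q[2], Conj(q[1]), tolerance = 1e-12)
  # the two roots are the two square-root branches of the same quadratic
  cf <- poredge:::.bilayer_char_coefs(ref, 0)
  for (qq in q)
    expect_lt(Mod(cf$a2 * qq^4 + cf$a1 * qq^2 + cf$a0), 1e-10)
  # all registered lipids stay in the damped-oscillatory regime at sigma0 = 0
  for (nm in list_lipids())
    expect_true(all(Re(characteristic_roots(get_lipid(nm))) > 0))
})

test_that("undeformed boundary data give identically zero deformation", {
  sol <- solve_bilayer(ref, env0, R0 = 2, Z0 = ref$h, n0 = 0)
  expect_equal(bilayer_energy(sol), 0, tolerance = 1e-12)
  f <- bilayer_fields(sol, c(2, 5, 12))
  expect_equal(f$n, rep(0, 3), tolerance = 1e-12)
  expect_equal(f$H, rep(ref$h, 3), tolerance = 1e-12)
})

test_that("junction conditions are met and fields decay at large distance", {
  sol <- solve_bilayer(ref, env0, R0 = 2, Z0 = 1.8, n0 = -0.3)
  f0 <- bilayer_fields(sol, 2)
  expect_equal(f0$n, -0.3, tolerance = 1e-9)
  expect_equal(f0$H, 1.8, tolerance = 1e-9)
  # decay length 1/Re(q) ~ 3.8 nm: fields are below 1e-6 some 15 decay
  # lengths out (and already below 1e-3 at R0 + 20)
  expect_lt(abs(bilayer_fields(sol, 22)$n), 1e-3)
  expect_lt(abs(bilayer_fields(sol, 62)$n), 1e-6)
  expect_lt(abs(bilayer_fields(sol, 62)$H - ref$h), 1e-6)
  # oscillatory decay: envelope of |n| at successive local extrema shrinks
  rho <- seq(2, 30, by = 0.01)
  n <- bilayer_fields(sol, rho)$n
  ex <- which(diff(sign(diff(n))) != 0) + 1
  expect_true(all(diff(abs(n[ex])) < 0))
})

test_that("boundary-flux energy equals quadrature and is a PSD form at J0 = 0", {
  sol <- solve_bilayer(ref, env0, R0 = 2, Z0 = 1.8, n0 = -0.3)
  Wb <- bilayer_energy(sol)
  Wq <- bilayer_energy(sol, method = "quadrature")
  expect_equal(Wb, Wq$total, tolerance = 1e-8)
  expect_equal(Wq$splay + Wq$tilt + Wq$stretch + Wq$tension, Wq$total,
               tolerance = 1e-10)
  expect_gt(Wq$tilt, 0)
  # quadratic form in (n0, Z0 - h): positive definite at J0 = 0, sigma0 = 0
  A <- poredge:::.bilayer_quad(ref, env0, 2.5)$A
  expect_true(all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_true(all(bilayer_energy(solve_bilayer(ref, env0, 3, 1.5, 0.4)) > 0))
})

test_that("analytic solution matches the discretized-functional minimizer", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  cases <- data.frame(R0 = runif(5, 1.5, 6), Z0 = runif(5, 1.2, 2.6),
                      n0 = runif(5, -0.45, 0.45))
  for (k in seq_len(nrow(cases))) {
    sol <- solve_bilayer(ref, env0, cases$R0[k], cases$Z0[k], cases$n0[k])
    fd <- fd_bilayer_oracle(ref, env0, cases$R0[k], cases$Z0[k], cases$n0[k])
    expect_equal(bilayer_energy(sol), fd$W, tolerance = 0.01)
  }
  # spontaneous curvature case (DOPC) and pointwise field agreement
  dopc <- get_lipid("DOPC")
  sol <- solve_bilayer(dopc, env0, 2, 1.3, -0.25)
  fd <- fd_bilayer_oracle(dopc, env0, 2, 1.3, -0.25)
  expect_equal(bilayer_energy(sol), fd$W, tolerance = 0.01)
  idx <- seq(1, 800, by = 80)
  an <- bilayer_fields(sol, fd$rho[idx])
  expect_lt(max(abs(an$n - fd$n[idx])), 0.01 * max(abs(fd$n)))
})
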