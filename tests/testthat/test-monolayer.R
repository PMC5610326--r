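# Vertical (edge-lining) monolayer region.

env0 <- environment_parameters()
ref <- get_lipid("reference")

test_that("equilibrium cylinder obeys local incompressibility", {
  expect_equal(equilibrium_cylinder(ref, 2), 3)
  expect_equal(equilibrium_cylinder(get_lipid("DOPC"), 1.45), 2.175)
  # flat-monolayer limit: M_v - R_v -> h
  expect_equal(equilibrium_cylinder(ref, 1e6) - 1e6, ref$h, tolerance = 1e-5)
  expect_error(equilibrium_cylinder(ref, 0.9), "h/2")
})

test_that("the literal expansion reproduces the known particular constant of m", {
  # m_p = (2 Rv^2 + h^2)(l^2 - 2 sigma Rv^2) / (4 Rv l^2), sigma = sigma0/K_t
  for (Rv in c(1, 2, 3.5)) for (s0mN in c(0, 2)) {
    envs <- environment_parameters(sigma0_mN_per_m = s0mN)
    ctx <- poredge:::.monolayer_context(ref, envs, Rv, radial_force = "literal")
    sig <- envs$sigma0 / ref$K_t
    m_exp <- (2 * Rv^2 + ref$h^2) * (ref$l2 - 2 * sig * Rv^2) / (4 * Rv * ref$l2)
    expect_equal(ctx$bas$y_p[2], m_exp, tolerance = 1e-9)
    expect_lt(abs(ctx$bas$y_p[1]), 1e-9)   # no particular term in v
    expect_lt(abs(ctx$bas$y_p[3]), 1e-9)   # nor in beta
  }
})

test_that("hand-derived quadratic expansion matches a numeric Taylor expansion", {
  for (Rv in c(1, 2.5)) {
    qf <- poredge:::.monolayer_quadform(ref, env0, Rv, radial_force = "literal")
    nq <- wall_numeric_quadform(ref, env0, Rv)
    expect_lt(max(abs(qf$Q - nq$Q)), 1e-5 * max(abs(nq$Q)))
    expect_lt(max(abs(qf$L - nq$L)), 1e-5 * max(abs(nq$L)))
    expect_equal(qf$G0, nq$G0, tolerance = 1e-12)
  }
})

test_that("lateral stretch vanishes identically in the solved wall", {
  # beta = 0 must emerge from the Euler-Lagrange solve, not be imposed
  ctx <- poredge:::.monolayer_context(ref, env0, 1.2)
  for (g in ctx$bas$gens) expect_lt(abs(g$phi[3]), 1e-8)
  geom <- pore_geometry(r = 1.2, L = 0, R0 = 2.4, Z0 = 1.6)
  sol <- solve_monolayer(ref, env0, geom, "hydrophilic", junction_director = -0.9)
  f <- monolayer_fields(sol, seq(0, 1.6, length.out = 30))
  expect_lt(max(abs(f$beta)), 1e-8)
})

test_that("solved fields satisfy the eliminated incompressibility relation", {
  geom <- pore_geometry(r = 1, L = 0, R0 = 2.2, Z0 = 1.6)
  sol <- solve_monolayer(ref, env0, geom, "hydrophilic", junction_director = -0.9)
  z <- seq(0.05, 1.55, length.out = 40)
  f <- monolayer_fields(sol, z)
  d <- 1e-6
  vp <- (monolayer_fields(sol, z + d)$v - monolayer_fields(sol, z - d)$v) / (2 * d)
  a <- sol$R_v^2 / (2 * sol$R_v^2 + ref$h^2)
  u_inc <- a * (2 * f$m + 2 * ref$h * f$beta + ref$h^2 * vp)
  expect_lt(max(abs(f$u - u_inc)), 1e-6)
  expect_equal(f$R, sol$R_v + f$u, tolerance = 1e-12)
  expect_equal(sol$M_v - sol$R_v, ref$h - ref$h^2 / (2 * sol$R_v), tolerance = 1e-12)
  # boundary conditions
  ends <- monolayer_fields(sol, c(0, 1.6))
  expect_equal(ends$v, c(0, -0.9), tolerance = 1e-9)
  expect_equal(ends$R, c(1, 2.2), tolerance = 1e-9)
})

test_that("wall solve matches the discretized-functional oracle", {
  skip_if_not_installed("Matrix")
  # hydrophobic-mode wall: fully pinned boundary data on [L, Z0]
  cases <- list(list(r = 0.675, L = 1.25, R0 = 1.9, Z0 = 1.8, vj = -0.9),
                list(r = 1.0, L = 0.8, R0 = 2.1, Z0 = 1.9, vj = -1.0),
                list(r = 1.0, L = 0, R0 = 2.2, Z0 = 1.6, vj = -0.9))
  for (cs in cases) {
    geom <- pore_geometry(cs$r, cs$L, cs$R0, cs$Z0)
    mode <- if (cs$L > 0) "hydrophobic" else "hydrophilic"
    sol <- solve_monolayer(ref, env0, geom, mode, junction_director = cs$vj)
    W <- monolayer_energy(sol)
    v_lo <- if (cs$L > 0) poredge:::.belt_rim_director(ref$h, cs$L) else 0
    fd <- fd_wall_oracle(ref, env0, R_v = cs$r, z_lo = cs$L, Z0 = cs$Z0,
                         v_lo = v_lo, u_lo = 0, v_hi = cs$vj, u_hi = cs$R0 - cs$r)
    expect_equal(W, fd$W, tolerance = 0.01)
  }
})

test_that("hydrophobic energetics join the hydrophilic branch as L -> 0", {
  gphilic <- pore_geometry(1, 0, 2.2, 1.6)
  gphob <- pore_geometry(1, 1e-3, 2.2, 1.6)
  Wp <- monolayer_energy(solve_monolayer(ref, env0, gphilic, "hydrophilic", -0.9))
  Wb <- monolayer_energy(solve_monolayer(ref, env0, gphob, "hydrophobic", -0.9))
  expect_lt(abs(Wb - Wp), 0.1)
})

test_that("an unconstrained-deviation wall reduces to the bare bent cylinder", {
  # with all deviation boundary data zero the harmonic wall stays at the
  # reference cylinder and the energy is the bare splay of bending
  r <- 30
  Z0 <- 1.5
  geom <- pore_geometry(r, 0, r, Z0)
  sol <- solve_monolayer(ref, env0, geom, "hydrophilic", junction_director = 0)
  W <- monolayer_energy(sol)
  W_bare <- 2 * Z0 * 2 * pi * r * (ref$B / 2) * (1 / r + ref$J0)^2
  expect_equal(W, W_bare, tolerance = 1e-6)
  f <- monolayer_fields(sol, seq(0, Z0, length.out = 11))
  expect_lt(max(abs(f$v)), 1e-9)
  expect_lt(max(abs(f$u)), 1e-9)
})
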