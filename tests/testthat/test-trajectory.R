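# Trajectory assembly, landscape features, classical relations, closure rate.

env0 <- environment_parameters()
ref <- get_lipid("reference")

test_that("belt-height scan finds the two-minimum structure near the transition", {
  sc <- scan_belt_height(ref, env0, r = 0.675)
  expect_false(is.null(sc$belt_minimum))
  # near-degenerate minima at 2L = 0 and 2L ~ 2.5 nm, a ~kBT-scale barrier
  expect_lt(abs(sc$belt_minimum$W - sc$W_philic), 3)
  expect_gt(2 * sc$belt_minimum$L, 1.8)
  expect_lt(2 * sc$belt_minimum$L, 2.9)
  expect_gt(sc$barrier, 0)
  expect_lt(sc$barrier, 4)
  # far above the transition the belt state disappears
  sc3 <- scan_belt_height(ref, env0, r = 3,
                          L_grid = seq(0.2, 1.9, by = 0.28))
  expect_true(is.null(sc3$belt_minimum) ||
                sc3$belt_minimum$W > sc3$W_philic + 5)
})

test_that("defect-branch energy is approximately quadratic at small radius", {
  rs <- c(0.1, 0.2, 0.3, 0.4)
  W <- vapply(rs, function(r) {
    sc <- scan_belt_height(ref, env0, r, L_grid = c(1.5, 1.7, 1.8, 1.9))
    sc$belt_minimum$W
  }, numeric(1))
  fit <- lm(W ~ I(rs^2))
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_true(all(diff(W) > 0))
})

test_that("pore energy grows linearly at large radius and gamma saturates", {
  rs <- c(20, 30, 40, 50)
  W <- vapply(rs, function(r)
    optimize_junction(ref, env0, r, 0, "hydrophilic")$W, numeric(1))
  fit <- lm(W ~ rs)
  expect_gt(summary(fit)$r.squared, 0.999)
  gam <- line_tension_to_pN(W / (2 * pi * rs))
  expect_true(all(diff(gam) > 0))          # approaching the asymptote from below
  expect_lt(gam[4] - gam[3], 0.25)         # and saturating
  # slope-based and point-based asymptote estimates agree to ~10%
  g_slope <- line_tension_to_pN(coef(fit)[[2]] / (2 * pi))
  expect_lt(abs(g_slope - gam[4]) / gam[4], 0.12)
})

test_that("equal B/h implies equal asymptotic line tension at zero curvature", {
  g30 <- vapply(c("reference", "model-B12-h3", "model-B5.3-h1.3"), function(nm) {
    lp <- get_lipid(nm)
    W <- optimize_junction(lp, env0, 30, 0, "hydrophilic")$W
    line_tension_to_pN(W / (2 * pi * 30))
  }, numeric(1))
  expect_lt(diff(range(g30)) / mean(g30), 0.05)
  # scaling: raising B by 1.5x raises the asymptote by roughly the same factor
  gB <- line_tension_to_pN(optimize_junction(get_lipid("model-B12"), env0, 30,
                                             0, "hydrophilic")$W / (2 * pi * 30))
  expect_gt(gB / g30[["reference"]], 1.3)
  expect_lt(gB / g30[["reference"]], 1.7)
})

test_that("the transition-region energy rises with spontaneous curvature", {
  Wt <- vapply(c("model-J0-0.1", "reference", "model-J0+0.1"), function(nm)
    optimize_junction(get_lipid(nm), env0, 0.7, 0, "hydrophilic")$W, numeric(1))
  expect_true(all(diff(Wt) > 0))
})

test_that("classical thin-film relations evaluate as documented", {
  expect_equal(critical_radius(11, 7), 11 / 7, tolerance = 1e-12)
  expect_equal(critical_radius(11, 7), 1.6, tolerance = 0.05)
  expect_equal(critical_radius(20, 10), 2)
  expect_warning(rs <- critical_radius(5, 0), "infinite")
  expect_identical(rs, Inf)
  r <- c(0.5, 1, 2, 4)
  E0 <- classical_energy(r, gamma_pN = 10, sigma0_mN_per_m = 0)
  expect_equal(E0, 2 * pi * r * line_tension_from_pN(10), tolerance = 1e-12)
  expect_lt(classical_energy(2, 10, 5), classical_energy(2, 10, 0))
})

test_that("closure rate reduces to the constant-line-tension limit", {
  rate <- closure_rate(function(r) rep(12, length(r)), eta = 1, h = 2)
  # dr/dt = -gamma/(4 eta h): 12 pN/(8 Pa s nm) = 1.5e-3 m/s = 1.5e-3 nm/ns
  expect_equal(rate(1), -12 / 8 * 1e-3, tolerance = 1e-6)
  expect_equal(rate(5), rate(1), tolerance = 1e-9)
  # gamma(r) = 4 V h eta + C/r closes at constant speed V
  gfun <- function(r) 4 * 5 * 2 * 1 + 3 / r   # V = 5e-3 nm/ns, C = 3 pN nm
  rate2 <- closure_rate(gfun, eta = 1, h = 2)
  expect_equal(rate2(c(0.5, 1, 2, 8)), rep(-5e-3, 4), tolerance = 1e-6)
  # spline route agrees with the functional route on a sampled curve
  rr <- seq(0.5, 8, by = 0.25)
  rate3 <- closure_rate(data.frame(r = rr, gamma_pN = gfun(rr)), eta = 1, h = 2)
  expect_equal(rate3(c(1, 2, 5)), rate2(c(1, 2, 5)), tolerance = 0.01)
})

test_that("line-tension curve carries the landscape features", {
  rg <- c(1, 1.5, 2, 3, 4, 6, 9, 14, 20)
  traj <- optimal_trajectory(ref, env0, r_grid = rg, hydrophobic = FALSE)
  lt <- line_tension_curve(traj)
  expect_equal(lt$gamma_pN,
               line_tension_to_pN(traj$points$W / (2 * pi * traj$points$r)),
               tolerance = 1e-12)
  expect_false(is.null(attr(lt, "gamma0_pN")))
  expect_lt(attr(lt, "gamma_min_pN"), attr(lt, "gamma0_pN"))
})
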