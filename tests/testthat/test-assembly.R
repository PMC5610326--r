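# Conjugation of the regions and junction-circle optimization.

env0 <- environment_parameters()
ref <- get_lipid("reference")

test_that("energy breakdown is conserved across regions and components", {
  opt <- optimize_junction(ref, env0, r = 2, L = 0, mode = "hydrophilic",
                           breakdown = TRUE)
  bd <- opt$breakdown
  expect_equal(bd$W_total, bd$W_b + bd$W_m + bd$W_h, tolerance = 1e-9)
  expect_equal(bd$splay + bd$tilt + bd$stretch + bd$tension + bd$W_h,
               bd$W_total, tolerance = 1e-6)
  # hydrophobic state: belt term enters the sum
  optb <- optimize_junction(ref, env0, r = 0.675, L = 1.25,
                            mode = "hydrophobic", breakdown = TRUE)
  bdb <- optb$breakdown
  expect_gt(bdb$W_h, 0)
  expect_equal(bdb$W_total, bdb$W_b + bdb$W_m + bdb$W_h, tolerance = 1e-9)
  expect_equal(bdb$splay + bdb$tilt + bdb$stretch + bdb$tension + bdb$W_h,
               bdb$W_total, tolerance = 1e-6)
})

test_that("gradient descent meets its stopping rule and is init-independent", {
  o1 <- optimize_junction(ref, env0, r = 1, L = 0, mode = "hydrophilic")
  expect_true(o1$converged)
  expect_lt(o1$grad_norm, 1e-7)
  # restarting at the optimum returns the same point with no extra descent
  o2 <- optimize_junction(ref, env0, r = 1, L = 0, mode = "hydrophilic",
                          init = c(o1$geometry$R0, o1$geometry$Z0))
  expect_equal(o2$W, o1$W, tolerance = 1e-10)
  expect_lt(abs(o2$geometry$R0 - o1$geometry$R0), 1e-4)
  # a deliberately different start converges to the same optimum
  o3 <- optimize_junction(ref, env0, r = 1, L = 0, mode = "hydrophilic",
                          init = c(3.4, 1.9))
  expect_equal(o3$W, o1$W, tolerance = 1e-6)
})

test_that("the optimum is a genuine local minimum of the junction energy", {
  o <- optimize_junction(ref, env0, r = 1, L = 0, mode = "hydrophilic")
  ectx <- poredge:::.edge_context(ref, env0, 1, 0, "hydrophilic")
  W0 <- poredge:::.edge_energy(ectx, o$geometry$R0, o$geometry$Z0)$W
  for (dd in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    Wp <- poredge:::.edge_energy(ectx, o$geometry$R0 + dd[1],
                                 o$geometry$Z0 + dd[2])$W
    expect_gt(Wp, W0)
  }
})

test_that("gradient descent agrees with an exhaustive junction grid search", {
  o <- optimize_junction(ref, env0, r = 1, L = 0, mode = "hydrophilic")
  ectx <- poredge:::.edge_context(ref, env0, 1, 0, "hydrophilic")
  # two-stage grid: 0.05 nm coarse, then 0.01 nm around the coarse minimum
  R0s <- seq(1.3, 3.2, by = 0.05)
  Z0s <- seq(0.5, 2.2, by = 0.05)
  Wg <- outer(R0s, Z0s, Vectorize(function(a, b) poredge:::.edge_energy(ectx, a, b)$W))
  i <- which(Wg == min(Wg), arr.ind = TRUE)[1, ]
  R0f <- R0s[i[1]] + seq(-0.05, 0.05, by = 0.01)
  Z0f <- Z0s[i[2]] + seq(-0.05, 0.05, by = 0.01)
  Wf <- outer(R0f, Z0f, Vectorize(function(a, b) poredge:::.edge_energy(ectx, a, b)$W))
  expect_lt(abs(o$W - min(Wf)), 0.5)
  expect_lte(o$W, min(Wf) + 1e-9)   # descent is at least as good as the grid
})

test_that("total energy is continuous across the defect-to-pore limit", {
  g0 <- pore_geometry(1, 0, 2.2, 1.6)
  gL <- pore_geometry(1, 1e-3, 2.2, 1.6)
  W0 <- total_energy(ref, env0, g0, "hydrophilic")$W_total
  WL <- total_energy(ref, env0, gL, "hydrophobic")$W_total
  expect_lt(abs(WL - W0), 0.1)
})
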