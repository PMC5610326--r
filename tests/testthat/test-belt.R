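# Hydrophobic belt (Marcelja-type integrated energy).

env0 <- environment_parameters()

test_that("belt energy limits and reference value", {
  expect_equal(belt_energy(0, 1, env0), 0)
  # large-radius flat-wall limit: W_h -> 4 pi r L sigma_h
  r <- 400
  expect_equal(belt_energy(r, 1.3, env0) / (4 * pi * r * 1.3 * env0$sigma_h), 1,
               tolerance = 2e-3)
  # power-series oracle for I1(1)/I0(1)
  k <- 0:30
  I0 <- sum(0.25^k / factorial(k)^2)
  I1 <- 0.5 * sum(0.25^k / (factorial(k) * factorial(k + 1)))
  expect_equal(belt_energy(1, 1.25, env0),
               4 * pi * 1 * 1.25 * tension_to_internal(36) * I1 / I0,
               tolerance = 1e-12)
  expect_equal(belt_energy(1, 1.25, env0), 61.0, tolerance = 2e-3)
})

test_that("belt energy is monotone in r and L and exactly linear in L, sigma_h", {
  r <- seq(0.05, 12, by = 0.05)
  W <- belt_energy(r, 1, env0)
  expect_true(all(diff(W) > 0))
  L <- seq(0.1, 1.9, by = 0.1)
  WL <- belt_energy(1, L, env0)
  expect_true(all(diff(WL) > 0))
  expect_equal(WL, L * belt_energy(1, 1, env0), tolerance = 1e-14)
  expect_equal(belt_energy(1, 1, sigma_h = 2 * env0$sigma_h, xi_h = env0$xi_h),
               2 * belt_energy(1, 1, env0), tolerance = 1e-14)
  # a softer (longer) hydrophobic decay reduces the belt cost at fixed r
  expect_lt(belt_energy(0.675, 1.25, sigma_h = env0$sigma_h, xi_h = 1.5),
            belt_energy(0.675, 1.25, env0))
})
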