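# Unit system and lipid registry.

test_that("tension and line-tension unit bridges are exact and round-trip", {
  expect_identical(tension_to_internal(0), 0)
  expect_equal(tension_to_internal(36), 36 / 4.14, tolerance = 1e-12)
  expect_equal(tension_to_internal(36), 8.6957, tolerance = 1e-4)
  expect_equal(tension_to_internal(40), 9.6618, tolerance = 1e-4)
  expect_equal(line_tension_to_pN(1), 4.14, tolerance = 1e-12)
  expect_equal(line_tension_to_pN(2.415), 10.0, tolerance = 1e-3)
  x <- c(0.013, 1, 36, 133, 5000)
  expect_equal(tension_to_mN_per_m(tension_to_internal(x)), x, tolerance = 1e-12)
  expect_equal(line_tension_to_pN(line_tension_from_pN(x)), x, tolerance = 1e-12)
})

test_that("registry holds the documented parameter sets", {
  dopc <- get_lipid("DOPC")
  expect_equal(dopc$B, 10.3)
  expect_equal(dopc$h, 1.45)
  expect_equal(dopc$J0, -0.091)
  expect_equal(tension_to_mN_per_m(dopc$K_A), 133, tolerance = 1e-12)
  expect_equal(get_lipid("DMPC")$J0, +0.075)
  expect_equal(get_lipid("POPC")$B, 11)
  ref <- get_lipid("reference")
  expect_equal(ref$A, 100 / 40, tolerance = 1e-12)
  expect_equal(ref$l2, 8 / tension_to_internal(40), tolerance = 1e-12)
  # derived ratios are recomputed, and all K_t are 40 mN/m
  for (nm in list_lipids()) {
    lp <- get_lipid(nm)
    expect_equal(lp$l2, lp$B / lp$K_t, tolerance = 1e-14)
    expect_equal(lp$A, lp$K_A / lp$K_t, tolerance = 1e-14)
    expect_equal(tension_to_mN_per_m(lp$K_t), 40, tolerance = 1e-12)
    expect_gt(lp$l2, 0.3)   # sanity band of the registry, nm^2
    expect_lt(lp$l2, 2.0)
  }
})

test_that("invalid lipid requests fail with informative errors", {
  expect_error(get_lipid("cholesterol"), "available")
  expect_error(lipid_parameters("x", B_kBT = -1, KA_mN_per_m = 100, h_nm = 2))
  expect_error(lipid_parameters("x", B_kBT = 8, KA_mN_per_m = 100, h_nm = 0))
  expect_error(environment_parameters(sigma_h_mN_per_m = -3))
})
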