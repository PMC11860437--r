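test_that("sphere geometry reproduces the cross-size ratios", {
  q <- sphere_quantities(c(23, 68))
  expect_equal(round(q$volume_nm3[2] / q$volume_nm3[1]), 26)
  expect_equal(round(q$atoms_per_particle[2] / q$atoms_per_particle[1]), 26)
  expect_equal(round(q$surface_area_nm2[2] / q$surface_area_nm2[1]), 9)
  # TEM-mean diameters give different rounded ratios (both modes available)
  qt <- sphere_quantities(c(23.4, 68.2))
  expect_equal(round(qt$volume_nm3[2] / qt$volume_nm3[1]), 25)
  expect_equal(round(qt$surface_area_nm2[2] / qt$surface_area_nm2[1]), 8)
})

test_that("gold-atom count matches the independent closed form", {
  # oracle: (pi/6)(23e-7 cm)^3 * 19.3 g/cm3 / 196.97 g/mol * 6.02214076e23
  oracle <- (pi / 6) * (23e-7)^3 * 19.3 / 196.97 * 6.02214076e23
  expect_equal(sphere_quantities(23)$atoms_per_particle, oracle,
               tolerance = 1e-12)
  expect_equal(oracle / 1e5, 3.76, tolerance = 0.01)
})

test_that("derived quantities scale with the right powers of diameter", {
  set.seed(5)
  d <- runif(20, 5, 120)
  k <- runif(20, 1.5, 4)
  q1 <- sphere_quantities(d)
  q2 <- sphere_quantities(k * d)
  expect_equal(q2$volume_nm3 / q1$volume_nm3, k^3, tolerance = 1e-12)
  expect_equal(q2$surface_area_nm2 / q1$surface_area_nm2, k^2,
               tolerance = 1e-12)
  expect_equal(q2$atoms_per_particle / q1$atoms_per_particle, k^3,
               tolerance = 1e-12)
})

test_that("extinction calibration is the documented power law", {
  expect_equal(extinction_coefficient(2, list(k = 3, a = 0)), 8)
  expect_equal(extinction_coefficient(1, list(k = 3, a = 2.5)), exp(2.5))
  # ratio identity: eps(d2)/eps(d1) = (d2/d1)^k
  cal <- liu_calibration()
  expect_equal(extinction_coefficient(68) / extinction_coefficient(23),
               (68 / 23)^cal$k, tolerance = 1e-12)
  expect_error(extinction_coefficient(-1), "positive")
})

test_that("Beer-Lambert inversion is exact", {
  eps <- extinction_coefficient(23)
  expect_equal(concentration_from_absorbance(0, eps), 0)
  expect_equal(concentration_from_absorbance(eps * 0.3 * 1e-9, eps,
                                             pathlength_cm = 0.3),
               1e-9)
  a <- 0.52
  expect_equal(concentration_from_absorbance(a, eps, 0.15),
               2 * concentration_from_absorbance(a, eps, 0.3))
  # round trip c -> A -> c
  set.seed(8)
  c0 <- runif(10, 1e-11, 1e-8)
  A <- eps * 0.3 * c0
  expect_equal(concentration_from_absorbance(A, eps, 0.3), c0,
               tolerance = 1e-12)
})

test_that("surface density scale reproduces the printed coverage series", {
  expect_equal(surface_density_from_ratio(1e5), 0.3)
  expect_equal(surface_density_from_ratio(75000), 0.225)
  expect_equal(surface_density_from_ratio(125000), 0.375)
  # truncation (not rounding) formatter gives report parity
  expect_equal(format_surface_density(0.225), "0.22")
  expect_equal(format_surface_density(0.375), "0.37")
  expect_equal(format_surface_density(0.3), "0.30")
})

test_that("conjugation recipe matches first-principles pipetting arithmetic", {
  au23 <- sphere_quantities(23)
  au68 <- sphere_quantities(68)
  plan <- conjugation_recipe(2.47, 2, 0.75, au23, peptide_stock_mM = 30,
                             normalize_by_area = FALSE)
  # oracle: 2e-3 L x 2.47e-9 M x 75,000 / 3e-2 M = 12.35 uL
  expect_equal(plan$peptide_volume_uL, 12.35, tolerance = 1e-9)
  expect_equal(plan$molar_ratio, 75000)
  expect_equal(plan$surface_density_printed, "0.22")

  # linear in coverage, particle concentration and volume
  full <- conjugation_recipe(2.47, 2, 1.00, au23, peptide_stock_mM = 30,
                             normalize_by_area = FALSE)
  expect_equal(full$peptide_volume_uL / plan$peptide_volume_uL, 4 / 3,
               tolerance = 1e-12)
  twice <- conjugation_recipe(4.94, 2, 0.75, au23, peptide_stock_mM = 30,
                              normalize_by_area = FALSE)
  expect_equal(twice$peptide_volume_uL, 2 * plan$peptide_volume_uL,
               tolerance = 1e-12)

  # area normalization scales the per-particle ratio by (68/23)^2
  big <- conjugation_recipe(0.054, 2, 1.00, au68, reference_np = au23,
                            peptide_stock_mM = 30, normalize_by_area = TRUE)
  expect_equal(big$area_scale, (68 / 23)^2, tolerance = 1e-12)
  expect_equal(big$molar_ratio, 1e5 * (68 / 23)^2, tolerance = 1e-9)
  # but the surface-density label is size-independent
  expect_equal(big$surface_density_nmol_nm2, 0.3)

  expect_error(conjugation_recipe(2.47, 2, 1, au23, peptide_stock_mM = 0),
               "positive")
})
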