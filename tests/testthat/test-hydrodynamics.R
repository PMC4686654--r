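test_that("rod diffusion reproduces hand-evaluated reference values", {
  # l = 120 nm, d = 2 nm, water 25 C: kBT/(3 pi eta l) = 4.0896 um^2/s,
  # ln(60) + nu(60) = 4.4157, product 18.058
  D25 <- rod_diffusion(rod_model(120, 2))$D_um2_s
  expect_equal(D25, 18.058, tolerance = 1e-4)
  # same rod at 4 C in colder, more viscous water
  D4 <- rod_diffusion(rod_model(120, 2),
                      solvent_conditions(277.15, water_viscosity(4)))$D_um2_s
  expect_equal(D4, 9.534, tolerance = 1e-4)
})

test_that("rod diffusion obeys its scaling laws and validity domain", {
  base <- rod_diffusion(rod_model(120, 2))$D_um2_s
  half_eta <- rod_diffusion(rod_model(120, 2),
                            solvent_conditions(298.15, 8.9e-4 / 2))$D_um2_s
  expect_equal(half_eta, 2 * base, tolerance = 1e-12)
  dbl_T <- rod_diffusion(rod_model(120, 2),
                         solvent_conditions(2 * 298.15, 8.9e-4))$D_um2_s
  expect_equal(dbl_T, 2 * base, tolerance = 1e-12)
  expect_warning(rod_diffusion(rod_model(3, 2)), "validity")
  expect_error(rod_model(2, 2), "length > diameter")
})

test_that("rod diffusion decreases with length and increases with T", {
  set.seed(21)
  for (i in 1:20) {
    d <- runif(1, 1, 4)
    l1 <- runif(1, 3 * d, 100 * d)
    l2 <- l1 * runif(1, 1.1, 3)
    sv <- solvent_conditions(runif(1, 270, 320), runif(1, 5e-4, 2e-3))
    expect_gt(rod_diffusion(rod_model(l1, d), sv)$D_um2_s,
              rod_diffusion(rod_model(l2, d), sv)$D_um2_s)
    sv_hot <- solvent_conditions(sv$temperature_K + 20, sv$viscosity_Pa_s)
    expect_gt(rod_diffusion(rod_model(l1, d), sv_hot)$D_um2_s,
              rod_diffusion(rod_model(l1, d), sv)$D_um2_s)
  }
})

test_that("sphere diffusion matches Stokes-Einstein hand evaluations", {
  expect_equal(sphere_diffusion(2.3)$D_um2_s, 106.68, tolerance = 1e-4)
  # minimal sphere for a 327 kDa dimer: R = 0.066 * M^(1/3) = 4.55 nm
  R <- sphere_radius_from_mass(327000)
  expect_equal(R, 4.55, tolerance = 0.01)
  expect_equal(sphere_diffusion(4.55)$D_um2_s, 53.93, tolerance = 1e-3)
  expect_equal(sphere_diffusion(4.6)$D_um2_s,
               sphere_diffusion(2.3)$D_um2_s / 2, tolerance = 1e-12)
  expect_error(sphere_diffusion(0), "positive")
})

test_that("a rod diffuses between its equal-volume and circumscribing spheres", {
  # elongation slows a particle relative to a compact sphere of the same
  # volume, but a thin rod still outruns the huge sphere that circumscribes
  # it: D(equal-volume sphere) > D(rod) > D(sphere of radius l/2)
  set.seed(31)
  for (i in 1:20) {
    d <- runif(1, 1, 5)
    l <- runif(1, 2.5 * d, 80 * d)
    D_rod <- rod_diffusion(rod_model(l, d))$D_um2_s
    R_eq <- (3 * d^2 * l / 16)^(1 / 3)  # sphere with the rod's volume
    expect_lt(D_rod, sphere_diffusion(R_eq)$D_um2_s)
    expect_gt(D_rod, sphere_diffusion(l / 2)$D_um2_s)
  }
})

test_that("SI and micrometre-scale computations agree to 12 digits", {
  # direct evaluation in um^2/s: kB T in J = kg m^2/s^2; with l in m the
  # SI result in m^2/s times 1e12 must equal a um-native evaluation
  l_nm <- 120; d_nm <- 2; T <- 298.15; eta <- 8.9e-4
  p <- l_nm / d_nm
  nu <- 0.312 + 0.565 / p - 0.100 / p^2
  D_um_native <- (1.380649e-23 * T * (log(p) + nu)) /
    (3 * pi * eta * (l_nm * 1e-3 * 1e-6)) * 1e12
  D_pkg <- rod_diffusion(rod_model(l_nm, d_nm))$D_um2_s
  expect_equal(D_pkg, D_um_native, tolerance = 1e-12)
})

test_that("measured diffusion classifies between rod and sphere limits", {
  rod <- rod_model(120, 2)
  D_rod <- rod_diffusion(rod)$D_um2_s
  D_sph <- sphere_diffusion(4.55)$D_um2_s
  expect_equal(classify_conformation(D_rod, rod, 4.55)$index, 0)
  expect_equal(classify_conformation(D_sph, rod, 4.55)$index, 1)
  cl <- classify_conformation(25, rod, 4.55)
  expect_equal(cl$index, 0.1935, tolerance = 1e-3)
  expect_identical(cl$verdict, "extended/semi-rigid")
  compact <- classify_conformation(45, rod, 4.55)
  expect_identical(compact$verdict, "compact")
  # out-of-range measurements are clamped but flagged
  slow <- classify_conformation(10, rod, 4.55)
  expect_true(slow$clamped)
  expect_equal(slow$index, 0)
  # inconsistent limits (sphere slower than rod) are an error
  expect_error(classify_conformation(25, rod, 100), "inconsistent")
})

test_that("water viscosity lookup covers the tabulated temperatures only", {
  expect_equal(water_viscosity(25), 8.9e-4)
  expect_equal(water_viscosity(4), 1.567e-3)
  expect_error(water_viscosity(30), "no tabulated")
})
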