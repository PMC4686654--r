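test_that("the 3D diffusion model has amplitude 1/N and decays strictly", {
  tau <- acf_tau_grid(1e-7, 1, 200)
  G <- model_acf(tau, N = 5, tau_d_s = 1e-3)
  expect_equal(G[1], 1 / 5, tolerance = 1e-3)  # G(tau -> 0) -> 1/N
  expect_true(all(G > 0))
  expect_true(all(diff(G) < 0))
  # at tau = tauD with a near-planar volume: (1/5)(1/2)(1 + 1/S^2)^-1/2
  g_half <- model_acf(1e-3, N = 5, tau_d_s = 1e-3,
                      geometry = confocal_geometry(S = 1000))
  expect_equal(g_half, 0.1, tolerance = 1e-5)
  expect_error(model_acf(tau, N = -1, tau_d_s = 1e-3), "positive")
})

test_that("acf_curve validates its invariants", {
  expect_error(acf_curve(1:5 * 1e-3, rep(0.2, 5)), "8 points")
  expect_error(acf_curve(c(1e-3, 1e-3, 2:7 * 1e-3), rep(0.2, 8)),
               "strictly increasing")
  expect_error(acf_curve(seq_len(8) * 1e-3, rep(0.2, 8),
                         sigma = rep(-1, 8)), "sigma")
})

test_that("noise-free fits recover parameters over a log-uniform sweep", {
  set.seed(17)
  for (i in 1:20) {
    N <- exp(runif(1, log(1), log(100)))
    tD <- exp(runif(1, log(5e-5), log(1e-2)))
    f <- fit_acf(gen_acf(N, tD, noise_cv = 0))
    expect_true(f$converged)
    expect_lt(abs(f$N - N) / N, 0.005)
    expect_lt(abs(f$tau_d_s - tD) / tD, 0.005)
  }
})

test_that("fits tolerate 2% multiplicative noise", {
  rel_err <- vapply(1:10, function(i) {
    f <- fit_acf(gen_acf(5, 4e-4, noise_cv = 0.02, seed = i))
    abs(f$D_um2_s - 25) / 25
  }, 1)
  expect_gte(sum(rel_err < 0.05), 9)
})

test_that("pathological curves fail gracefully with a diagnostic", {
  flat <- acf_curve(acf_tau_grid(n = 16), rep(0.2, 16))
  f <- fit_acf(flat)
  expect_false(f$converged)
  expect_match(f$reason, "no decay")
  neg <- acf_curve(acf_tau_grid(n = 16), rep(-0.1, 16))
  expect_match(fit_acf(neg)$reason, "amplitude")
})

test_that("diffusion time converts to diffusion coefficient via w0^2/4tauD", {
  expect_equal(diffusion_from_tau(4e-4), 25)
  expect_equal(diffusion_from_tau(5.556e-4), 18, tolerance = 1e-4)
  expect_equal(diffusion_from_tau(8e-4), 12.5)  # doubling tauD halves D
  # D scales with w0^2, so the geometry must be echoed
  expect_equal(diffusion_from_tau(4e-4, confocal_geometry(w0_um = 0.4)), 100)
  expect_error(diffusion_from_tau(-1), "positive")
})

test_that("brightness is intensity per particle", {
  expect_equal(brightness(1e5, 5), 2e4)
  expect_equal(brightness(123, 1), 123)
  expect_equal(brightness(0, 5), 0)
  expect_error(brightness(100, 0), "positive")
})

test_that("fit results are invariant to tau-grid density", {
  f_coarse <- fit_acf(gen_acf(8, 1e-3, tau_grid = acf_tau_grid(n = 64),
                              noise_cv = 0))
  f_fine <- fit_acf(gen_acf(8, 1e-3, tau_grid = acf_tau_grid(n = 256),
                            noise_cv = 0))
  expect_equal(f_coarse$N, f_fine$N, tolerance = 1e-6)
  expect_equal(f_coarse$D_um2_s, f_fine$D_um2_s, tolerance = 1e-6)
})

test_that("replicate fits pool into mean +/- sample s.d.", {
  mk <- function(D) {
    tauD <- 0.2^2 / (4 * D)
    structure(list(converged = TRUE, N = 5, tau_d_s = tauD, D_um2_s = D,
                   geometry = confocal_geometry()), class = "fcs_fit")
  }
  pool <- average_replicates(lapply(c(24, 25, 26), mk))
  expect_equal(pool$D_um2_s$mean, 25)
  expect_equal(pool$D_um2_s$sd, 1)
  same <- average_replicates(lapply(rep(25, 10), mk))
  expect_equal(same$D_um2_s$sd, 0)
  expect_identical(same$n, 10L)
  # heterogeneous geometry is an error
  odd <- mk(25); odd$geometry <- confocal_geometry(w0_um = 0.3)
  expect_error(average_replicates(list(mk(24), odd)), "heterogeneous")
  expect_error(average_replicates(list(mk(24))), "at least 2")
})

test_that("pooled fits of seeded noisy replicates centre on the truth", {
  fits <- lapply(1:10, function(i) {
    fit_acf(gen_acf(5, 4e-4, noise_cv = 0.02, seed = 100 + i))
  })
  pool <- average_replicates(fits)
  expect_lt(abs(pool$D_um2_s$mean - 25) / 25, 0.02)
})

test_that("ACF tables and fit JSON serialize to disk", {
  curve <- gen_acf(5, 1e-3, noise_cv = 0.02, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_acf_table(curve, path)
  back <- read_acf_table(path)
  expect_equal(back$G, curve$G, tolerance = 1e-12)
  expect_equal(back$sigma, curve$sigma, tolerance = 1e-12)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_fcs_fit_json(fit_acf(curve), jpath)
  parsed <- jsonlite::fromJSON(jpath)
  expect_true(parsed$converged)
  expect_equal(parsed$geometry$w0_um, 0.2)
})
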