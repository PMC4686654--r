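test_that("all generators are pure functions of their spec", {
  expect_identical(gen_heptad_sequence(12, 30, seed = 4),
                   gen_heptad_sequence(12, 30, seed = 4))
  expect_identical(gen_ortholog_family(4, 20, 33, seed = 4),
                   gen_ortholog_family(4, 20, 33, seed = 4))
  a <- gen_acf(5, 1e-3, noise_cv = 0.02, seed = 4)
  b <- gen_acf(5, 1e-3, noise_cv = 0.02, seed = 4)
  expect_identical(a$G, b$G)
  expect_identical(gen_particle_traces(3, 80, 60, 2, 1, seed = 4),
                   gen_particle_traces(3, 80, 60, 2, 1, seed = 4))
  # different seeds give different draws
  expect_false(identical(gen_heptad_sequence(12, 30, seed = 4),
                         gen_heptad_sequence(12, 30, seed = 5)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(gen_heptad_sequence(10, 10, seed = 1))
  invisible(gen_particle_traces(2, 50, 50, 2, 1, seed = 1))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("heptad sequences follow the a-g construction", {
  s <- gen_heptad_sequence(1, 0, seed = 2)
  chars <- strsplit(s, "")[[1]]
  expect_length(chars, 7L)
  expect_true(all(chars[c(1, 4)] %in% c("L", "I", "V", "M")))  # a and d
  expect_true(all(chars[c(5, 7)] %in% c("E", "K", "R", "Q")))  # e and g
  s2 <- gen_heptad_sequence(10, 25, seed = 2)
  expect_identical(nchar(s2), 10L * 7L + 2L * 25L)
  expect_identical(attr(s2, "coil_start"), 26L)
  expect_identical(attr(s2, "coil_end"), 95L)
  expect_error(gen_heptad_sequence(0), ">= 1")
})

test_that("the predictor finds the generated core, not the flanks", {
  s <- gen_heptad_sequence(104, 200, seed = 1)
  segs <- call_segments(score_sequence(s))
  expect_equal(nrow(segs), 1L)
  core <- c(attr(s, "coil_start"), attr(s, "coil_end"))
  covered <- max(0, min(segs$end, core[2]) - max(segs$start, core[1]) + 1)
  expect_gte(covered / (core[2] - core[1] + 1), 0.9)
  flank_called <- segs$n_residues - covered
  expect_lt(flank_called / (2 * 200), 0.1)
})

test_that("ortholog families conserve coil length exactly", {
  fam <- gen_ortholog_family(6, 30, 50, seed = 8, flank_len = 40)
  expect_identical(nrow(fam), 6L)
  expect_true(all(fam$coil_end - fam$coil_start + 1 == 210L))
  coils <- substr(fam$sequence, fam$coil_start[1], fam$coil_end[1])
  expect_length(unique(nchar(coils)), 1L)
  # taxon labels recycle
  fam2 <- gen_ortholog_family(4, 10, 80, seed = 8,
                              taxa = c("chordata", "arthropoda"))
  expect_identical(fam2$taxon, rep(c("chordata", "arthropoda"), 2))
})

test_that("family identity is driven to its target", {
  fam <- gen_ortholog_family(10, 104, 33, seed = 7)
  regions <- lapply(seq_len(nrow(fam)),
                    function(i) c(fam$coil_start[i], fam$coil_end[i]))
  idn <- mean_pairwise_identity(fam$sequence, regions = regions)
  expect_lt(abs(idn - 33), 5)
  # a 100% target leaves all coils identical
  same <- gen_ortholog_family(5, 20, 100, seed = 7, flank_len = 0)
  expect_length(unique(same$sequence), 1L)
  # below the class-constrained floor the target is unreachable
  expect_error(gen_ortholog_family(5, 20, 10, seed = 7), "unreachable")
})

test_that("noise-free synthetic ACF curves equal the model exactly", {
  tau <- acf_tau_grid(1e-6, 0.1, 64)
  curve <- gen_acf(7, 2e-3, tau_grid = tau, noise_cv = 0)
  expect_identical(curve$G, model_acf(tau, 7, 2e-3))
  expect_null(curve$sigma)
  noisy <- gen_acf(7, 2e-3, tau_grid = tau, noise_cv = 0.02, seed = 1)
  expect_false(identical(noisy$G, curve$G))
  expect_equal(noisy$sigma, curve$G * 0.02)
})

test_that("trace generator hits its contour and straight-rod limit", {
  straight <- gen_particle_traces(1, 100, Inf, 2, 0, seed = 1)[[1]]
  expect_equal(contour_length(straight), 100, tolerance = 1e-9)
  # without jitter the polyline contour is exact by construction
  bent <- gen_particle_traces(5, 106.7, 100, 2, 0, seed = 2)
  for (tr in bent) {
    expect_equal(contour_length(tr), 106.7, tolerance = 1e-9)
  }
  # generated traces satisfy the consumer's input invariants
  jittered <- gen_particle_traces(5, 106.7, 100, 2, 1, seed = 2)
  for (tr in jittered) {
    expect_gte(length(tr$x), 2L)
    expect_true(all(is.finite(tr$x)) && all(is.finite(tr$y)))
  }
  expect_error(gen_particle_traces(2, -1, 100, 2), "positive")
})
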