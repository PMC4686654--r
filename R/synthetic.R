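# Seeded synthetic-data generators. Every generator draws from its own RNG
# stream (derived from the user seed plus a fixed per-generator tag) and
# restores the caller's RNG state, so identical calls are bit-reproducible
# and adding one generator never shifts another's output.

AD_CLASS <- c("L", "I", "V", "M")            # core positions a, d
EG_CLASS <- c("E", "K", "R", "Q")            # flanking charged e, g
BCF_CLASS <- c("A", "S", "T", "N", "Q", "E", "K", "D")  # surface b, c, f

heptad_core <- function(n_heptads) {
  # one heptad = positions a b c d e f g
  draw <- function(classes, k) sample(classes, k, replace = TRUE)
  core <- character(n_heptads * 7L)
  pos <- rep(1:7, n_heptads)
  core[pos == 1] <- draw(AD_CLASS, n_heptads)
  core[pos == 4] <- draw(AD_CLASS, n_heptads)
  core[pos == 5] <- draw(EG_CLASS, n_heptads)
  core[pos == 7] <- draw(EG_CLASS, n_heptads)
  n_bcf <- sum(pos %in% c(2, 3, 6))
  core[pos %in% c(2, 3, 6)] <- draw(BCF_CLASS, n_bcf)
  core
}

random_flank <- function(len) {
  if (len <= 0) return(character(0))
  sample(Biostrings::AA_STANDARD, len, replace = TRUE)
}

#' Generate a heptad-patterned coiled-coil sequence
#'
#' Core of `n_heptads` x 7 residues with aliphatic residues at positions
#' a/d, charged residues at e/g and polar residues at b/c/f, optionally
#' flanked on both sides by `flank_len` residues of uniform background
#' composition. The heptad register starts at position a (sequence index
#' `flank_len + 1`).
#'
#' @param n_heptads Number of heptads (>= 1).
#' @param flank_len Flank length on each side (default 0).
#' @param seed Integer seed; identical calls give identical sequences.
#' @return A character string; attributes `coil_start`/`coil_end` give the
#'   true core coordinates (1-based inclusive).
#' @export
gen_heptad_sequence <- function(n_heptads, flank_len = 0, seed = 1) {
  if (!is.numeric(n_heptads) || n_heptads < 1) stop("n_heptads must be >= 1")
  with_stream(seed, "heptad_sequence", {
    s <- paste(c(random_flank(flank_len),
                 heptad_core(as.integer(n_heptads)),
                 random_flank(flank_len)), collapse = "")
    attr(s, "coil_start") <- as.integer(flank_len + 1)
    attr(s, "coil_end") <- as.integer(flank_len + n_heptads * 7)
    s
  })
}

# expected pairwise identity (fraction) when each coil position is
# independently redrawn from its class with probability q in each record
expected_identity <- function(q, class_sizes = c(4, 4, 8),
                              weights = c(2, 2, 3) / 7) {
  keep2 <- (1 - q)^2
  sum(weights * (keep2 + (1 - keep2) / class_sizes))
}

#' Generate an orthologue family with a length-conserved coiled-coil
#'
#' All members carry exactly the same coil residue count; sequence
#' divergence is introduced by redrawing coil positions within their
#' heptad-position class (a/d aliphatic, e/g charged, b/c/f polar), so the
#' heptad pattern — and hence the predicted length — is preserved while
#' pairwise identity is driven toward `coil_identity_target`. Flanks are
#' independent background sequence per record.
#'
#' @param n Family size (>= 2).
#' @param coil_heptads Number of heptads in the shared coil.
#' @param coil_identity_target Target mean pairwise coil identity, percent.
#'   Must be above the class-constrained floor (~19.6%: the identity of
#'   unrelated sequences drawn from the same position classes).
#' @param seed Integer seed.
#' @param flank_len Per-side flank length (default 100).
#' @param taxa Optional vector of group labels, recycled to length `n`.
#' @return A data.frame with columns `id`, `taxon`, `sequence`,
#'   `coil_start`, `coil_end` (true coil coordinates).
#' @export
gen_ortholog_family <- function(n, coil_heptads, coil_identity_target,
                                seed = 1, flank_len = 100, taxa = NULL) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  if (!is.numeric(coil_identity_target) || coil_identity_target <= 0 ||
      coil_identity_target > 100) {
    stop("coil_identity_target must be in (0, 100]")
  }
  t_frac <- coil_identity_target / 100
  floor_frac <- expected_identity(1)
  if (t_frac < floor_frac) {
    stop(sprintf(
      "unreachable identity target %.1f%%: class-constrained floor is %.1f%%",
      coil_identity_target, 100 * floor_frac))
  }
  q <- if (t_frac >= 1) 0 else {
    stats::uniroot(function(q) expected_identity(q) - t_frac,
                   c(0, 1), tol = 1e-10)$root
  }
  with_stream(seed, "ortholog_family", {
    n <- as.integer(n)
    len <- as.integer(coil_heptads) * 7L
    ancestor <- heptad_core(as.integer(coil_heptads))
    pos <- rep(1:7, coil_heptads)
    class_of <- ifelse(pos %in% c(1, 4), "ad",
                       ifelse(pos %in% c(5, 7), "eg", "bcf"))
    classes <- list(ad = AD_CLASS, eg = EG_CLASS, bcf = BCF_CLASS)
    taxa <- if (is.null(taxa)) rep("unassigned", n)
            else rep_len(taxa, n)
    rows <- lapply(seq_len(n), function(i) {
      coil <- ancestor
      hit <- stats::runif(len) < q
      for (cl in names(classes)) {
        sel <- hit & class_of == cl
        if (any(sel)) {
          coil[sel] <- sample(classes[[cl]], sum(sel), replace = TRUE)
        }
      }
      seq <- paste(c(random_flank(flank_len), coil, random_flank(flank_len)),
                   collapse = "")
      data.frame(id = sprintf("ortho_%02d", i), taxon = taxa[i],
                 sequence = seq,
                 coil_start = flank_len + 1L,
                 coil_end = flank_len + len,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Log-spaced lag-time grid for synthetic ACF curves
#'
#' @param tau_min_s,tau_max_s Grid limits in seconds.
#' @param n Number of points (default 128).
#' @return Strictly increasing lag times.
#' @export
acf_tau_grid <- function(tau_min_s = 1e-6, tau_max_s = 1, n = 128) {
  if (tau_min_s <= 0 || tau_max_s <= tau_min_s || n < 8) {
    stop("need 0 < tau_min_s < tau_max_s and n >= 8")
  }
  exp(seq(log(tau_min_s), log(tau_max_s), length.out = n))
}

#' Generate a noisy autocorrelation curve
#'
#' Model values from [model_acf()] multiplied by `(1 + eps)` with
#' `eps ~ N(0, noise_cv)` — multiplicative noise with the given coefficient
#' of variation. With `noise_cv = 0` the curve equals the model exactly.
#'
#' @param N,tau_d_s True particle number and diffusion time.
#' @param geometry A [confocal_geometry()].
#' @param tau_grid Lag-time grid (default [acf_tau_grid()]).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @return An [acf_curve()]; `sigma` is set to `G_model * noise_cv` when
#'   noise is present.
#' @export
gen_acf <- function(N, tau_d_s, geometry = confocal_geometry(),
                    tau_grid = acf_tau_grid(), noise_cv = 0, seed = 1) {
  if (!is.numeric(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  g0 <- model_acf(tau_grid, N, tau_d_s, geometry)
  if (noise_cv == 0) return(acf_curve(tau_grid, g0))
  with_stream(seed, "acf_curve", {
    eps <- stats::rnorm(length(tau_grid), 0, noise_cv)
    acf_curve(tau_grid, g0 * (1 + eps), sigma = g0 * noise_cv)
  })
}

# Smooth (correlated) unit-variance noise: white noise convolved with a
# Gaussian kernel of s.d. corr_pts points. Models digitization error as a
# slowly varying tracing drift; independent per-point jitter at fine
# sampling would systematically inflate polyline contour lengths.
smooth_noise <- function(n_pts, corr_pts) {
  if (corr_pts <= 0) return(stats::rnorm(n_pts))
  half <- ceiling(3 * corr_pts)
  k <- stats::dnorm(seq(-half, half), sd = corr_pts)
  k <- k / sum(k)
  w <- stats::rnorm(n_pts + 2 * half)
  s <- as.numeric(stats::filter(w, k, sides = 2))
  s <- s[(half + 1):(half + n_pts)]
  s / sqrt(sum(k^2))
}

#' Generate worm-like-chain particle traces
#'
#' 2D discrete worm-like chains (projected chains, as imaged for
#' surface-adsorbed molecules): successive bond angles are drawn with
#' variance `step_nm / persistence_nm`; the polyline contour before jitter
#' equals `contour_nm` exactly (the step is adjusted to divide the contour
#' evenly). Digitization noise is added as smooth correlated point
#' displacement of s.d. `point_noise_nm` (correlation length
#' `noise_corr_nm`).
#'
#' @param n Number of traces.
#' @param contour_nm True contour length (nm).
#' @param persistence_nm Persistence length (nm); `Inf` gives straight rods.
#' @param step_nm Nominal digitization step (nm).
#' @param point_noise_nm Point jitter s.d. (nm, default 0).
#' @param seed Integer seed.
#' @param noise_corr_nm Correlation length of the jitter along the trace
#'   (default 50 nm).
#' @return A named list of [particle_trace()] objects.
#' @export
gen_particle_traces <- function(n, contour_nm, persistence_nm, step_nm,
                                point_noise_nm = 0, seed = 1,
                                noise_corr_nm = 50) {
  if (any(c(contour_nm, persistence_nm, step_nm) <= 0)) {
    stop("contour_nm, persistence_nm and step_nm must be positive")
  }
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  with_stream(seed, "particle_traces", {
    n_seg <- max(1L, as.integer(round(contour_nm / step_nm)))
    seg <- contour_nm / n_seg
    ang_sd <- if (is.infinite(persistence_nm)) 0
              else sqrt(step_nm / persistence_nm)
    corr_pts <- noise_corr_nm / step_nm
    traces <- lapply(seq_len(n), function(i) {
      theta0 <- stats::runif(1, 0, 2 * pi)
      dtheta <- if (ang_sd > 0) stats::rnorm(n_seg - 1, 0, ang_sd)
                else rep(0, max(0, n_seg - 1))
      theta <- theta0 + c(0, cumsum(dtheta))
      x <- c(0, cumsum(seg * cos(theta)))
      y <- c(0, cumsum(seg * sin(theta)))
      if (point_noise_nm > 0) {
        x <- x + point_noise_nm * smooth_noise(length(x), corr_pts)
        y <- y + point_noise_nm * smooth_noise(length(y), corr_pts)
      }
      particle_trace(x, y, id = sprintf("particle_%02d", i))
    })
    names(traces) <- vapply(traces, `[[`, "", "id")
    traces
  })
}
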