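# Fluorescence correlation spectroscopy: single-component 3D diffusion
# autocorrelation model, nonlinear least-squares fitting, diffusion-time to
# diffusion-coefficient conversion, and molecular brightness.

#' Confocal detection-volume geometry
#'
#' The FCS model depends on the lateral beam waist w0 and the structure
#' parameter S (axial/lateral waist ratio). Because D scales with w0^2,
#' every fit result echoes the geometry used.
#'
#' @param w0_um Lateral beam waist (μm, default 0.2).
#' @param S Structure parameter (> 1, default 5).
#' @return An object of class `confocal_geometry`.
#' @export
confocal_geometry <- function(w0_um = 0.2, S = 5) {
  if (!is.numeric(w0_um) || w0_um <= 0) stop("w0_um must be positive")
  if (!is.numeric(S) || S <= 1) stop("structure parameter S must be > 1")
  structure(list(w0_um = w0_um, S = S), class = "confocal_geometry")
}

#' An autocorrelation curve
#'
#' @param tau_s Lag times in seconds: at least 8 points, strictly
#'   increasing, all positive.
#' @param G Correlation amplitudes G(tau).
#' @param sigma Optional per-point uncertainties (same length).
#' @return An object of class `acf_curve`.
#' @export
acf_curve <- function(tau_s, G, sigma = NULL) {
  if (!is.numeric(tau_s) || !is.numeric(G) || length(tau_s) != length(G)) {
    stop("tau_s and G must be numeric vectors of equal length")
  }
  if (length(tau_s) < 8L) stop("need at least 8 points")
  if (any(tau_s <= 0) || any(diff(tau_s) <= 0)) {
    stop("tau_s must be positive and strictly increasing")
  }
  if (!is.null(sigma) && (length(sigma) != length(G) || any(sigma <= 0))) {
    stop("sigma must be positive and match G in length")
  }
  structure(list(tau_s = tau_s, G = G, sigma = sigma), class = "acf_curve")
}

#' Single-component 3D diffusion autocorrelation model
#'
#' G(tau) = (1/N) (1 + tau/tauD)^-1 (1 + tau/(S^2 tauD))^-1/2: amplitude
#' 1/N at tau -> 0, strictly decreasing in tau.
#'
#' @param tau_s Lag times (s).
#' @param N Mean particle number in the focal volume (> 0).
#' @param tau_d_s Diffusion time (s, > 0).
#' @param geometry A [confocal_geometry()].
#' @return G values on the tau grid.
#' @export
model_acf <- function(tau_s, N, tau_d_s,
                      geometry = confocal_geometry()) {
  stopifnot(inherits(geometry, "confocal_geometry"))
  if (!is.numeric(N) || N <= 0 || !is.numeric(tau_d_s) || tau_d_s <= 0) {
    stop("N and tau_d_s must be positive")
  }
  x <- tau_s / tau_d_s
  (1 / N) / ((1 + x) * sqrt(1 + x / geometry$S^2))
}

#' Diffusion coefficient from diffusion time
#'
#' D = w0^2 / (4 tauD), in μm²/s.
#'
#' @param tau_d_s Diffusion time (s, > 0).
#' @param geometry A [confocal_geometry()].
#' @return D in μm²/s.
#' @examples
#' diffusion_from_tau(4e-4) # 25 um^2/s at w0 = 0.2 um
#' @export
diffusion_from_tau <- function(tau_d_s, geometry = confocal_geometry()) {
  stopifnot(inherits(geometry, "confocal_geometry"))
  if (!is.numeric(tau_d_s) || any(tau_d_s <= 0)) {
    stop("tau_d_s must be positive")
  }
  geometry$w0_um^2 / (4 * tau_d_s)
}

#' Apparent molecular brightness
#'
#' Mean recorded intensity divided by the mean particle number in the
#' focal volume.
#'
#' @param mean_intensity_cps Average fluorescence intensity (counts/s, >= 0).
#' @param N Mean particle number (> 0).
#' @return Brightness in counts/s per particle.
#' @export
brightness <- function(mean_intensity_cps, N) {
  if (!is.numeric(N) || any(N <= 0)) stop("N must be positive")
  if (!is.numeric(mean_intensity_cps) || any(mean_intensity_cps < 0)) {
    stop("intensity must be non-negative")
  }
  mean_intensity_cps / N
}

fcs_failure <- function(reason, geometry) {
  structure(list(converged = FALSE, reason = reason, geometry = geometry),
            class = "fcs_fit")
}

#' Fit the 3D diffusion model to an autocorrelation curve
#'
#' Nonlinear least squares (Levenberg–Marquardt) for (N, tauD), with the
#' initial guess N = 1/G(first point) and tauD = the lag where G falls to
#' half its initial amplitude. D is derived as w0^2/(4 tauD). Pathological
#' curves (non-positive amplitude, no decay) return a diagnostic fit-failure
#' object instead of raising.
#'
#' @param curve An [acf_curve()].
#' @param geometry A [confocal_geometry()].
#' @param mean_intensity_cps Optional mean intensity; if given, brightness
#'   is filled in.
#' @param weighted Use 1/sigma^2 weights when the curve carries
#'   uncertainties (default TRUE; unweighted otherwise).
#' @return An object of class `fcs_fit`: either `converged = TRUE` with
#'   `N`, `tau_d_s`, `D_um2_s`, `brightness_cps`, `residual_norm`,
#'   `geometry`, or `converged = FALSE` with a `reason`.
#' @export
fit_acf <- function(curve, geometry = confocal_geometry(),
                    mean_intensity_cps = NULL, weighted = TRUE) {
  stopifnot(inherits(curve, "acf_curve"),
            inherits(geometry, "confocal_geometry"))
  tau <- curve$tau_s
  G <- curve$G
  amp <- mean(G[1:3])
  if (!is.finite(amp) || amp <= 0) {
    return(fcs_failure("non-positive amplitude", geometry))
  }
  if (mean(utils::tail(G, 3)) >= 0.9 * amp) {
    return(fcs_failure("no decay", geometry))
  }
  N0 <- 1 / amp
  below <- which(G <= amp / 2)
  tauD0 <- if (length(below)) tau[below[1]] else stats::median(tau)
  S <- geometry$S
  w <- if (weighted && !is.null(curve$sigma)) 1 / curve$sigma^2
       else rep(1, length(G))
  dat <- data.frame(tau = tau, G = G, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      G ~ (1 / N) / ((1 + tau / tauD) * sqrt(1 + tau / (S^2 * tauD))),
      data = dat, start = list(N = N0, tauD = tauD0),
      lower = c(N = 1e-12, tauD = 1e-12), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(fcs_failure(paste("solver failure:", conditionMessage(fit)),
                       geometry))
  }
  est <- stats::coef(fit)
  structure(list(
    converged = TRUE,
    N = unname(est["N"]),
    tau_d_s = unname(est["tauD"]),
    D_um2_s = diffusion_from_tau(unname(est["tauD"]), geometry),
    brightness_cps = if (is.null(mean_intensity_cps)) NA_real_
                     else brightness(mean_intensity_cps, unname(est["N"])),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    geometry = geometry
  ), class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "<fcs_fit> N = %.3g, tauD = %.4g s, D = %.3g um^2/s (w0 = %g um, S = %g)\n",
      x$N, x$tau_d_s, x$D_um2_s, x$geometry$w0_um, x$geometry$S))
  } else {
    cat(sprintf("<fcs_fit> FAILED: %s\n", x$reason))
  }
  invisible(x)
}

#' Pool replicate FCS fits
#'
#' Per-parameter mean and sample (n-1) standard deviation across replicate
#' measurements of one sample; all fits must share the same geometry.
#'
#' @param fits List of converged `fcs_fit` objects (>= 2).
#' @return List of class `fcs_fit_summary` with `n` and `mean`/`sd` for
#'   `N`, `tau_d_s`, `D_um2_s`, plus the common geometry.
#' @export
average_replicates <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, inherits, TRUE, "fcs_fit"))) {
    stop("need a list of at least 2 fcs_fit objects")
  }
  if (!all(vapply(fits, function(f) isTRUE(f$converged), TRUE))) {
    stop("all fits must have converged")
  }
  geo <- fits[[1]]$geometry
  same <- vapply(fits, function(f) {
    isTRUE(all.equal(f$geometry$w0_um, geo$w0_um)) &&
      isTRUE(all.equal(f$geometry$S, geo$S))
  }, TRUE)
  if (!all(same)) stop("heterogeneous geometry across fits")
  grab <- function(fld) vapply(fits, `[[`, 1, fld)
  stat <- function(v) list(mean = mean(v),
                           sd = stats::sd(v))
  structure(list(
    n = length(fits),
    N = stat(grab("N")),
    tau_d_s = stat(grab("tau_d_s")),
    D_um2_s = stat(grab("D_um2_s")),
    geometry = geo
  ), class = "fcs_fit_summary")
}

#' Read / write autocorrelation curves as TSV
#'
#' Two or three tab-separated columns: `tau_s`, `G`, optional `sigma`.
#'
#' @param path File path.
#' @param curve An [acf_curve()].
#' @return `read_acf_table` returns an [acf_curve()].
#' @export
read_acf_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("tau_s", "G") %in% names(tab))) {
    stop("ACF table needs columns tau_s and G")
  }
  acf_curve(tab$tau_s, tab$G, sigma = tab$sigma)
}

#' @rdname read_acf_table
#' @export
write_acf_table <- function(curve, path) {
  stopifnot(inherits(curve, "acf_curve"))
  df <- data.frame(tau_s = curve$tau_s, G = curve$G)
  if (!is.null(curve$sigma)) df$sigma <- curve$sigma
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize an FCS fit as JSON
#'
#' @param fit An `fcs_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fcs_fit"))
  x <- unclass(fit)
  x$geometry <- unclass(x$geometry)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
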