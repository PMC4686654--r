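# Closed-form translational diffusion for stiff rods and spheres, and
# classification of measured diffusion coefficients between these limits.

KBOLTZ <- 1.380649e-23  # J/K (exact, SI)

#' Solvent conditions for diffusion calculations
#'
#' @param temperature_K Absolute temperature (default 298.15 K, 25 °C).
#' @param viscosity_Pa_s Dynamic viscosity (default 8.9e-4 Pa s, water at
#'   25 °C).
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature_K = 298.15,
                               viscosity_Pa_s = 8.9e-4) {
  if (!is.numeric(temperature_K) || temperature_K <= 0 ||
      !is.numeric(viscosity_Pa_s) || viscosity_Pa_s <= 0) {
    stop("temperature and viscosity must be positive")
  }
  structure(list(temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s),
            class = "solvent_conditions")
}

#' Dynamic viscosity of water at common lab temperatures
#'
#' Small lookup (4, 20, 25, 37 °C) sufficient for rod/sphere comparisons;
#' other temperatures must supply viscosity explicitly.
#'
#' @param temp_c Temperature in °C (one of 4, 20, 25, 37).
#' @return Viscosity in Pa s.
#' @export
water_viscosity <- function(temp_c) {
  tab <- c(`4` = 1.567e-3, `20` = 1.002e-3, `25` = 8.9e-4, `37` = 6.913e-4)
  key <- as.character(temp_c)
  if (!key %in% names(tab)) {
    stop("no tabulated water viscosity at ", temp_c,
         " degC (have 4, 20, 25, 37); supply viscosity_Pa_s directly")
  }
  unname(tab[key])
}

#' Stiff-rod geometry
#'
#' @param length_nm Rod length l (nm).
#' @param diameter_nm Rod diameter d (nm); must satisfy l > d > 0.
#' @return An object of class `rod_model`.
#' @export
rod_model <- function(length_nm, diameter_nm) {
  if (!is.numeric(length_nm) || !is.numeric(diameter_nm) ||
      diameter_nm <= 0 || length_nm <= diameter_nm) {
    stop("need rod length > diameter > 0")
  }
  structure(list(length_nm = length_nm, diameter_nm = diameter_nm),
            class = "rod_model")
}

diffusion_estimate <- function(D_um2_s, model, inputs) {
  structure(list(D_um2_s = D_um2_s, model = model, inputs = inputs),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> %s: D = %.3f um^2/s\n", x$model,
              x$D_um2_s))
  invisible(x)
}

#' Translational diffusion coefficient of a stiff rod
#'
#' End-corrected rigid-rod formula (Tirado–García de la Torre form):
#' D = kB T (ln p + nu(p)) / (3 pi eta l), with aspect ratio p = l/d and
#' end correction nu(p) = 0.312 + 0.565/p - 0.100/p^2. Valid for p > 2;
#' a warning is issued for 1 < p <= 2.
#'
#' @param rod A [rod_model()].
#' @param solvent A [solvent_conditions()].
#' @param nu_coefficients Coefficients (c0, c1, c2) of
#'   nu(p) = c0 + c1/p + c2/p^2, exposed so alternative end corrections can
#'   be used.
#' @return A `diffusion_estimate` (field `D_um2_s`, μm²/s).
#' @examples
#' rod_diffusion(rod_model(120, 2)) # ~18 um^2/s in water at 25 C
#' @export
rod_diffusion <- function(rod, solvent = solvent_conditions(),
                          nu_coefficients = c(0.312, 0.565, -0.100)) {
  stopifnot(inherits(rod, "rod_model"),
            inherits(solvent, "solvent_conditions"))
  p <- rod$length_nm / rod$diameter_nm
  if (p <= 1) stop("aspect ratio l/d = ", format(p), " <= 1: not a rod")
  if (p <= 2) warning("aspect ratio ", format(p),
                      " is below the validity domain (p > 2)")
  nu <- nu_coefficients[1] + nu_coefficients[2] / p +
    nu_coefficients[3] / p^2
  l_m <- rod$length_nm * 1e-9
  D_si <- KBOLTZ * solvent$temperature_K * (log(p) + nu) /
    (3 * pi * solvent$viscosity_Pa_s * l_m)
  diffusion_estimate(D_si * 1e12, "rod",
                     list(length_nm = rod$length_nm,
                          diameter_nm = rod$diameter_nm,
                          aspect_ratio = p,
                          nu_coefficients = nu_coefficients,
                          temperature_K = solvent$temperature_K,
                          viscosity_Pa_s = solvent$viscosity_Pa_s))
}

#' Stokes–Einstein diffusion coefficient of a sphere
#'
#' D = kB T / (6 pi eta R): the compact-limit comparator for a particle of
#' hydrodynamic radius R.
#'
#' @param hydrodynamic_radius_nm Radius in nm (> 0).
#' @param solvent A [solvent_conditions()].
#' @return A `diffusion_estimate` (μm²/s).
#' @export
sphere_diffusion <- function(hydrodynamic_radius_nm,
                             solvent = solvent_conditions()) {
  stopifnot(inherits(solvent, "solvent_conditions"))
  if (!is.numeric(hydrodynamic_radius_nm) || hydrodynamic_radius_nm <= 0) {
    stop("hydrodynamic radius must be positive")
  }
  R_m <- hydrodynamic_radius_nm * 1e-9
  D_si <- KBOLTZ * solvent$temperature_K /
    (6 * pi * solvent$viscosity_Pa_s * R_m)
  diffusion_estimate(D_si * 1e12, "sphere",
                     list(radius_nm = hydrodynamic_radius_nm,
                          temperature_K = solvent$temperature_K,
                          viscosity_Pa_s = solvent$viscosity_Pa_s))
}

#' Minimal-sphere radius of a globular protein from its mass
#'
#' R = 0.066 M^(1/3) nm with M in Da: the radius of the anhydrous minimal
#' sphere, useful as the compact-limit geometry for
#' [classify_conformation()].
#'
#' @param mass_da Molecular mass in Daltons.
#' @return Radius in nm.
#' @export
sphere_radius_from_mass <- function(mass_da) {
  if (!is.numeric(mass_da) || any(mass_da <= 0)) stop("mass must be positive")
  0.066 * mass_da^(1 / 3)
}

#' Classify a measured diffusion coefficient between rod and sphere limits
#'
#' Places a measured D on the flexibility axis between the rigid-rod limit
#' (f = 0) and the compact-sphere limit (f = 1):
#' f = (D_meas - D_rod) / (D_sphere - D_rod). Values outside `[0, 1]` are
#' reported clamped (with a flag). Verdict is "extended/semi-rigid" for
#' f below the threshold, "compact" otherwise.
#'
#' @param measured Measured D in μm²/s (or a `diffusion_estimate`).
#' @param rod A [rod_model()] for the extended limit.
#' @param compact_radius_nm Hydrodynamic radius (nm) for the compact limit.
#' @param solvent A [solvent_conditions()].
#' @param threshold Verdict threshold on f (default 0.5).
#' @return List with `index` (clamped f), `index_raw`, `clamped`, `verdict`,
#'   `D_measured_um2_s`, `D_rod_um2_s`, `D_sphere_um2_s`.
#' @examples
#' classify_conformation(25, rod_model(120, 2), compact_radius_nm = 4.55)
#' @export
classify_conformation <- function(measured, rod, compact_radius_nm,
                                  solvent = solvent_conditions(),
                                  threshold = 0.5) {
  D_meas <- if (inherits(measured, "diffusion_estimate")) measured$D_um2_s
            else measured
  if (!is.numeric(D_meas) || length(D_meas) != 1L || D_meas <= 0) {
    stop("measured D must be a single positive number")
  }
  D_rod <- rod_diffusion(rod, solvent)$D_um2_s
  D_sph <- sphere_diffusion(compact_radius_nm, solvent)$D_um2_s
  if (D_rod >= D_sph) {
    stop("inconsistent models: D_rod (", format(D_rod),
         ") >= D_sphere (", format(D_sph), ")")
  }
  f_raw <- (D_meas - D_rod) / (D_sph - D_rod)
  f <- min(max(f_raw, 0), 1)
  list(index = f,
       index_raw = f_raw,
       clamped = !identical(f, f_raw),
       verdict = if (f < threshold) "extended/semi-rigid" else "compact",
       D_measured_um2_s = D_meas,
       D_rod_um2_s = D_rod,
       D_sphere_um2_s = D_sph)
}
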