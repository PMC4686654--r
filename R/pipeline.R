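# Pipeline: compose prediction, ruler arithmetic, hydrodynamics and
# construct design into a deterministic "ruler report", plus the
# fold-difference worked-example utility.

CONFIG_VERSION <- "1"

config_defaults <- function() {
  list(
    config_version = CONFIG_VERSION,
    rise_per_residue = 1.46,        # Å per residue
    window = 28,                    # predictor window (residues)
    threshold = 0.5,                # segment-calling probability
    min_len = 21,                   # minimum segment length (residues)
    merge_gap = 7,                  # merge runs closer than this (residues)
    rod_diameter_nm = 2,            # canonical coiled-coil diameter
    temperature_K = 298.15,
    viscosity_Pa_s = 8.9e-4,
    nu_coefficients = c(0.312, 0.565, -0.100),
    w0_um = 0.2,                    # confocal lateral waist
    structure_parameter = 5,
    end_allowance_kinase_nm = 7,    # kinase-dimer end domain
    end_allowance_regulatory_nm = 6,  # C1/PH regulatory end
    truncation_targets_nm = c(2, 5, 10, 20, 30, 60),
    design_mode = "heptad",
    anchor_start = NULL             # default: start of the longest segment
  )
}

#' Pipeline configuration
#'
#' A single validated configuration document holding every tunable constant
#' of the ruler report; unknown keys are errors (typo protection), and all
#' constants are echoed in the report's provenance block. The end-domain
#' allowances model the globular kinase-dimer and regulatory ends that,
#' added to the coiled-coil, give the full particle length.
#'
#' @param ... Named overrides of the defaults (see
#'   `ccruler:::config_defaults()`): `rise_per_residue`, `window`,
#'   `threshold`, `min_len`, `merge_gap`, `rod_diameter_nm`,
#'   `temperature_K`, `viscosity_Pa_s`, `nu_coefficients`, `w0_um`,
#'   `structure_parameter`, `end_allowance_kinase_nm`,
#'   `end_allowance_regulatory_nm`, `truncation_targets_nm`,
#'   `design_mode`, `anchor_start`.
#' @return An object of class `ruler_config`.
#' @export
ruler_config <- function(...) {
  cfg <- config_defaults()
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots))))) {
    stop("all config entries must be named")
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (!identical(as.character(cfg$config_version), CONFIG_VERSION)) {
    stop("unsupported config_version: ", cfg$config_version)
  }
  if (!cfg$design_mode %in% c("heptad", "exact")) {
    stop("design_mode must be 'heptad' or 'exact'")
  }
  structure(cfg, class = "ruler_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path (`.json` parsed as JSON, anything else as YAML).
#' @return A validated [ruler_config()].
#' @export
read_ruler_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(ruler_config, vals)
}

#' Generate a ruler report for a sequence
#'
#' Runs the full analysis chain: coiled-coil prediction, residue-to-nm
#' conversion, full-particle length (coil plus the two end-domain
#' allowances), rigid-rod diffusion for that geometry, and a truncation
#' design table for the configured nanometre targets. Any stage failure is
#' reported with the stage name attached. The report is deterministic:
#' repeated runs on the same input and config serialize byte-identically.
#'
#' @param sequence Amino-acid string, or a named character vector as
#'   returned by [read_fasta()] (the first entry is used).
#' @param config A [ruler_config()].
#' @param id Identifier for the report (defaults to the sequence name, or
#'   `"query"`).
#' @return An object of class `ruler_report`.
#' @export
ruler_report <- function(sequence, config = ruler_config(), id = NULL) {
  stopifnot(inherits(config, "ruler_config"))
  if (length(sequence) == 0L) stop_stage("input", "no sequence supplied")
  if (is.null(id)) id <- names(sequence)[1] %||% "query"
  sequence <- as.character(sequence[[1]])
  if (is.na(sequence) || !nzchar(sequence)) {
    stop_stage("input", "empty sequence")
  }
  params <- ruler_params(config$rise_per_residue)
  table <- default_propensity_table(window = config$window)

  assignment <- tryCatch(
    score_sequence(sequence, table),
    error = function(e) stop_stage("predict", conditionMessage(e)))
  segments <- tryCatch(
    call_segments(assignment, threshold = config$threshold,
                  min_len = config$min_len, merge_gap = config$merge_gap),
    error = function(e) stop_stage("predict", conditionMessage(e)))
  coil_nm <- tryCatch(
    predicted_cc_length(segments, params),
    error = function(e) stop_stage("length", conditionMessage(e)))
  particle_nm <- coil_nm + config$end_allowance_kinase_nm +
    config$end_allowance_regulatory_nm

  solvent <- solvent_conditions(config$temperature_K, config$viscosity_Pa_s)
  rod_D <- tryCatch({
    if (particle_nm > config$rod_diameter_nm) {
      rod_diffusion(rod_model(particle_nm, config$rod_diameter_nm),
                    solvent, nu_coefficients = config$nu_coefficients)$D_um2_s
    } else {
      NA_real_
    }
  }, error = function(e) stop_stage("hydrodynamics", conditionMessage(e)))

  designs <- tryCatch({
    anchor <- config$anchor_start %||% (
      if (nrow(segments)) segments$start[which.max(segments$n_residues)]
      else 1L)
    construct_table(lapply(config$truncation_targets_nm, function(t) {
      d <- design_truncation(t, anchor, mode = config$design_mode,
                             params = params)
      d$name <- sprintf("d%gnm", t)
      d
    }))
  }, error = function(e) stop_stage("design", conditionMessage(e)))

  structure(list(
    id = id,
    n_residues = nchar(sequence),
    segments = as.data.frame(segments),
    predicted_cc_length_nm = coil_nm,
    full_particle_length_nm = particle_nm,
    rod_diffusion_um2_s = rod_D,
    truncation_designs = designs,
    provenance = list(
      package = "ccruler",
      package_version = as.character(utils::packageVersion("ccruler")),
      propensity_table = table$version,
      config = unclass(config),
      kB_J_per_K = KBOLTZ
    )
  ), class = "ruler_report")
}

#' @export
print.ruler_report <- function(x, ...) {
  cat(sprintf("<ruler_report> %s (%d aa)\n", x$id, x$n_residues))
  cat(sprintf("  predicted coiled-coil: %.2f nm over %d segment(s)\n",
              x$predicted_cc_length_nm, nrow(x$segments)))
  cat(sprintf("  full particle: %.2f nm; rod D = %.2f um^2/s\n",
              x$full_particle_length_nm, x$rod_diffusion_um2_s))
  cat(sprintf("  %d truncation design(s)\n", nrow(x$truncation_designs)))
  invisible(x)
}

#' Serialize a ruler report as deterministic JSON
#'
#' @param report A `ruler_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string, or `path` invisibly.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ruler_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

AFFINITY_UNITS <- c(M = 1, mM = 1e-3, uM = 1e-6, "μM" = 1e-6,
                    nM = 1e-9, pM = 1e-12)

#' Fold difference between two affinities (or any positive quantities)
#'
#' Reports larger/smaller as an exact ratio and as the nearest integer
#' fold. Values may carry units (e.g. `"nM"`, `"uM"`), which are converted
#' before comparison.
#'
#' @param value_a,value_b Positive values.
#' @param units Optional length-2 character vector of units for the two
#'   values (same unit system; see names of `ccruler:::AFFINITY_UNITS`).
#' @return List of class `fold_difference` with `exact`, `fold`,
#'   `larger`, `smaller` (values in common units).
#' @examples
#' fold_difference(21.2, 354, units = c("uM", "nM")) # 59.89 exact, 60-fold
#' @export
fold_difference <- function(value_a, value_b, units = NULL) {
  if (!is.numeric(value_a) || !is.numeric(value_b) ||
      length(value_a) != 1L || length(value_b) != 1L ||
      !is.finite(value_a) || !is.finite(value_b) ||
      value_a <= 0 || value_b <= 0) {
    stop("both values must be single positive numbers")
  }
  if (!is.null(units)) {
    if (length(units) != 2L || !all(units %in% names(AFFINITY_UNITS))) {
      stop("unit mismatch: units must be two of ",
           paste(unique(names(AFFINITY_UNITS)), collapse = ", "))
    }
    value_a <- value_a * AFFINITY_UNITS[[units[1]]]
    value_b <- value_b * AFFINITY_UNITS[[units[2]]]
  }
  larger <- max(value_a, value_b)
  smaller <- min(value_a, value_b)
  exact <- larger / smaller
  structure(list(exact = exact,
                 fold = as.integer(round_half_away(exact)),
                 larger = larger, smaller = smaller),
            class = "fold_difference")
}

#' @export
print.fold_difference <- function(x, ...) {
  cat(sprintf("<fold_difference> %.4g-fold (exact %.4f)\n", x$fold, x$exact))
  invisible(x)
}

#' Splice points of the ROCK2/Rok coiled-coil swap chimera
#'
#' Fixture table recording the segment boundaries of the published chimera
#' (human kinase + insect coiled-coil + human regulatory domains); no
#' splice-point optimization is performed.
#'
#' @return A data.frame with columns `segment`, `source`, `start`, `end`.
#' @export
rock2_chimera_segments <- function() {
  path <- system.file("extdata", "rock2_rok_chimera.tsv",
                      package = "ccruler")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
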