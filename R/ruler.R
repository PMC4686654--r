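#' Ruler parameters: the helical rise of a canonical coiled-coil
#'
#' A canonical parallel two-stranded coiled-coil rises 1.46 Å along its
#' superhelical axis per residue. This single constant converts residue
#' counts into physical lengths and underpins all construct design in the
#' package. It is configurable to allow sensitivity analysis (e.g. for
#' non-canonical pitch).
#'
#' @param rise_per_residue Axial rise per residue in Ångström (default 1.46).
#' @return An object of class `ruler_params`.
#' @examples
#' p <- ruler_params()
#' residues_to_length(730, p) # ~106.6 nm
#' @export
ruler_params <- function(rise_per_residue = 1.46) {
  if (!is.numeric(rise_per_residue) || length(rise_per_residue) != 1L ||
      !is.finite(rise_per_residue) || rise_per_residue <= 0) {
    stop("rise_per_residue must be a single positive number (Å)")
  }
  structure(list(rise_per_residue = rise_per_residue), class = "ruler_params")
}

# rise in nm per residue
rise_nm <- function(params) params$rise_per_residue / 10

#' Convert a residue count to coiled-coil length in nanometres
#'
#' @param n_residues Non-negative residue count (vectorised).
#' @param params A [ruler_params()] object.
#' @return Length(s) in nm.
#' @examples
#' residues_to_length(730) # 106.58 nm
#' @export
residues_to_length <- function(n_residues, params = ruler_params()) {
  stopifnot(inherits(params, "ruler_params"))
  if (!is.numeric(n_residues) || any(!is.finite(n_residues)) ||
      any(n_residues < 0)) {
    stop("n_residues must be non-negative")
  }
  n_residues * rise_nm(params)
}

#' Nominal integer nanometre label for a designed shortening
#'
#' Truncation constructs are conventionally labelled by their designed
#' shortening rounded to the nearest integer nanometre; halves round away
#' from zero (2.044 nm -> 2; 4.672 nm -> 5).
#'
#' @param length_nm Non-negative length in nm (vectorised).
#' @return Integer nm label(s).
#' @export
nominal_label <- function(length_nm) {
  if (!is.numeric(length_nm) || any(!is.finite(length_nm)) ||
      any(length_nm < 0)) {
    stop("length_nm must be non-negative")
  }
  as.integer(round_half_away(length_nm))
}

#' Describe a deletion construct from its residue range
#'
#' Residue ranges are 1-based and inclusive throughout the package, matching
#' the conventional "Δ440–453" notation: the deletion removes both
#' endpoints, so the residue count is `end - start + 1`.
#'
#' @param del_start,del_end First and last deleted residue (1-based,
#'   inclusive).
#' @param name Optional construct name; defaults to
#'   `"d<start>-<end>"`.
#' @param params A [ruler_params()] object.
#' @return An object of class `construct_design` with fields `name`,
#'   `del_start`, `del_end`, `n_deleted`, `shortening_nm`, `nominal_nm`,
#'   `register_preserved` (TRUE when `n_deleted` is a multiple of 7, i.e.
#'   the heptad phase downstream of the deletion is unchanged).
#' @examples
#' construct_design(440, 849) # the 60 nm deletion
#' @export
construct_design <- function(del_start, del_end, name = NULL,
                             params = ruler_params()) {
  stopifnot(inherits(params, "ruler_params"))
  if (!is.numeric(del_start) || !is.numeric(del_end) ||
      length(del_start) != 1L || length(del_end) != 1L ||
      del_start < 1 || del_end < del_start ||
      del_start != round(del_start) || del_end != round(del_end)) {
    stop("need integer residue indices with 1 <= del_start <= del_end")
  }
  n <- del_end - del_start + 1
  shortening <- residues_to_length(n, params)
  structure(list(
    name = name %||% sprintf("d%d-%d", as.integer(del_start),
                             as.integer(del_end)),
    del_start = as.integer(del_start),
    del_end = as.integer(del_end),
    n_deleted = as.integer(n),
    shortening_nm = shortening,
    nominal_nm = nominal_label(shortening),
    register_preserved = (n %% 7) == 0
  ), class = "construct_design")
}

#' @export
print.construct_design <- function(x, ...) {
  cat(sprintf(
    "<construct_design> %s: Δ%d–%d (%d aa, %.3f nm, Δ%d nm, register %s)\n",
    x$name, x$del_start, x$del_end, x$n_deleted, x$shortening_nm,
    x$nominal_nm, if (x$register_preserved) "preserved" else "shifted"))
  invisible(x)
}

#' Design a coiled-coil truncation for a target shortening
#'
#' Chooses the number of residues to delete so the physical shortening of
#' the coiled-coil is as close as possible to `target_nm`, anchored at
#' `anchor_start`. In `"heptad"` mode (default) the deletion size is
#' restricted to multiples of 7 so the heptad register downstream of the
#' junction is preserved; in `"exact"` mode any residue count is allowed.
#'
#' @param target_nm Desired shortening in nm (> half a residue rise).
#' @param anchor_start First deleted residue (1-based).
#' @param mode `"heptad"` or `"exact"`.
#' @param params A [ruler_params()] object.
#' @return A [construct_design()] object.
#' @examples
#' design_truncation(2, 440)            # 14 residues: d440-453
#' design_truncation(10, 440)           # 70 residues: d440-509
#' design_truncation(60, 440, "exact")  # 411 residues
#' @export
design_truncation <- function(target_nm, anchor_start,
                              mode = c("heptad", "exact"),
                              params = ruler_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "ruler_params"))
  r <- rise_nm(params)
  if (!is.numeric(target_nm) || length(target_nm) != 1L ||
      !is.finite(target_nm) || target_nm < r / 2) {
    stop("target_nm must be at least half a residue rise (",
         format(r / 2), " nm)")
  }
  if (!is.numeric(anchor_start) || length(anchor_start) != 1L ||
      anchor_start < 1 || anchor_start != round(anchor_start)) {
    stop("anchor_start must be a residue index >= 1")
  }
  n <- if (mode == "exact") {
    max(1, round_half_away(target_nm / r))
  } else {
    k_lo <- max(1, floor(target_nm / (7 * r)))
    k_hi <- k_lo + 1
    # ties broken towards the smaller deletion
    if (abs(k_hi * 7 * r - target_nm) < abs(k_lo * 7 * r - target_nm)) {
      7 * k_hi
    } else {
      7 * k_lo
    }
  }
  d <- construct_design(anchor_start, anchor_start + n - 1, params = params)
  d$target_nm <- target_nm
  d$mode <- mode
  d
}

#' Remaining coiled-coil length after a deletion
#'
#' @param full_cc_residues Residue count of the intact coiled-coil.
#' @param design A [construct_design()] object (or a bare residue count to
#'   delete).
#' @param params A [ruler_params()] object.
#' @return Remaining length in nm.
#' @examples
#' remaining_length(730, construct_design(440, 849)) # 46.72 nm
#' @export
remaining_length <- function(full_cc_residues, design,
                             params = ruler_params()) {
  n_del <- if (inherits(design, "construct_design")) design$n_deleted
           else design
  if (!is.numeric(n_del) || length(n_del) != 1L || n_del < 0) {
    stop("design must be a construct_design or a non-negative count")
  }
  if (n_del > full_cc_residues) {
    stop("deletion (", n_del, " aa) exceeds the coiled-coil (",
         full_cc_residues, " aa)")
  }
  residues_to_length(full_cc_residues - n_del, params)
}

#' The six ROCK2 coiled-coil truncation constructs
#'
#' The published deletion series that shortens the human ROCK2 coiled-coil
#' in calibrated nanometre steps, shipped as a fixture table (residue
#' endpoints as reported; derived columns recomputed by the ruler).
#'
#' @param params A [ruler_params()] object.
#' @return A data.frame with columns `name`, `del_start`, `del_end`,
#'   `n_deleted`, `shortening_nm`, `nominal_nm`, `register_ok`.
#' @export
rock2_constructs <- function(params = ruler_params()) {
  path <- system.file("extdata", "rock2_constructs.tsv", package = "ccruler")
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  designs <- lapply(seq_len(nrow(raw)), function(i) {
    construct_design(raw$del_start[i], raw$del_end[i], name = raw$name[i],
                     params = params)
  })
  construct_table(designs)
}

#' Assemble construct designs into a table
#'
#' @param designs A list of [construct_design()] objects.
#' @return A data.frame with one row per design.
#' @export
construct_table <- function(designs) {
  stopifnot(length(designs) > 0,
            all(vapply(designs, inherits, TRUE, "construct_design")))
  data.frame(
    name = vapply(designs, `[[`, "", "name"),
    del_start = vapply(designs, `[[`, 1L, "del_start"),
    del_end = vapply(designs, `[[`, 1L, "del_end"),
    n_deleted = vapply(designs, `[[`, 1L, "n_deleted"),
    shortening_nm = vapply(designs, `[[`, 1, "shortening_nm"),
    nominal_nm = vapply(designs, `[[`, 1L, "nominal_nm"),
    register_ok = vapply(designs, `[[`, TRUE, "register_preserved"),
    stringsAsFactors = FALSE
  )
}

#' Read / write construct tables as TSV
#'
#' @param path File path.
#' @param table A data.frame as produced by [construct_table()].
#' @return `read_construct_table` returns the data.frame;
#'   `write_construct_table` returns `path` invisibly.
#' @export
read_construct_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "del_start", "del_end", "n_deleted", "shortening_nm",
            "nominal_nm", "register_ok")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("construct table missing columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_construct_table
#' @export
write_construct_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
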