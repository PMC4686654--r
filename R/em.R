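# Contour-length morphometry of digitized EM particle traces.
#
# Traces are ordered 2D point lists in nm (pixel -> nm scaling is applied
# upstream or via scale_trace()). By convention input traces span the
# coiled-coil only — globular end lobes are excluded by the tracer — so the
# contour length is the coiled-coil length. Lengths are measured
# curvilinearly (polyline sum), not end-to-end.

#' A digitized particle trace
#'
#' @param x,y Point coordinates in nm (finite, equal length).
#' @param id Particle identifier.
#' @return An object of class `particle_trace`.
#' @export
particle_trace <- function(x, y, id = "particle") {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 1L || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite numeric vectors of equal length >= 1")
  }
  structure(list(id = as.character(id), x = x, y = y),
            class = "particle_trace")
}

as_trace_xy <- function(trace) {
  if (inherits(trace, "particle_trace")) {
    cbind(trace$x, trace$y)
  } else if (is.matrix(trace) && ncol(trace) == 2L) {
    trace
  } else if (is.data.frame(trace) && all(c("x", "y") %in% names(trace))) {
    cbind(trace$x, trace$y)
  } else {
    stop("trace must be a particle_trace, a 2-column matrix, ",
         "or a data.frame with x and y")
  }
}

#' Contour length of a particle trace
#'
#' Sum of Euclidean segment lengths along the ordered polyline. Duplicate
#' consecutive points contribute zero; fewer than 2 points is an error.
#'
#' @param trace A [particle_trace()], 2-column matrix, or data.frame with
#'   `x`/`y` (nm).
#' @return Contour length in nm.
#' @examples
#' contour_length(particle_trace(c(0, 3), c(0, 4))) # 5
#' @export
contour_length <- function(trace) {
  xy <- as_trace_xy(trace)
  if (nrow(xy) < 2L) stop("need at least 2 points to measure a trace")
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Summarize an ensemble of particle lengths
#'
#' @param lengths Numeric vector of particle lengths (nm), n >= 1.
#' @return An object of class `length_summary` with `n`, `mean_nm`,
#'   `sd_nm` (sample s.d., n-1 denominator; `NA` when n = 1) and the
#'   individual `lengths_nm`.
#' @export
summarize_lengths <- function(lengths) {
  if (!is.numeric(lengths) || length(lengths) < 1L ||
      any(!is.finite(lengths))) {
    stop("lengths must be a non-empty finite numeric vector")
  }
  structure(list(
    n = length(lengths),
    mean_nm = mean(lengths),
    sd_nm = if (length(lengths) >= 2L) stats::sd(lengths) else NA_real_,
    lengths_nm = lengths
  ), class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("<length_summary> %.1f +/- %s nm (n = %d)\n", x$mean_nm,
              if (is.na(x$sd_nm)) "NA" else sprintf("%.1f", x$sd_nm), x$n))
  invisible(x)
}

#' Apply a scalar nm-per-pixel calibration to a trace
#'
#' @param trace A [particle_trace()] in pixel units.
#' @param nm_per_pixel Positive scale factor.
#' @return A [particle_trace()] in nm.
#' @export
scale_trace <- function(trace, nm_per_pixel) {
  stopifnot(inherits(trace, "particle_trace"))
  if (!is.numeric(nm_per_pixel) || nm_per_pixel <= 0) {
    stop("nm_per_pixel must be positive")
  }
  particle_trace(trace$x * nm_per_pixel, trace$y * nm_per_pixel, trace$id)
}

#' Read / write particle traces as CSV
#'
#' Long format with columns `particle_id`, `point_index`, `x_nm`, `y_nm`;
#' points are ordered by `point_index` within each particle.
#'
#' @param path File path.
#' @param traces List of [particle_trace()] objects.
#' @return `read_trace_csv` returns a named list of [particle_trace()].
#' @export
read_trace_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("particle_id", "point_index", "x_nm", "y_nm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trace CSV missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(tab, tab$particle_id), function(d) {
    d <- d[order(d$point_index), ]
    particle_trace(d$x_nm, d$y_nm, id = d$particle_id[1])
  })
  out[order(names(out))]
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(is.list(traces),
            all(vapply(traces, inherits, TRUE, "particle_trace")))
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(particle_id = tr$id,
               point_index = seq_along(tr$x),
               x_nm = tr$x, y_nm = tr$y,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
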