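# Sliding-window heptad-propensity coiled-coil prediction.
#
# A window of fixed length is slid along the sequence in each of the seven
# possible heptad frames; the window score is the geometric mean of the
# per-residue propensities at their assigned heptad positions. Each residue
# takes the best score over all windows/frames covering it, and the score is
# converted to a probability by a two-population (coiled-coil vs globular)
# Gaussian ratio, as in classic heptad-propensity predictors.

predictor_env <- new.env(parent = emptyenv())

HEPTAD_POSITIONS <- c("a", "b", "c", "d", "e", "f", "g")

#' Construct a heptad propensity table
#'
#' @param propensities A 20 x 7 numeric matrix (rows named by one-letter
#'   amino-acid codes, columns `a`–`g`) of strictly positive relative
#'   propensities.
#' @param window Sliding-window length in residues (>= 7; default 28, the
#'   standard choice for long coiled-coil detection).
#' @param calibration List with `cc_mean`, `cc_sd`, `bg_mean`, `bg_sd`: the
#'   location/scale of the Gaussian score populations for coiled-coil and
#'   globular sequence used to convert scores to probabilities.
#' @param version Free-text version label echoed in provenance.
#' @return An object of class `propensity_table`.
#' @export
propensity_table <- function(propensities, window = 28,
                             calibration = list(cc_mean = 1.60,
                                                cc_sd = 0.15,
                                                bg_mean = 0.90,
                                                bg_sd = 0.15),
                             version = "custom") {
  if (!is.matrix(propensities) || ncol(propensities) != 7L ||
      nrow(propensities) < 20L || is.null(rownames(propensities))) {
    stop("propensities must be a matrix with >= 20 named rows and 7 columns")
  }
  if (any(!is.finite(propensities)) || any(propensities <= 0)) {
    stop("all propensities must be finite and > 0")
  }
  if (!is.numeric(window) || length(window) != 1L || window < 7) {
    stop("window must be >= 7")
  }
  need <- c("cc_mean", "cc_sd", "bg_mean", "bg_sd")
  if (!all(need %in% names(calibration))) {
    stop("calibration must supply ", paste(need, collapse = ", "))
  }
  colnames(propensities) <- HEPTAD_POSITIONS
  structure(list(propensities = propensities,
                 window = as.integer(window),
                 calibration = calibration,
                 version = version),
            class = "propensity_table")
}

#' The packaged default propensity table
#'
#' Loads the versioned propensity file shipped with the package (a curated
#' synthetic table encoding canonical heptad-position preferences; see the
#' file header in `extdata/cc_propensity_v1.tsv`).
#'
#' @param window Sliding-window length (default 28).
#' @return A [propensity_table()].
#' @export
default_propensity_table <- function(window = 28) {
  key <- paste0("default_", window)
  if (!is.null(predictor_env[[key]])) return(predictor_env[[key]])
  path <- system.file("extdata", "cc_propensity_v1.tsv", package = "ccruler")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, HEPTAD_POSITIONS])
  rownames(m) <- tab$aa
  out <- propensity_table(m, window = window, version = "cc_propensity_v1")
  predictor_env[[key]] <- out
  out
}

# score -> probability via the two-population Gaussian ratio, computed on
# the log-density scale so extreme scores do not underflow to NaN
score_to_probability <- function(score, calib) {
  lcc <- stats::dnorm(score, calib$cc_mean, calib$cc_sd, log = TRUE)
  lbg <- stats::dnorm(score, calib$bg_mean, calib$bg_sd, log = TRUE)
  1 / (1 + exp(lbg - lcc))
}

#' Score a protein sequence for coiled-coil propensity
#'
#' Slides a window over the sequence in all seven heptad frames. The score
#' of a window in a frame is the geometric mean of the residue propensities
#' at their assigned heptad positions; each residue reports the best score
#' over every window/frame covering it (residues near the termini take the
#' max over the windows that do cover them — no padding). Probabilities come
#' from the table's two-population calibration.
#'
#' @param sequence Character scalar (or `Biostrings::AAString`) of standard
#'   one-letter amino-acid codes; `X` is treated as neutral (propensity 1).
#' @param table A [propensity_table()].
#' @return A data.frame of class `heptad_assignment` with columns `index`,
#'   `aa`, `score`, `frame` (0–6: the heptad phase of the best-scoring
#'   window, such that heptad position of residue i is
#'   `((i - 1 + frame) mod 7) + 1` = a..g), `probability`.
#' @examples
#' a <- score_sequence(strrep("LAALEKE", 8))
#' mean(a$probability > 0.9)
#' @export
score_sequence <- function(sequence, table = default_propensity_table()) {
  stopifnot(inherits(table, "propensity_table"))
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single string")
  }
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  W <- table$window
  if (L == 0L) stop("empty sequence")
  if (L < W) stop("sequence (", L, " aa) shorter than window (", W, " aa)")

  known <- rownames(table$propensities)
  bad <- which(!(chars %in% c(known, "X")))
  if (length(bad)) {
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1]],
                 bad[1]))
  }
  # log-propensity matrix, with a neutral all-zero row for X
  logp <- rbind(log(table$propensities),
                X = rep(0, 7))
  aa_idx <- match(chars, rownames(logp))

  n_win <- L - W + 1L
  best_score <- rep(-Inf, L)
  best_frame <- integer(L)
  for (f in 0:6) {
    pos <- ((seq_len(L) - 1L + f) %% 7L) + 1L
    lp <- logp[cbind(aa_idx, pos)]
    cs <- c(0, cumsum(lp))
    win <- (cs[(W + 1):(L + 1)] - cs[1:n_win]) / W  # mean log over window
    for (i in seq_len(L)) {
      lo <- max(1L, i - W + 1L)
      hi <- min(i, n_win)
      m <- max(win[lo:hi])
      if (m > best_score[i]) {
        best_score[i] <- m
        best_frame[i] <- f
      }
    }
  }
  score <- exp(best_score)
  out <- data.frame(
    index = seq_len(L),
    aa = chars,
    score = score,
    frame = best_frame,
    probability = score_to_probability(score, table$calibration),
    stringsAsFactors = FALSE
  )
  class(out) <- c("heptad_assignment", "data.frame")
  attr(out, "window") <- W
  attr(out, "table_version") <- table$version
  out
}

#' Call coiled-coil segments from a per-residue assignment
#'
#' Maximal runs of residues with probability at or above `threshold`; runs
#' separated by fewer than `merge_gap` sub-threshold residues are merged,
#' then merged runs shorter than `min_len` are discarded.
#'
#' @param assignment A `heptad_assignment` (or any data.frame with columns
#'   `index`, `probability` and optionally `frame`).
#' @param threshold Calling probability threshold in (0, 1); default 0.5.
#' @param min_len Minimum segment length in residues (default 21, three
#'   heptads — shorter hits are unreliable for long-coil detection).
#' @param merge_gap Runs separated by fewer than this many residues are
#'   merged (default 7, one heptad: short stutters do not break a coil).
#' @return A data.frame of class `cc_segments` with columns `start`, `end`
#'   (1-based inclusive), `n_residues`, `mean_probability`, `frame` (modal
#'   frame over the segment).
#' @export
call_segments <- function(assignment, threshold = 0.5, min_len = 21,
                          merge_gap = 7) {
  if (!is.data.frame(assignment) ||
      !all(c("index", "probability") %in% names(assignment))) {
    stop("assignment must have columns index and probability")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)")
  }
  empty <- data.frame(start = integer(), end = integer(),
                      n_residues = integer(), mean_probability = numeric(),
                      frame = integer())
  class(empty) <- c("cc_segments", "data.frame")
  if (nrow(assignment) == 0L) return(empty)

  ord <- order(assignment$index)
  idx <- assignment$index[ord]
  prob <- assignment$probability[ord]
  frame <- if ("frame" %in% names(assignment)) assignment$frame[ord]
           else rep(NA_integer_, length(idx))

  above <- prob >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = idx[starts[r$values]],
                     end = idx[ends[r$values]])
  # merge runs separated by < merge_gap sub-threshold residues
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged$n_residues <- merged$end - merged$start + 1L
  merged <- merged[merged$n_residues >= min_len, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)

  merged$mean_probability <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- idx >= merged$start[i] & idx <= merged$end[i]
    mean(prob[sel])
  }, 1)
  merged$frame <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- idx >= merged$start[i] & idx <= merged$end[i]
    fr <- frame[sel]
    fr <- fr[!is.na(fr)]
    if (!length(fr)) return(NA_integer_)
    tab <- table(fr)
    as.integer(names(tab)[which.max(tab)])  # ties -> smallest frame
  }, 1L)
  rownames(merged) <- NULL
  class(merged) <- c("cc_segments", "data.frame")
  merged
}

#' Total predicted coiled-coil length of called segments
#'
#' @param segments A `cc_segments` data.frame (columns `start`, `end`).
#' @param params A [ruler_params()] object.
#' @return Summed segment length in nm.
#' @examples
#' segs <- data.frame(start = 1, end = 730)
#' predicted_cc_length(segs) # 106.58 nm
#' @export
predicted_cc_length <- function(segments, params = ruler_params()) {
  if (!is.data.frame(segments) ||
      !all(c("start", "end") %in% names(segments))) {
    stop("segments must have columns start and end")
  }
  if (nrow(segments) == 0L) return(0)
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1 &&
      any(segments$start[-1] <= segments$end[-nrow(segments)])) {
    stop("segments overlap")
  }
  residues_to_length(sum(segments$end - segments$start + 1), params)
}

#' Write per-residue scores / called segments as TSV
#'
#' `write_scores_tsv` writes the per-residue table (index, aa, score, frame,
#' probability). `write_segments_tsv` writes segments with 1-based inclusive
#' coordinates by default (matching residue notation); `bed = TRUE` emits
#' 0-based half-open BED3+ instead.
#'
#' @param assignment A `heptad_assignment`.
#' @param segments A `cc_segments` data.frame.
#' @param name Sequence name used in the BED-like first column.
#' @param path Output file path.
#' @param bed Emit true BED coordinates (0-based half-open)?
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
write_segments_tsv <- function(segments, path, name = "seq", bed = FALSE) {
  df <- as.data.frame(segments)
  out <- data.frame(name = rep(name, nrow(df)),
                    start = if (bed) df$start - 1L else df$start,
                    end = df$end,
                    n_residues = df$n_residues,
                    mean_probability = df$mean_probability,
                    frame = df$frame)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings returning plain named character vectors;
#' output wraps lines at 80 characters.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
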