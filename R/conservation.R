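# Cross-orthologue coiled-coil length-conservation analysis: per-sequence
# predicted lengths, grouped summaries, and pairwise sequence identity to
# show that length conservation is decoupled from sequence conservation.

#' Predicted coiled-coil length for every member of an orthologue family
#'
#' Runs the heptad predictor on each record and sums the called segments.
#' Records failing prediction preconditions (e.g. shorter than the scoring
#' window) are flagged in the output, not dropped.
#'
#' @param records A data.frame with columns `id`, `sequence`, and optionally
#'   `taxon` (free-text group label).
#' @param table A [propensity_table()].
#' @param params A [ruler_params()].
#' @param threshold,min_len,merge_gap Segment-calling parameters, see
#'   [call_segments()].
#' @return A data.frame with one row per record: `id`, `taxon`, `length_nm`,
#'   `n_segments`, `coil_start`, `coil_end` (span of the longest segment),
#'   `ok`, `note`.
#' @export
family_length_table <- function(records,
                                table = default_propensity_table(),
                                params = ruler_params(),
                                threshold = 0.5, min_len = 21,
                                merge_gap = 7) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records))) {
    stop("records must be a data.frame with columns id and sequence")
  }
  if (nrow(records) < 1L) stop("need at least one record")
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  if (any(!nzchar(records$sequence))) stop("empty sequence in records")
  taxon <- if ("taxon" %in% names(records)) records$taxon
           else rep("all", nrow(records))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    res <- tryCatch({
      a <- score_sequence(records$sequence[i], table)
      segs <- call_segments(a, threshold = threshold, min_len = min_len,
                            merge_gap = merge_gap)
      len <- predicted_cc_length(segs, params)
      if (nrow(segs)) {
        main <- which.max(segs$n_residues)
        list(len = len, nseg = nrow(segs),
             cs = segs$start[main], ce = segs$end[main],
             ok = TRUE, note = "")
      } else {
        list(len = 0, nseg = 0L, cs = NA_integer_, ce = NA_integer_,
             ok = TRUE, note = "no segment called")
      }
    }, error = function(e) {
      list(len = NA_real_, nseg = NA_integer_, cs = NA_integer_,
           ce = NA_integer_, ok = FALSE, note = conditionMessage(e))
    })
    data.frame(id = records$id[i], taxon = taxon[i],
               length_nm = res$len, n_segments = res$nseg,
               coil_start = res$cs, coil_end = res$ce,
               ok = res$ok, note = res$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize length conservation across a family
#'
#' Sample (n-1) standard deviations, matching conventional "mean ± s.d."
#' reporting; groups with a single member report the s.d. as `NA`, never 0.
#'
#' @param table Output of [family_length_table()] (rows with `ok = FALSE`
#'   or `NA` lengths are excluded with a warning).
#' @param group_col Column holding the group label (default `"taxon"`).
#' @return An object of class `conservation_summary`: `per_group`
#'   data.frame (`group`, `n`, `mean_nm`, `sd_nm`) and `overall` list
#'   (`n`, `mean_nm`, `sd_nm`).
#' @export
summarize_conservation <- function(table, group_col = "taxon") {
  if (!is.data.frame(table) || !"length_nm" %in% names(table)) {
    stop("table must be a family length table with a length_nm column")
  }
  if (!group_col %in% names(table)) {
    table[[group_col]] <- "all"
  }
  usable <- !is.na(table$length_nm)
  if (!all(usable)) {
    warning(sum(!usable), " record(s) without a length were excluded")
  }
  tab <- table[usable, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no usable lengths")
  groups <- split(tab$length_nm, tab[[group_col]])
  per_group <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    mean_nm = vapply(groups, mean, 1),
    sd_nm = vapply(groups, function(v) {
      if (length(v) >= 2L) stats::sd(v) else NA_real_
    }, 1),
    stringsAsFactors = FALSE
  )
  rownames(per_group) <- NULL
  structure(list(
    per_group = per_group,
    overall = list(n = nrow(tab),
                   mean_nm = mean(tab$length_nm),
                   sd_nm = if (nrow(tab) >= 2L) stats::sd(tab$length_nm)
                           else NA_real_)
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation_summary> overall %.1f +/- %s nm (n = %d)\n",
              x$overall$mean_nm,
              if (is.na(x$overall$sd_nm)) "NA"
              else sprintf("%.1f", x$overall$sd_nm),
              x$overall$n))
  print(x$per_group)
  invisible(x)
}

identity_submat <- function() {
  aas <- c(Biostrings::AA_STANDARD, "X")
  m <- matrix(0, length(aas), length(aas), dimnames = list(aas, aas))
  diag(m) <- 1
  m
}

#' Percent identity between two sequences over a region
#'
#' Global alignment with a match/mismatch identity matrix and a linear gap
#' penalty; identity = exact matches / aligned positions x 100.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param region Optional `c(start, end)` (1-based inclusive) applied to
#'   both sequences, restricting the comparison to that region (e.g. the
#'   coiled-coil); both sequences must cover it.
#' @param region_b Optional separate region for `seq_b` (when the
#'   coiled-coil sits at different coordinates in the two orthologues).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, region = NULL,
                              region_b = NULL) {
  clip <- function(s, r) {
    if (is.null(r)) return(s)
    if (length(r) != 2L || r[1] < 1 || r[2] < r[1]) {
      stop("region must be c(start, end) with 1 <= start <= end")
    }
    if (nchar(s) < r[2]) stop("sequence does not cover the region")
    substr(s, r[1], r[2])
  }
  a <- clip(as.character(seq_a), region)
  b <- clip(as.character(seq_b), region_b %||% region)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence or region")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = identity_submat(),
    gapOpening = 0, gapExtension = 1)
  # PID1: matches / (aligned positions + internal gaps)
  Biostrings::pid(aln, type = "PID1")
}

#' Mean pairwise identity across a family
#'
#' @param seqs Character vector of sequences (>= 2).
#' @param regions Optional list (same length) of per-sequence
#'   `c(start, end)` regions; identity is computed between the clipped
#'   regions of each pair.
#' @return Mean over all unordered pairs, percent.
#' @export
mean_pairwise_identity <- function(seqs, regions = NULL) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  if (!is.null(regions) && length(regions) != n) {
    stop("regions must match seqs in length")
  }
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, pairwise_identity(
        seqs[i], seqs[j],
        region = if (is.null(regions)) NULL else regions[[i]],
        region_b = if (is.null(regions)) NULL else regions[[j]]))
    }
  }
  mean(vals)
}
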