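ideal <- function(n) strrep("LAALEKE", n)

test_that("ideal heptad repeats score as coiled-coil, poly-proline does not", {
  a <- score_sequence(ideal(8))  # 56 aa
  expect_gte(mean(a$probability > 0.9), 0.9)
  p <- score_sequence(strrep("P", 56))
  expect_true(all(p$probability < 0.5))
})

test_that("sequence validation errors are informative", {
  expect_error(score_sequence(""), "empty")
  expect_error(score_sequence("LAALEKE"), "shorter than window")
  bad <- paste0(strrep("LAALEKE", 5), "B", strrep("LAALEKE", 3))
  expect_error(score_sequence(bad), "illegal residue 'B' at position 36")
})

test_that("the best frame is constant within an ideal uninterrupted repeat", {
  a <- score_sequence(ideal(10))
  expect_length(unique(a$frame), 1L)
})

test_that("prepending one ideal heptad shifts segment boundaries by 7", {
  s <- gen_heptad_sequence(20, flank_len = 50, seed = 3)
  segs_a <- call_segments(score_sequence(s))
  segs_b <- call_segments(score_sequence(paste0("LAALEKE", s)))
  expect_equal(nrow(segs_b), nrow(segs_a))
  expect_equal(segs_b$start, segs_a$start + 7L)
  expect_equal(segs_b$end, segs_a$end + 7L)
})

test_that("heptad sequences outscore their shuffles in >= 19/20 replicates", {
  wins <- vapply(1:20, function(i) {
    s <- gen_heptad_sequence(30, flank_len = 0, seed = i)
    set.seed(1000 + i)
    shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    stats::median(score_sequence(s)$probability) >
      stats::median(score_sequence(shuf)$probability)
  }, TRUE)
  expect_gte(sum(wins), 19)
})

test_that("segment calling merges, filters and sorts runs", {
  mk <- function(prob) data.frame(index = seq_along(prob),
                                  probability = prob, frame = 0L)
  # all above threshold -> one spanning segment
  one <- call_segments(mk(rep(0.9, 60)), min_len = 21)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(1L, 60L))
  # two 40-residue runs separated by 5 sub-threshold residues merge at gap 7
  p <- c(rep(0.9, 40), rep(0.1, 5), rep(0.9, 40))
  merged <- call_segments(mk(p), merge_gap = 7)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(1L, 85L))
  # ...but stay separate when the gap is not below merge_gap
  split2 <- call_segments(mk(p), merge_gap = 5)
  expect_equal(nrow(split2), 2L)
  expect_true(all(diff(split2$start) > 0))
  # nothing above threshold -> empty
  expect_equal(nrow(call_segments(mk(rep(0.2, 60)))), 0L)
  # short runs discarded
  expect_equal(nrow(call_segments(mk(rep(0.9, 10)), min_len = 21)), 0L)
  expect_error(call_segments(mk(rep(0.9, 10)), threshold = 1.5), "threshold")
})

test_that("predicted coiled-coil length sums segments through the ruler", {
  expect_equal(predicted_cc_length(data.frame(start = 1, end = 730)), 106.58)
  expect_equal(predicted_cc_length(data.frame(start = integer(),
                                              end = integer())), 0)
  two <- data.frame(start = c(1, 201), end = c(100, 230))  # 100 + 30 aa
  expect_equal(predicted_cc_length(two), 18.98)
  expect_error(predicted_cc_length(data.frame(start = c(1, 50),
                                              end = c(60, 80))), "overlap")
})

test_that("score and segment tables serialize as TSV, segments also as BED", {
  a <- score_sequence(ideal(8))
  segs <- call_segments(a)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(a, f1)
  back <- read.delim(f1)
  expect_equal(nrow(back), nrow(a))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_segments_tsv(segs, f2, name = "ideal", bed = TRUE)
  bed <- read.delim(f2)
  expect_equal(bed$start, segs$start - 1L)  # 0-based half-open
  expect_equal(bed$end, segs$end)
})

test_that("FASTA i/o round-trips named sequences", {
  seqs <- c(a = as.character(gen_heptad_sequence(10, 5, seed = 1)),
            b = as.character(gen_heptad_sequence(8, 3, seed = 2)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(unname(back), unname(as.character(seqs)))
  expect_identical(names(back), c("a", "b"))
})

test_that("custom propensity tables are validated", {
  m <- matrix(1, 20, 7,
              dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              letters[1:7]))
  tab <- propensity_table(m, window = 14)
  expect_s3_class(tab, "propensity_table")
  m_bad <- m; m_bad[1, 1] <- 0
  expect_error(propensity_table(m_bad), "> 0")
  expect_error(propensity_table(m, window = 3), "window")
})
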