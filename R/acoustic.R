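#' Acoustic distance between two MFCC sequences
#'
#' Each sequence of MFCC frames is partitioned into `k_segments` contiguous
#' segments of (as near as possible) equal frame counts; each segment is
#' reduced to its mean frame, and the distance is the mean over segments of
#' the Euclidean distance between corresponding segment means. The measure
#' is length-invariant: sequences of different durations are compared
#' through their k-segment reductions.
#'
#' @param seq_a,seq_b numeric matrices of MFCC frames (rows = frames,
#'   columns = cepstral coefficients; both sequences must share the frame
#'   dimension).
#' @param k_segments number of contiguous segments (default 10). Both
#'   sequences must have at least `k_segments` frames.
#' @return Non-negative dissimilarity; zero iff the reduced representations
#'   are identical.
#' @export
acoustic_word_distance <- function(seq_a, seq_b, k_segments = 10L) {
  seq_a <- as.matrix(seq_a); seq_b <- as.matrix(seq_b)
  if (k_segments < 1L) abort("`k_segments` must be >= 1.")
  if (!nrow(seq_a) || !nrow(seq_b)) abort("MFCC sequences must be non-empty.")
  if (ncol(seq_a) != ncol(seq_b)) abort("Frame dimensions differ between sequences.")
  if (nrow(seq_a) < k_segments || nrow(seq_b) < k_segments) {
    abort(sprintf("Sequences must have at least k_segments = %d frames.", k_segments))
  }
  ma <- segment_means(seq_a, k_segments)
  mb <- segment_means(seq_b, k_segments)
  mean(sqrt(rowSums((ma - mb)^2)))
}

# contiguous near-equal-count segmentation; segment s gets frames with
# ceiling(i * k / n) == s
segment_means <- function(x, k) {
  n <- nrow(x)
  seg <- ceiling(seq_len(n) * k / n)
  out <- matrix(0, k, ncol(x))
  for (s in seq_len(k)) {
    out[s, ] <- colMeans(x[seg == s, , drop = FALSE])
  }
  out
}

#' Acoustic-phonological dissimilarity model from MFCC sequences
#'
#' Entry (i, j) is the [acoustic_word_distance()] between words i and j,
#' computed within each speaker separately (a word is only ever compared to
#' another word spoken by the same speaker) and then averaged across
#' speakers.
#'
#' @param words character vector of item labels.
#' @param mfcc nested list: `mfcc[[speaker]][[word]]` is a frames x
#'   coefficients matrix. Every listed speaker must supply every word.
#' @param speakers speaker ids to use; defaults to all speakers in `mfcc`.
#' @inheritParams acoustic_word_distance
#' @return A [model_rdm()] with measure `"phonological"`.
#' @export
phonological_rdm <- function(words, mfcc, speakers = names(mfcc),
                             k_segments = 10L) {
  if (length(words) < 2L) abort("Need at least two words.")
  if (!length(speakers)) abort("Need at least one speaker.")
  n <- length(words)
  acc <- matrix(0, n, n)
  for (sp in speakers) {
    seqs <- mfcc[[sp]]
    if (is.null(seqs)) abort(sprintf("No MFCC data for speaker '%s'.", sp))
    for (w in words) {
      if (is.null(seqs[[w]])) {
        abort(sprintf("Missing MFCC sequence for word '%s', speaker '%s'.", w, sp))
      }
    }
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        d[i, j] <- d[j, i] <- acoustic_word_distance(seqs[[words[i]]],
                                                     seqs[[words[j]]],
                                                     k_segments = k_segments)
      }
    }
    acc <- acc + d
  }
  model_rdm(acc / length(speakers), items = words, measure = "phonological")
}
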