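# Toy phoneme inventory with binary articulatory features. Columns are a
# compact distinctive-feature set (syllabicity, voicing, manner, place,
# vowel height/backness/rounding); enough structure that feature-weighted
# substitution costs grade sensibly from near-identical segments (p/b differ
# in voicing only) to maximally different ones (p/a).
phoneme_feature_data <- function() {
  feats <- c("syllabic", "consonantal", "voiced", "nasal", "continuant",
             "labial", "coronal", "dorsal", "high", "low", "back", "round")
  rows <- list(
    p = c(0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0),
    b = c(0, 1, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0),
    t = c(0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
    d = c(0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0),
    k = c(0, 1, 0, 0, 0, 0, 0, 1, 1, 0, 1, 0),
    g = c(0, 1, 1, 0, 0, 0, 0, 1, 1, 0, 1, 0),
    m = c(0, 1, 1, 1, 0, 1, 0, 0, 0, 0, 0, 0),
    n = c(0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 0),
    s = c(0, 1, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    z = c(0, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    f = c(0, 1, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    v = c(0, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    l = c(0, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    r = c(0, 1, 1, 0, 1, 0, 1, 0, 0, 0, 1, 0),
    w = c(0, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1),
    j = c(0, 0, 1, 0, 1, 0, 0, 1, 1, 0, 0, 0),
    h = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    a = c(1, 0, 1, 0, 1, 0, 0, 0, 0, 1, 1, 0),
    e = c(1, 0, 1, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    i = c(1, 0, 1, 0, 1, 0, 0, 0, 1, 0, 0, 0),
    o = c(1, 0, 1, 0, 1, 0, 0, 0, 0, 0, 1, 1),
    u = c(1, 0, 1, 0, 1, 0, 0, 0, 1, 0, 1, 1)
  )
  m <- do.call(rbind, rows)
  colnames(m) <- feats
  m
}

#' Bundled phoneme feature table
#'
#' A binary articulatory feature table over a 22-phoneme toy inventory
#' (stops, nasals, fricatives, liquids, glides, and five vowels). Used by
#' the feature-weighted edit distance; any table with phonemes as rownames
#' and binary feature columns can be substituted.
#'
#' @return Binary matrix, phonemes x features.
#' @export
phoneme_features <- function() phoneme_feature_data()

# substitution cost matrix: proportion of mismatched features
substitution_costs <- function(ft) {
  ft <- as.matrix(ft)
  f <- ncol(ft)
  # hamming distance via cross products of the binary table
  g <- ft %*% t(ft) + (1 - ft) %*% t(1 - ft)
  (f - g) / f
}

#' Feature-weighted phonological edit distance
#'
#' Dynamic-programming edit distance between two phoneme sequences in which
#' substituting one phoneme for another costs the proportion of articulatory
#' features on which they differ (so near segments are cheap to exchange),
#' insertions and deletions cost `indel_cost`, and the total is normalised
#' for word length by dividing by the longer sequence's length. With the
#' default `indel_cost = 1` (the maximum substitution cost) results lie in
#' \[0, 1\].
#'
#' @param tr_a,tr_b character vectors of phonemes (or space-separated
#'   strings), both non-empty.
#' @param ft phoneme feature table (binary matrix, phonemes as rownames);
#'   defaults to the bundled [phoneme_features()].
#' @param indel_cost insertion/deletion cost.
#' @return Normalised dissimilarity, zero iff the sequences are identical.
#' @export
#' @examples
#' weighted_edit_distance(c("s", "a", "l", "t"), c("s", "a", "l", "u"))
weighted_edit_distance <- function(tr_a, tr_b, ft = phoneme_features(),
                                   indel_cost = 1) {
  tr_a <- parse_transcription(tr_a)
  tr_b <- parse_transcription(tr_b)
  if (!length(tr_a) || !length(tr_b)) abort("Transcriptions must be non-empty.")
  unknown <- setdiff(c(tr_a, tr_b), rownames(ft))
  if (length(unknown)) {
    abort(sprintf("Unknown phoneme(s): %s", paste(unique(unknown), collapse = ", ")))
  }
  sub <- substitution_costs(ft)
  la <- length(tr_a); lb <- length(tr_b)
  D <- matrix(0, la + 1L, lb + 1L)
  D[, 1L] <- (0:la) * indel_cost
  D[1L, ] <- (0:lb) * indel_cost
  for (i in seq_len(la)) {
    sc <- sub[tr_a[i], tr_b]
    for (j in seq_len(lb)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j] + sc[j],
        D[i, j + 1L] + indel_cost,
        D[i + 1L, j] + indel_cost
      )
    }
  }
  D[la + 1L, lb + 1L] / max(la, lb)
}

parse_transcription <- function(x) {
  if (length(x) == 1L && grepl(" ", x)) x <- strsplit(x, " +")[[1]]
  as.character(x[nzchar(x)])
}

#' Articulatory dissimilarity model from feature-weighted edit distances
#'
#' Entry (i, j) is the length-normalised feature-weighted edit distance
#' between the phonemic transcriptions of words i and j. Homophones (equal
#' transcriptions) receive dissimilarity zero.
#'
#' @param words character vector of item labels.
#' @param transcriptions list (or space-separated character vector) of
#'   phoneme sequences, parallel to `words`.
#' @inheritParams weighted_edit_distance
#' @return A [model_rdm()] with measure `"articulatory"`.
#' @export
articulatory_rdm <- function(words, transcriptions, ft = phoneme_features(),
                             indel_cost = 1) {
  if (length(words) < 2L) abort("Need at least two words.")
  if (length(transcriptions) != length(words)) {
    abort("`transcriptions` must be parallel to `words`.")
  }
  trs <- lapply(transcriptions, parse_transcription)
  n <- length(words)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- weighted_edit_distance(trs[[i]], trs[[j]], ft,
                                                   indel_cost = indel_cost)
    }
  }
  model_rdm(d, items = words, measure = "articulatory")
}
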