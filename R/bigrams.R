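#' Unconstrained open-bigram feature vector
#'
#' Counts every ordered letter pair of `word` taken at any gap: for letter
#' positions i < j the pair (letter_i, letter_j) is one open bigram. A word
#' of length L therefore contributes L(L-1)/2 bigram tokens; counts (not
#' binary presence) are recorded so repeated-letter structure is preserved.
#'
#' @param word a string of length >= 2.
#' @param vocabulary ordered character vector of bigrams defining the vector
#'   dimensions; must cover every bigram of `word`.
#' @param counts if `FALSE`, binary presence is returned instead of token
#'   counts.
#' @return Named integer vector of length `length(vocabulary)`.
#' @export
#' @examples
#' v <- open_bigram_vector("salt", open_bigram_vocabulary("salt"))
#' sum(v)  # 4 * 3 / 2 = 6
open_bigram_vector <- function(word, vocabulary, counts = TRUE) {
  word <- tolower(word)
  L <- nchar(word)
  if (L < 2L) abort("`word` must have at least 2 letters.")
  ch <- strsplit(word, "")[[1]]
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  bg <- paste0(ch[idx[, "row"]], ch[idx[, "col"]])
  missing <- setdiff(unique(bg), vocabulary)
  if (length(missing)) {
    abort(sprintf("Vocabulary does not cover bigram(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tab <- table(factor(bg, levels = vocabulary))
  v <- as.integer(tab)
  names(v) <- vocabulary
  if (!counts) v <- as.integer(v > 0L)
  v
}

#' Open-bigram vocabulary of a word list
#'
#' @param words character vector.
#' @return Sorted character vector of all open bigrams occurring in `words`.
#' @export
open_bigram_vocabulary <- function(words) {
  all_bg <- unlist(lapply(tolower(words), function(w) {
    ch <- strsplit(w, "")[[1]]
    L <- length(ch)
    if (L < 2L) return(character())
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    paste0(ch[idx[, "row"]], ch[idx[, "col"]])
  }), use.names = FALSE)
  sort(unique(all_bg))
}

#' Orthographic dissimilarity model from open bigrams
#'
#' Entry (i, j) is the correlation distance between the unconstrained
#' open-bigram count vectors of words i and j, computed over the shared
#' vocabulary of all bigrams occurring in the word list.
#'
#' @inheritParams open_bigram_vector
#' @param words character vector, all of length >= 2.
#' @return A [model_rdm()] with measure `"orthographic"`.
#' @export
orthographic_rdm <- function(words, counts = TRUE) {
  if (length(words) < 2L) abort("Need at least two words.")
  vocab <- open_bigram_vocabulary(words)
  if (length(vocab) < 2L) abort("Degenerate vocabulary: need > 1 distinct bigram.")
  vecs <- do.call(rbind, lapply(words, open_bigram_vector,
                                vocabulary = vocab, counts = counts))
  d <- correlation_distance_matrix(vecs, what = "bigram vector")
  model_rdm(d, items = words, measure = "orthographic")
}
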