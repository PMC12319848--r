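#' Semantic dissimilarity model from word embeddings
#'
#' Entry (i, j) is the cosine distance `1 - cos(embedding_i, embedding_j)`
#' between the words' embedding vectors; entries lie in \[0, 2\].
#'
#' @param words character vector of item labels.
#' @param embeddings numeric matrix with one row per word (rownames must
#'   cover `words`, or rows parallel to `words` if unnamed). All embeddings
#'   must share one dimension; zero vectors are rejected.
#' @return A [model_rdm()] with measure `"semantic"`.
#' @export
semantic_rdm <- function(words, embeddings) {
  if (length(words) < 2L) abort("Need at least two words.")
  embeddings <- as.matrix(embeddings)
  if (!is.null(rownames(embeddings))) {
    missing <- setdiff(words, rownames(embeddings))
    if (length(missing)) {
      abort(sprintf("No embedding for word(s): %s", paste(missing, collapse = ", ")))
    }
    e <- embeddings[words, , drop = FALSE]
  } else {
    if (nrow(embeddings) != length(words)) {
      abort("Unnamed `embeddings` must have one row per word.")
    }
    e <- embeddings
  }
  nrm <- sqrt(rowSums(e^2))
  if (any(nrm == 0)) {
    abort(sprintf("Zero-norm embedding for word(s): %s",
                  paste(words[nrm == 0], collapse = ", ")))
  }
  cs <- tcrossprod(e / nrm)
  cs[cs > 1] <- 1
  cs[cs < -1] <- -1
  model_rdm(1 - cs, items = words, measure = "semantic")
}
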