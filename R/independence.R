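#' Pairwise independence screening of hypothesis models
#'
#' Vectorises each model RDM, computes the Pearson correlation between every
#' unordered pair of models, and attaches a correlation Bayes factor
#' ([correlation_bf()]) quantifying the evidence for a true (anti-)
#' correlation, treating the n(n-1)/2 RDM cells as observations. This is
#' the screening used to check that the five dissimilarity measures are
#' mutually independent before they are entered together as regressors: a
#' pair with BF10 < 3 is conventionally read as no compelling evidence of
#' dependence.
#'
#' @param rdms named list of [model_rdm()] objects over the same ordered
#'   item list (names default to each model's measure tag).
#' @param prior prior passed to [correlation_bf()].
#' @return A tibble with one row per model pair (upper triangle):
#'   `model_a`, `model_b`, `n_pairs`, `r`, `bf10`.
#' @export
model_independence_report <- function(rdms, prior = "jzs") {
  if (length(rdms) < 2L) abort("Need at least two models.")
  if (is.null(names(rdms)) || any(!nzchar(names(rdms)))) {
    names(rdms) <- vapply(rdms, rdm_measure, character(1))
  }
  items <- rdm_items(rdms[[1]])
  for (m in rdms) {
    if (!identical(rdm_items(m), items)) {
      abort("All models must share one ordered item list.")
    }
  }
  vecs <- lapply(rdms, rdm_vectorize)
  n_pairs <- length(vecs[[1]])
  combos <- utils::combn(names(rdms), 2L)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1L, k]; b <- combos[2L, k]
    r <- cor(vecs[[a]], vecs[[b]])
    tibble(
      model_a = a, model_b = b, n_pairs = n_pairs,
      r = r, bf10 = correlation_bf(r, n_pairs, prior = prior)
    )
  })
}
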