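#' Construct a word lexicon
#'
#' A lexicon is a tibble with one row per word (columns `word`,
#' `transcription` — space-separated phonemes — and `condition`, one of
#' `"aloud"`, `"silent"`, `"unassigned"`), carrying the word embeddings and
#' per-speaker MFCC sequences as attributes so the whole stimulus
#' description travels as one object.
#'
#' @param words character vector of lowercase alphabetic words.
#' @param transcriptions character vector of space-separated phoneme
#'   strings, parallel to `words`.
#' @param embeddings numeric matrix of word embeddings (rownames = words);
#'   all rows share one dimension.
#' @param mfcc nested list `mfcc[[speaker]][[word]]` of MFCC frame matrices.
#' @param condition condition labels, recycled; defaults to "unassigned".
#' @return A tibble of class `lexicon`.
#' @export
lexicon <- function(words, transcriptions, embeddings = NULL, mfcc = NULL,
                    condition = "unassigned") {
  if (any(!grepl("^[a-z]+$", words))) abort("Words must be lowercase alphabetic.")
  if (anyDuplicated(words)) abort("Words must be unique.")
  if (length(transcriptions) != length(words)) {
    abort("`transcriptions` must be parallel to `words`.")
  }
  if (any(!nzchar(transcriptions))) abort("Transcriptions must be non-empty.")
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (is.null(rownames(embeddings))) rownames(embeddings) <- words
  }
  out <- tibble(
    word = as.character(words),
    transcription = as.character(transcriptions),
    condition = rep_len(as.character(condition), length(words))
  )
  structure(out, embeddings = embeddings, mfcc = mfcc,
            class = c("lexicon", class(out)))
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d words", nrow(x)))
  emb <- attr(x, "embeddings")
  if (!is.null(emb)) cat(sprintf(", %d-d embeddings", ncol(emb)))
  mf <- attr(x, "mfcc")
  if (!is.null(mf)) cat(sprintf(", MFCCs for %d speaker(s)", length(mf)))
  cat("\n")
  NextMethod()
}

lexicon_embeddings <- function(lex) attr(lex, "embeddings")
lexicon_mfcc <- function(lex) attr(lex, "mfcc")

#' Build the five hypothesis models for a word set
#'
#' Convenience wrapper constructing all five dissimilarity models — visual,
#' orthographic, phonological, semantic, articulatory — for the words of a
#' lexicon. With `condition = NULL` the models span every word (exemplar
#' models, used for independence screening); with a condition label they
#' span that condition's words only (the per-condition hypothesis models
#' entered into the searchlight regression).
#'
#' @param lex a [lexicon()] with embeddings and MFCC data attached.
#' @param condition `NULL`, `"aloud"`, or `"silent"`.
#' @param cfg [render_config()] for the visual model.
#' @param k_segments segment count for the acoustic distance.
#' @param ft phoneme feature table for the articulatory model.
#' @return Named list of five [model_rdm()] objects
#'   (`visual`, `orthographic`, `phonological`, `semantic`, `articulatory`).
#' @export
build_hypothesis_models <- function(lex, condition = NULL,
                                    cfg = render_config(), k_segments = 10L,
                                    ft = phoneme_features()) {
  stopifnot(inherits(lex, "lexicon"))
  rows <- if (is.null(condition)) lex else dplyr::filter(lex, .data$condition == !!condition)
  if (nrow(rows) < 3L) abort("Need at least three words to build models.")
  words <- rows$word
  emb <- lexicon_embeddings(lex)
  mf <- lexicon_mfcc(lex)
  if (is.null(emb)) abort("Lexicon has no embeddings.")
  if (is.null(mf)) abort("Lexicon has no MFCC data.")
  list(
    visual = visual_rdm(words, cfg = cfg),
    orthographic = orthographic_rdm(words),
    phonological = phonological_rdm(words, mf, k_segments = k_segments),
    semantic = semantic_rdm(words, emb),
    articulatory = articulatory_rdm(words, rows$transcription, ft = ft)
  )
}

#' Read / write a lexicon
#'
#' The lexicon itself is a TSV (`word`, `transcription`, `condition`);
#' embeddings are a TSV of `word` plus numeric columns; MFCC sequences are a
#' JSON map speaker -> word -> list of frames.
#'
#' @param lex a [lexicon()].
#' @param path TSV path for the word table; the embeddings TSV and MFCC JSON
#'   are written beside it as `<path>_embeddings.tsv` / `<path>_mfcc.json`.
#' @return `write_lexicon()` returns `path` invisibly; `read_lexicon()`
#'   returns a [lexicon()].
#' @export
write_lexicon <- function(lex, path) {
  readr::write_tsv(tibble(word = lex$word, transcription = lex$transcription,
                          condition = lex$condition), path)
  emb <- lexicon_embeddings(lex)
  if (!is.null(emb)) {
    df <- as_tibble(as.data.frame(emb), .name_repair = "minimal")
    names(df) <- paste0("d", seq_len(ncol(df)))
    readr::write_tsv(dplyr::bind_cols(tibble(word = rownames(emb)), df),
                     sub("\\.tsv$", "_embeddings.tsv", path))
  }
  mf <- lexicon_mfcc(lex)
  if (!is.null(mf)) {
    jsonlite::write_json(
      purrr::map(mf, function(sp) purrr::map(sp, ~ apply(.x, 1, as.numeric, simplify = FALSE))),
      sub("\\.tsv$", "_mfcc.json", path), digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  emb_path <- sub("\\.tsv$", "_embeddings.tsv", path)
  mfcc_path <- sub("\\.tsv$", "_mfcc.json", path)
  emb <- NULL
  if (file.exists(emb_path)) {
    e <- readr::read_tsv(emb_path, show_col_types = FALSE)
    emb <- as.matrix(e[, -1])
    rownames(emb) <- e$word
  }
  mf <- NULL
  if (file.exists(mfcc_path)) {
    raw <- jsonlite::read_json(mfcc_path, simplifyVector = TRUE)
    mf <- purrr::map(raw, function(sp) purrr::map(sp, function(w) {
      if (is.matrix(w)) w else do.call(rbind, w)
    }))
  }
  lexicon(df$word, df$transcription, embeddings = emb, mfcc = mf,
          condition = df$condition)
}
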