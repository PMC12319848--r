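test_that("silhouette rendering is deterministic, binary, and matches the frozen ink count", {
  a <- render_silhouette("reading")
  b <- render_silhouette("reading")
  expect_identical(a, b)
  expect_setequal(unique(a), c(0L, 1L))
  expect_equal(length(a), 64 * 11)
  # frozen: ink pixels of "cat" counted once from the fixture glyph bitmaps
  expect_identical(sum(render_silhouette("cat")), 36L)
  expect_error(render_silhouette("café"), "alphabetic")
})

test_that("visual RDM equals hand-computed Pearson distances and respects bounds", {
  # three toy 'words' with hand-specified silhouettes, bypassing the font
  sils <- rbind(c(1, 0, 1, 0, 1, 0),
                c(1, 1, 0, 0, 1, 0),
                c(0, 1, 0, 1, 0, 1))
  d <- readrsa:::correlation_distance_matrix(sils)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d[i, j],
                 max(0, oracle_pearson_distance(sils[i, ], sils[j, ])),
                 tolerance = 1e-12)
  }
  rdm <- visual_rdm(c("salt", "pepper", "salt", "basil"))
  expect_s3_class(rdm, "model_rdm")
  expect_equal(unclass(rdm)[1, 3], 0)        # duplicate word -> distance 0
  expect_true(all(rdm >= 0 & rdm <= 2))
  expect_equal(unclass(rdm), t(unclass(rdm)))
})

test_that("open bigram counts match exhaustive pair enumeration", {
  expect_identical(
    open_bigram_vector("at", open_bigram_vocabulary("at")),
    c(at = 1L)
  )
  v <- open_bigram_vector("salt", open_bigram_vocabulary("salt"))
  expect_equal(sum(v), 6)  # 4 * 3 / 2
  expect_setequal(names(v[v > 0]), c("sa", "sl", "st", "al", "at", "lt"))
  v2 <- open_bigram_vector("banana", open_bigram_vocabulary("banana"))
  expect_equal(unname(v2["an"]), 3L)
  expect_equal(sum(v2), 15)
  # property: every lexicon word up to length 10 matches the enumeration
  words <- generate_lexicon(20, seed = 31)$word
  vocab <- open_bigram_vocabulary(words)
  for (w in words) {
    v <- open_bigram_vector(w, vocab)
    oc <- oracle_bigram_counts(w)
    expect_equal(sum(v), nchar(w) * (nchar(w) - 1) / 2)
    expect_equal(v[names(oc)], setNames(as.integer(oc), names(oc)))
    expect_true(all(v[setdiff(vocab, names(oc))] == 0))
  }
  expect_error(open_bigram_vector("a", "aa"), "at least 2")
})

test_that("orthographic RDM separates letter-disjoint words and is a valid RDM", {
  rdm <- orthographic_rdm(c("abab", "cdcd", "abcd"))
  expect_equal(unclass(rdm)[1, 1], 0)
  expect_gt(unclass(rdm)[1, 2], 1)  # disjoint letters: anti-correlated vectors
  expect_equal(unclass(rdm), t(unclass(rdm)))
  same <- orthographic_rdm(c("salt", "salt", "slat"))
  expect_equal(unclass(same)[1, 2], 0)
})

test_that("acoustic distance reduces segments correctly", {
  a <- matrix(c(0, 0), 1, 2)[rep(1, 4), ]
  b <- matrix(c(3, 4), 1, 2)[rep(1, 4), ]
  expect_equal(acoustic_word_distance(a, b, k_segments = 1), 5)
  expect_equal(acoustic_word_distance(a, a, k_segments = 2), 0)
  # hand-built 4-frame sequences, k = 2: segment means then Euclidean, averaged
  sa <- rbind(c(0, 0), c(2, 0), c(4, 0), c(6, 0))
  sb <- rbind(c(1, 1), c(1, 3), c(5, 0), c(5, 4))
  m_a1 <- c(1, 0); m_a2 <- c(5, 0)
  m_b1 <- c(1, 2); m_b2 <- c(5, 2)
  expected <- mean(c(sqrt(sum((m_a1 - m_b1)^2)), sqrt(sum((m_a2 - m_b2)^2))))
  expect_equal(acoustic_word_distance(sa, sb, k_segments = 2), expected)
  expect_error(acoustic_word_distance(sa[1:1, , drop = FALSE], sb, k_segments = 2),
               "at least")
})

test_that("phonological RDM averages within-speaker distances across speakers", {
  words <- c("ba", "do", "ki")
  set.seed(4)
  mk <- function() {
    out <- lapply(words, function(w) matrix(rnorm(12 * 3), 12, 3))
    names(out) <- words
    out
  }
  mfcc <- list(s1 = mk(), s2 = mk())
  rdm <- phonological_rdm(words, mfcc, k_segments = 4)
  # brute force: per speaker then average
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    d1 <- acoustic_word_distance(mfcc$s1[[words[i]]], mfcc$s1[[words[j]]], 4)
    d2 <- acoustic_word_distance(mfcc$s2[[words[i]]], mfcc$s2[[words[j]]], 4)
    expect_equal(unclass(rdm)[i, j], (d1 + d2) / 2)
  }
  one <- phonological_rdm(words, mfcc["s1"], k_segments = 4)
  d1 <- acoustic_word_distance(mfcc$s1$ba, mfcc$s1$do, 4)
  expect_equal(unclass(one)[1, 2], d1)
  mfcc$s2$ki <- NULL
  expect_error(phonological_rdm(words, mfcc, k_segments = 4), "ki.*s2|s2.*ki")
})

test_that("semantic RDM hits the cosine landmarks", {
  e <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  rdm <- semantic_rdm(c("a", "b", "c", "d"), e)
  expect_equal(unclass(rdm)["a", "b"], 0)  # parallel
  expect_equal(unclass(rdm)["a", "c"], 1)  # orthogonal
  expect_equal(unclass(rdm)["a", "d"], 2)  # antiparallel
  expect_error(semantic_rdm(c("a", "b"), rbind(a = c(0, 0), b = c(1, 0))),
               "Zero-norm")
})

test_that("weighted edit distance matches the exhaustive-alignment oracle", {
  ft <- phoneme_features()
  expect_equal(weighted_edit_distance(c("s", "a", "l"), c("s", "a", "l"), ft), 0)
  # one substitution among length-3 sequences: (mismatches / F) / 3
  m <- sum(ft["p", ] != ft["b", ])
  expect_equal(weighted_edit_distance(c("p", "a", "t"), c("b", "a", "t"), ft),
               (m / ncol(ft)) / 3)
  # single insertion: indel / max(1, 2)
  expect_equal(weighted_edit_distance("a", c("a", "t"), ft), 1 / 2)
  # all pairs of a toy set over a 4-phoneme alphabet, lengths 1..5
  alphabet <- c("p", "b", "a", "s")
  set.seed(8)
  seqs <- c(
    lapply(1:4, function(i) alphabet[i]),
    lapply(1:20, function(i) sample(alphabet, sample(2:5, 1), replace = TRUE))
  )
  for (i in seq_along(seqs)) {
    for (j in seq_len(i - 1)) {
      expect_equal(weighted_edit_distance(seqs[[i]], seqs[[j]], ft),
                   oracle_edit_distance(seqs[[i]], seqs[[j]], ft),
                   tolerance = 1e-12)
    }
  }
  expect_error(weighted_edit_distance(c("x9"), c("a"), ft), "x9")
})

test_that("articulatory RDM is symmetric with zero distance for homophones", {
  words <- c("pat", "bat", "tap")
  trs <- c("p a t", "p a t", "t a p")
  rdm <- articulatory_rdm(words, trs)
  expect_equal(unclass(rdm)[1, 2], 0)  # homophones
  expect_equal(unclass(rdm), t(unclass(rdm)))
  expect_equal(unclass(rdm)[1, 3],
               weighted_edit_distance("p a t", "t a p"))
})

test_that("rdm_vectorize follows the row-major lower-triangle contract", {
  m3 <- model_rdm(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3), c("a", "b", "c"))
  expect_equal(rdm_vectorize(m3), c(1, 2, 3))  # d21, d31, d32
  expect_length(rdm_vectorize(make_test_models(sprintf("w%d", 1:15), 1)[[1]]), 105)
  expect_length(rdm_vectorize(make_test_models(sprintf("w%d", 1:30), 1)[[1]]), 435)
  # explicit order check at n = 4 (row-major differs from column-major here)
  m4 <- matrix(0, 4, 4)
  m4[lower.tri(m4)] <- 1:6
  m4 <- m4 + t(m4)
  expect_equal(rdm_vectorize(model_rdm(m4, letters[1:4])),
               c(m4[2, 1], m4[3, 1], m4[3, 2], m4[4, 1], m4[4, 2], m4[4, 3]))
  expect_error(rdm_vectorize(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("all five builders are equivariant under word-list permutation", {
  lex <- generate_lexicon(8, seed = 21)
  words <- lex$word
  mods <- build_hypothesis_models(lex)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  plex <- lex[perm, ]
  attributes(plex)[c("embeddings", "mfcc")] <- attributes(lex)[c("embeddings", "mfcc")]
  class(plex) <- class(lex)
  pmods <- build_hypothesis_models(plex)
  for (k in names(mods)) {
    expect_equal(unclass(pmods[[k]]), unclass(mods[[k]])[perm, perm],
                 ignore_attr = TRUE, tolerance = 1e-12)
    # validity: symmetric, zero diagonal, non-negative
    m <- unclass(mods[[k]])
    expect_true(all(m >= 0))
    expect_equal(diag(m), setNames(rep(0, 8), words))
    if (k %in% c("visual", "orthographic", "semantic")) expect_true(all(m <= 2))
  }
})

test_that("model independence report screens exemplar models", {
  items <- sprintf("w%d", 1:30)
  mods <- make_test_models(items, n_models = 2, seed = 5)
  rep <- model_independence_report(mods)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$n_pairs, 435)
  # independently generated random RDMs: near-zero correlation, BF < 3
  expect_lt(abs(rep$r), 0.15)
  expect_lt(rep$bf10, 3)
  rep5 <- model_independence_report(make_test_models(items, 5, seed = 6))
  expect_equal(nrow(rep5), choose(5, 2))
  expect_true(all(rep5$n_pairs == choose(30, 2)))
  bad <- make_test_models(sprintf("v%d", 1:30), n_models = 2)
  expect_error(model_independence_report(list(mods[[1]], bad[[2]])), "item list")
})

test_that("RDM TSV round trip preserves matrix, items, and measure", {
  rdm <- make_test_models(c("alpha", "beta", "gamma"), 1, seed = 2)[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdm_tsv(rdm, path)
  back <- read_rdm_tsv(path)
  expect_equal(unclass(back), unclass(rdm), tolerance = 1e-12)
  expect_equal(attr(back, "measure"), attr(rdm, "measure"))
})
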