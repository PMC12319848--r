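test_that("lexicon generation is deterministic with valid word shapes", {
  a <- generate_lexicon(30, seed = 3)
  b <- generate_lexicon(30, seed = 3)
  expect_identical(a$word, b$word)
  expect_identical(attr(a, "embeddings"), attr(b, "embeddings"))
  expect_equal(nrow(a), 30)
  expect_false(anyDuplicated(a$word) > 0)
  expect_true(all(nchar(a$word) >= 6 & nchar(a$word) <= 10))
  expect_true(all(grepl("^[a-z]+$", a$word)))
  # transcriptions resolve in the bundled feature table
  phon <- unique(unlist(strsplit(a$transcription, " ")))
  expect_true(all(phon %in% rownames(phoneme_features())))
  # MFCC sequences exist per speaker per word
  mf <- attr(a, "mfcc")
  expect_equal(length(mf), 2)
  expect_true(all(a$word %in% names(mf[[1]])))
})

test_that("condition allocation splits evenly and varies between subjects", {
  lex <- generate_lexicon(30, seed = 5)
  s1 <- allocate_conditions(lex, seed = 10)
  expect_equal(sum(s1$condition == "aloud"), 15)
  expect_equal(sum(s1$condition == "silent"), 15)
  expect_identical(allocate_conditions(lex, seed = 10)$condition, s1$condition)
  # different seeds almost surely give different mappings
  diffs <- vapply(11:15, function(sd) {
    any(allocate_conditions(lex, seed = sd)$condition != s1$condition)
  }, logical(1))
  expect_true(any(diffs))
  odd <- generate_lexicon(7, seed = 2)
  expect_error(allocate_conditions(odd, seed = 1), "even")
})

test_that("planting calibrates the model-neural correlation", {
  lex <- allocate_conditions(generate_lexicon(30, seed = 8), seed = 9)
  mdl <- build_hypothesis_models(lex, "aloud")$semantic
  # rho 0: pure noise
  p0 <- plant_item_patterns(mdl, 200, 0, seed = 4)
  expect_lte(abs(attr(p0, "achieved_rho")), 0.05 + 0.1)  # single-draw slack
  expect_equal(attr(p0, "weight"), 0)
  # rho 0.5: the returned draw's correlation, recomputed from the patterns,
  # matches the stored attribute and sits near the target
  p5 <- plant_item_patterns(mdl, 200, 0.5, seed = 4)
  r_draw <- cor(rdm_vectorize(neural_rdm(p5)), rdm_vectorize(mdl))
  expect_equal(r_draw, attr(p5, "achieved_rho"))
  expect_gt(r_draw, 0.35)
  expect_lt(r_draw, 0.65)
  # two seeds give different patterns, both near target
  p5b <- plant_item_patterns(mdl, 200, 0.5, seed = 5)
  expect_false(isTRUE(all.equal(p5, p5b)))
  expect_lt(abs(attr(p5b, "achieved_rho") - 0.5), 0.15)
  # infeasible target errors with the achieved value
  expect_error(plant_item_patterns(mdl, 200, 0.99, seed = 4), "achieve")
})

test_that("simulated BOLD is invertible without noise and reproducible", {
  dims <- c(8L, 8L, 6L)
  mask <- ellipsoid_mask(dims)
  lex <- allocate_conditions(generate_lexicon(10, seed = 12), seed = 13)
  ds <- make_dataset(n_subjects = 1, dims = dims, mask = mask, seed = 7,
                     lex = generate_lexicon(10, seed = 12), noise_sd = 0)
  subj <- ds$subjects[[1]]
  expect_equal(length(subj$runs), 4)
  expect_equal(dim(subj$runs[[1]]$data)[4], 100)
  expect_equal(subj$runs[[1]]$tr, 1.8)
  # noiseless inversion recovers truth
  trials <- lapply(1:4, function(r) {
    des <- build_design_matrix(subj$events[[r]], n_vols = 100, tr = 1.8)
    fit_lsa(subj$runs[[r]], des)
  })
  items <- average_item_patterns(trials, item_order = subj$lexicon$word)
  expect_lt(max(abs(items$beta - subj$truth$beta)), 1e-6)
  # same seed -> bitwise identical runs
  ds2 <- make_dataset(n_subjects = 1, dims = dims, mask = mask, seed = 7,
                      lex = generate_lexicon(10, seed = 12), noise_sd = 0)
  expect_identical(ds$subjects[[1]]$runs[[1]]$data, ds2$subjects[[1]]$runs[[1]]$data)
})

test_that("dataset invariants hold on a small smoke study", {
  dims <- c(10L, 10L, 8L)
  ds <- make_dataset(n_subjects = 2, dims = dims, seed = 3, keep_bold = TRUE)
  expect_equal(length(ds$subjects), 2)
  for (subj in ds$subjects) {
    expect_equal(length(subj$events), 4)
    words <- unlist(lapply(subj$events, `[[`, "word"))
    expect_equal(sort(table(words)), sort(table(words)))
    expect_true(all(table(words) == 4))  # each word 4 times total
    for (ev in subj$events) {
      expect_equal(nrow(ev), 30)
      expect_silent(validate_events(ev, run_length = 180))
    }
    expect_equal(sum(subj$lexicon$condition == "aloud"), 15)
  }
  # no plants -> achieved table empty
  expect_equal(nrow(ds$achieved), 0)
})

test_that("planted datasets retain measurable ground truth", {
  dims <- c(12L, 12L, 10L)
  mask <- ellipsoid_mask(dims)
  region <- sphere_region(dims, radius = 3) & mask
  ps <- plant_spec(region, "semantic", rho_target = 0.5, conditions = "aloud")
  ds <- make_dataset(n_subjects = 2, dims = dims, mask = mask,
                     plant_specs = list(ps), seed = 21, keep_bold = FALSE)
  expect_equal(nrow(ds$achieved), 2)
  for (s in 1:2) {
    subj <- ds$subjects[[s]]
    cols <- match(which(region & mask), subj$truth$voxels)
    aloud_rows <- which(subj$truth$conditions == "aloud")
    pat <- subj$truth$beta[aloud_rows, cols]
    mdl <- subj$models$aloud$semantic
    ord <- match(rdm_items(mdl), subj$truth$items[aloud_rows])
    r <- cor(rdm_vectorize(neural_rdm(pat[ord, ])), rdm_vectorize(mdl))
    expect_equal(r, ds$achieved$achieved_rho[s], tolerance = 1e-10)
    expect_gt(r, 0.3)
  }
  # region outside the mask is rejected
  bad_region <- array(TRUE, dims)
  expect_error(make_dataset(n_subjects = 1, dims = dims, mask = mask,
                            plant_specs = list(plant_spec(bad_region, "semantic")),
                            seed = 1, keep_bold = FALSE),
               "outside the mask")
})

test_that("study I/O round-trips BOLD, events, lexicon and RDMs", {
  dims <- c(6L, 6L, 4L)
  ds <- make_dataset(n_subjects = 1, dims = dims, seed = 9,
                     lex = generate_lexicon(6, seed = 2), keep_bold = TRUE)
  dir <- withr::local_tempdir()
  write_study(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  lex_back <- read_lexicon(file.path(dir, "lexicon.tsv"))
  expect_equal(lex_back$word, ds$lexicon$word)
  expect_equal(attr(lex_back, "embeddings"), attr(ds$lexicon, "embeddings"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(lex_back, "mfcc")[[1]][[1]],
               attr(ds$lexicon, "mfcc")[[1]][[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  run_back <- read_bold_nifti(file.path(dir, "sub-01", "run-1_bold.nii.gz"))
  expect_equal(run_back$data, ds$subjects[[1]]$runs[[1]]$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(run_back$mask, ds$subjects[[1]]$runs[[1]]$mask)
  ev <- readr::read_tsv(file.path(dir, "sub-01", "run-1_events.tsv"),
                        show_col_types = FALSE)
  expect_equal(ev$onset, ds$subjects[[1]]$events[[1]]$onset)
  rdm_back <- read_rdm_tsv(file.path(dir, "sub-01", "model_aloud_semantic.tsv"))
  expect_equal(unclass(rdm_back), unclass(ds$subjects[[1]]$models$aloud$semantic),
               tolerance = 1e-9)
})
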