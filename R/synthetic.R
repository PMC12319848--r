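# Deterministic seed fan-out: one master seed yields independent child seeds
# for each (stage, subject, run) without seed collisions across stages.
child_seed <- function(master, ...) {
  ids <- c(...)
  x <- as.double(master %% 2147483647)
  for (id in ids) {
    x <- (x * 48271 + as.double(id) * 104729 + 12345) %% 2147483647
  }
  as.integer(x)
}

#' Generate a synthetic word lexicon
#'
#' Builds `n` unique pronounceable-ish words (alternating consonant/vowel
#' letters, lengths 6 to 10) with: phonemic transcriptions over the bundled
#' toy inventory (one phoneme per letter), iid standard-normal embedding
#' vectors, and per-speaker MFCC sequences drawn from smooth per-word
#' Gaussian processes (a word-level latent trajectory shared across
#' speakers plus speaker-specific jitter, so same-word renditions are
#' similar across speakers while different words diverge). Deterministic
#' under `seed`.
#'
#' @param n number of words (default 30).
#' @param seed integer seed.
#' @param embedding_dim embedding dimensionality.
#' @param n_speakers number of synthetic speakers.
#' @param mfcc_dim number of cepstral coefficients per frame.
#' @return A [lexicon()] with condition `"unassigned"`.
#' @export
generate_lexicon <- function(n = 30L, seed = 1L, embedding_dim = 50L,
                             n_speakers = 2L, mfcc_dim = 13L) {
  if (n < 2L) abort("Need n >= 2 words.")
  consonants <- c("p", "b", "t", "d", "k", "g", "m", "n", "s", "l", "r", "f", "v", "w")
  vowels <- c("a", "e", "i", "o", "u")
  withr_seed(seed)
  words <- character(0)
  guard <- 0L
  while (length(words) < n) {
    guard <- guard + 1L
    if (guard > 1000L * n) abort("Unable to generate enough unique words.")
    len <- sample(6:10, 1L)
    start_c <- runif(1) < 0.8
    w <- vapply(seq_len(len), function(i) {
      if (xor(i %% 2L == 1L, !start_c)) sample(consonants, 1L) else sample(vowels, 1L)
    }, character(1))
    w <- paste(w, collapse = "")
    if (!w %in% words) words <- c(words, w)
  }
  transcriptions <- vapply(words, function(w) {
    paste(strsplit(w, "")[[1]], collapse = " ")
  }, character(1))
  emb <- matrix(rnorm(n * embedding_dim), n, embedding_dim,
                dimnames = list(words, NULL))
  speakers <- sprintf("speaker%02d", seq_len(n_speakers))
  # word-level latent MFCC trajectory: smooth random walk over ~2-4 frames
  # per letter; speakers add small jitter and their own frame count
  base <- lapply(words, function(w) {
    nf <- 3L * nchar(w) + 10L
    traj <- apply(matrix(rnorm(nf * mfcc_dim, sd = 1), nf, mfcc_dim), 2L,
                  function(col) as.numeric(stats::filter(col, rep(1 / 4, 4),
                                                         circular = TRUE)))
    traj * 3
  })
  names(base) <- words
  mfcc <- lapply(speakers, function(sp) {
    out <- lapply(words, function(w) {
      b <- base[[w]]
      b + matrix(rnorm(length(b), sd = 0.4), nrow(b), ncol(b))
    })
    names(out) <- words
    out
  })
  names(mfcc) <- speakers
  lexicon(words, transcriptions, embeddings = emb, mfcc = mfcc)
}

# set.seed without leaking state changes into caller expectations; plain
# wrapper kept for a single point of control
withr_seed <- function(seed) set.seed(as.integer(seed %% 2147483647))

#' Randomly allocate words to reading conditions
#'
#' Assigns exactly half the lexicon to `"aloud"` and half to `"silent"`,
#' uniformly at random; word-condition mappings are intended to be
#' re-randomised per participant (pass a per-subject seed).
#'
#' @param lex a [lexicon()] with an even number of words.
#' @param seed integer seed.
#' @return The lexicon with its `condition` column filled in.
#' @export
allocate_conditions <- function(lex, seed = 1L) {
  n <- nrow(lex)
  if (n %% 2L != 0L) abort("Lexicon must have an even number of words.")
  withr_seed(seed)
  aloud <- sample(n, n / 2L)
  cond <- rep("silent", n)
  cond[aloud] <- "aloud"
  lex$condition <- cond
  lex
}

#' Plant model geometry into item activation patterns
#'
#' Generates item x voxel patterns whose neural RDM (1 - Pearson) correlates
#' with the vectorised model RDM at a target level. Prototype item
#' coordinates come from classical multidimensional scaling of the model
#' RDM; they are embedded into voxel space by a random linear map and mixed
#' with iid Gaussian noise patterns. The mixing weight is calibrated by
#' bisection so that the achieved model-neural correlation, averaged over
#' `n_reps` internal noise replicates, lands within `tol` of `rho_target`.
#'
#' @param model a [model_rdm()].
#' @param n_voxels number of voxels (>= 20).
#' @param rho_target target Pearson correlation in \[0, 1).
#' @param seed integer seed.
#' @param tol calibration tolerance on the achieved correlation.
#' @param n_reps internal replicates used to estimate the achieved
#'   correlation during calibration.
#' @param max_iter bisection iteration cap.
#' @return Items x voxels matrix with attributes `achieved_rho` (measured on
#'   the returned draw), `weight` (calibrated mixing weight).
#' @export
plant_item_patterns <- function(model, n_voxels, rho_target, seed = 1L,
                                tol = 0.05, n_reps = 20L, max_iter = 40L) {
  if (rho_target < 0 || rho_target >= 1) abort("`rho_target` must be in [0, 1).")
  if (n_voxels < 20L) abort("Need at least 20 voxels.")
  n <- nrow(model)
  mvec <- rdm_vectorize(model)
  withr_seed(child_seed(seed, 77L))
  coords <- suppressWarnings(cmdscale(unclass(model), k = min(n - 1L, 12L)))
  proto <- coords %*% matrix(rnorm(ncol(coords) * n_voxels), ncol(coords), n_voxels)
  proto <- proto / sd(proto)

  achieved_for <- function(w, rep_id) {
    withr_seed(child_seed(seed, 101L, rep_id))
    noise <- matrix(rnorm(n * n_voxels), n, n_voxels)
    pat <- w * proto + (1 - w) * noise
    nv <- rdm_vectorize(neural_rdm(pat))
    list(r = cor(nv, mvec), pat = pat)
  }
  mean_achieved <- function(w) {
    mean(vapply(seq_len(n_reps), function(i) achieved_for(w, i)$r, numeric(1)))
  }

  if (rho_target == 0) {
    w <- 0
  } else {
    lo <- 0; hi <- 1
    r_hi <- mean_achieved(1)
    if (r_hi < rho_target - tol) {
      abort(sprintf(
        "Calibration infeasible: pure-signal patterns achieve r = %.3f < target %.3f.",
        r_hi, rho_target))
    }
    w <- 0.5
    for (it in seq_len(max_iter)) {
      r_w <- mean_achieved(w)
      if (abs(r_w - rho_target) <= tol / 2) break
      if (r_w < rho_target) lo <- w else hi <- w
      w <- (lo + hi) / 2
    }
  }
  draw <- achieved_for(w, 0L)
  structure(draw$pat, achieved_rho = draw$r, weight = w)
}

#' Simulate BOLD runs for one subject
#'
#' Generates each run as design x patterns plus noise: the LSA trial
#' regressors (word presentation boxcars convolved with the true HRF) are
#' multiplied by the subject's ground-truth item patterns, and Gaussian
#' noise — optionally with AR(1) temporal autocorrelation — is added at
#' every voxel. Deterministic under `seed`.
#'
#' @param truth an `item_patterns` object holding the subject's ground-truth
#'   patterns for all items (both conditions).
#' @param events_by_run list of per-run event tables.
#' @param n_vols volumes per run.
#' @param tr repetition time, seconds.
#' @param hrf HRF kernel (step `dt`).
#' @param dt convolution grid step, seconds.
#' @param noise_sd BOLD noise standard deviation (pattern scale is ~1).
#' @param ar1 AR(1) coefficient for temporal noise autocorrelation
#'   (0 = white).
#' @param seed integer seed.
#' @return List of [bold_run()]s.
#' @export
simulate_subject_bold <- function(truth, events_by_run, n_vols = 100L,
                                  tr = 1.8, hrf = gamma_hrf(dt = dt), dt = 0.1,
                                  noise_sd = 0.5, ar1 = 0, seed = 1L) {
  stopifnot(inherits(truth, "item_patterns"))
  dims <- truth$geometry$dim
  mask <- array(FALSE, dims)
  mask[truth$voxels] <- TRUE
  lapply(seq_along(events_by_run), function(r) {
    events <- validate_events(events_by_run[[r]], run_length = n_vols * tr)
    des <- build_design_matrix(events, n_vols = n_vols, tr = tr, hrf = hrf, dt = dt)
    rows <- match(events$word, truth$items)
    if (anyNA(rows)) abort("Events contain words absent from the truth patterns.")
    signal <- des$X[, des$trial_idx, drop = FALSE] %*% truth$beta[rows, , drop = FALSE]
    withr_seed(child_seed(seed, 211L, r))
    eps <- matrix(rnorm(n_vols * ncol(signal), sd = noise_sd), n_vols)
    if (ar1 != 0) {
      eps <- apply(eps, 2L, function(e) {
        as.numeric(stats::filter(e, ar1, method = "recursive")) * sqrt(1 - ar1^2)
      })
    }
    Y <- signal + eps
    data <- array(0, c(dims, n_vols))
    flat <- matrix(data, prod(dims), n_vols)
    flat[truth$voxels, ] <- t(Y)
    bold_run(array(flat, c(dims, n_vols)), tr = tr, mask = mask,
             affine = truth$geometry$affine)
  })
}

#' Ellipsoidal brain mask
#'
#' @param dims 3-vector of volume dimensions.
#' @param semi_axes semi-axes in voxels; defaults to 0.45 of each dimension.
#' @return 3D logical array.
#' @export
ellipsoid_mask <- function(dims, semi_axes = 0.45 * dims) {
  ctr <- (dims + 1) / 2
  idx <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- ((idx[, 1] - ctr[1]) / semi_axes[1])^2 +
    ((idx[, 2] - ctr[2]) / semi_axes[2])^2 +
    ((idx[, 3] - ctr[3]) / semi_axes[3])^2
  array(d2 <= 1, dims)
}

#' Spherical plant region
#'
#' @param dims volume dimensions.
#' @param center sphere centre in voxel coordinates (defaults to the volume
#'   centre).
#' @param radius sphere radius in voxels.
#' @return 3D logical array.
#' @export
sphere_region <- function(dims, center = (dims + 1) / 2, radius = 4.5) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  array(d2 <= radius^2, dims)
}

#' Specify a geometry plant
#'
#' Describes one planted representational effect: in which region, for
#' which hypothesis model, at what target model-neural correlation, and in
#' which condition(s).
#'
#' @param region 3D logical array (must lie inside the study mask).
#' @param model model tag (`"visual"`, `"orthographic"`, `"phonological"`,
#'   `"semantic"`, `"articulatory"`).
#' @param rho_target target correlation in \[0, 1).
#' @param conditions `"aloud"`, `"silent"`, or both.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(region, model, rho_target = 0.5, conditions = "aloud") {
  if (rho_target < 0 || rho_target >= 1) abort("`rho_target` must be in [0, 1).")
  structure(list(region = region, model = model, rho_target = rho_target,
                 conditions = conditions),
            class = "plant_spec")
}

#' Generate a complete synthetic study
#'
#' Builds a full multi-subject dataset matching the modelled experimental
#' design: one shared lexicon; per-subject random word-condition
#' allocation; per-subject, per-condition hypothesis models built by the
#' stimulus-model module from the synthetic lexicon; ground-truth item
#' patterns over the mask (iid noise outside plant regions, calibrated
#' planted geometry inside); and per-subject BOLD runs (default 4 runs of
#' 100 volumes at TR 1.8 s, 30 trials per run at a fixed 6 s SOA, each word
#' once per run in a random order, word onset 1.5 s into its trial with a
#' 2.5 s presentation).
#'
#' @param n_subjects number of subjects (study default 26; use fewer for
#'   desk-scale tests).
#' @param dims volume dimensions.
#' @param mask brain mask (defaults to an ellipsoid).
#' @param plant_specs list of [plant_spec()]s (empty = pure null study).
#' @param seed master seed; all per-subject/per-run randomness is derived
#'   from it.
#' @param n_runs runs per subject.
#' @param n_vols volumes per run.
#' @param tr repetition time, seconds.
#' @param soa stimulus onset asynchrony, seconds.
#' @param word_onset_in_trial word onset relative to trial start, seconds.
#' @param word_duration word presentation duration, seconds.
#' @param noise_sd,ar1 BOLD noise parameters (see
#'   [simulate_subject_bold()]).
#' @param lex optional pre-built lexicon (defaults to
#'   [generate_lexicon()] with 30 words).
#' @param keep_bold if `FALSE`, BOLD runs are omitted (events, models and
#'   ground truth only).
#' @return A `synthetic_dataset`: list with `lexicon`, `mask`, `geometry`,
#'   `subjects` (per subject: `lexicon` with allocation, `models` per
#'   condition, `truth`, `events`, `runs`), `plant_specs`, `achieved`
#'   (tibble of calibrated correlations), `seed`.
#' @export
make_dataset <- function(n_subjects = 26L, dims = c(24L, 24L, 16L),
                         mask = ellipsoid_mask(dims), plant_specs = list(),
                         seed = 1L, n_runs = 4L, n_vols = 100L, tr = 1.8,
                         soa = 6, word_onset_in_trial = 1.5,
                         word_duration = 2.5, noise_sd = 0.5, ar1 = 0,
                         lex = NULL, keep_bold = TRUE) {
  if (inherits(plant_specs, "plant_spec")) plant_specs <- list(plant_specs)
  for (ps in plant_specs) {
    if (any(ps$region & !mask)) abort("Plant region extends outside the mask.")
  }
  lex <- lex %||% generate_lexicon(n = 30L, seed = child_seed(seed, 1L))
  n_words <- nrow(lex)
  vox <- which(mask)
  geometry <- list(dim = dims, affine = default_affine())
  hrf <- gamma_hrf()
  achieved <- list()

  subjects <- lapply(seq_len(n_subjects), function(s) {
    slex <- allocate_conditions(lex, seed = child_seed(seed, 2L, s))
    models <- list(
      aloud = build_hypothesis_models(slex, "aloud"),
      silent = build_hypothesis_models(slex, "silent")
    )
    # ground-truth patterns: iid noise everywhere, planted geometry in regions
    withr_seed(child_seed(seed, 3L, s))
    beta <- matrix(rnorm(n_words * length(vox)), n_words, length(vox))
    for (pi in seq_along(plant_specs)) {
      ps <- plant_specs[[pi]]
      cols <- match(which(ps$region & mask), vox)
      for (cond in ps$conditions) {
        cond_words <- slex$word[slex$condition == cond]
        mdl <- models[[cond]][[ps$model]]
        pat <- plant_item_patterns(mdl, n_voxels = length(cols),
                                   rho_target = ps$rho_target,
                                   seed = child_seed(seed, 4L, s, pi))
        rows <- match(cond_words, slex$word)
        beta[rows, cols] <- pat
        achieved[[length(achieved) + 1L]] <<- tibble(
          subject = s, plant = pi, model = ps$model, condition = cond,
          rho_target = ps$rho_target,
          achieved_rho = attr(pat, "achieved_rho"),
          weight = attr(pat, "weight"))
      }
    }
    truth <- structure(
      list(beta = beta, items = slex$word, conditions = slex$condition,
           voxels = vox, geometry = geometry, centered = FALSE),
      class = "item_patterns")
    events <- lapply(seq_len(n_runs), function(r) {
      withr_seed(child_seed(seed, 5L, s, r))
      ord <- sample(n_words)
      tibble(
        onset = (seq_len(n_words) - 1) * soa + word_onset_in_trial,
        duration = word_duration,
        word = slex$word[ord],
        condition = slex$condition[ord],
        run = r
      )
    })
    runs <- NULL
    if (keep_bold) {
      runs <- simulate_subject_bold(truth, events, n_vols = n_vols, tr = tr,
                                    hrf = hrf, noise_sd = noise_sd, ar1 = ar1,
                                    seed = child_seed(seed, 6L, s))
    }
    list(id = s, lexicon = slex, models = models, truth = truth,
         events = events, runs = runs)
  })
  structure(
    list(lexicon = lex, mask = mask, geometry = geometry,
         subjects = subjects, plant_specs = plant_specs,
         achieved = dplyr::bind_rows(achieved), seed = seed,
         design = list(n_runs = n_runs, n_vols = n_vols, tr = tr, soa = soa,
                       noise_sd = noise_sd, ar1 = ar1)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d subject(s), %d words, %s volume, %d plant(s), seed %s\n",
    length(x$subjects), nrow(x$lexicon),
    paste(x$geometry$dim, collapse = " x "), length(x$plant_specs),
    format(x$seed)))
  invisible(x)
}
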