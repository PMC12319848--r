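#' Estimate one subject's searchlight beta maps
#'
#' The per-subject arm of the pipeline: fits the LSA GLM to every run,
#' averages each item's trial coefficients across runs, removes the
#' condition-mean pattern, and runs the searchlight RSA once per condition
#' against that subject's condition-specific hypothesis models.
#'
#' @param subject one element of a `synthetic_dataset`'s `subjects` list (or
#'   any list with `runs`, `events`, `models`, `lexicon`); if `runs` is
#'   `NULL` they are simulated on the fly from `truth`.
#' @param design study design parameters (list with `n_vols`, `tr`,
#'   `noise_sd`, `ar1`), as stored in a `synthetic_dataset`.
#' @param radius searchlight radius.
#' @param min_voxels minimum sphere size.
#' @param seed seed used only when runs must be simulated.
#' @return Named list of two `beta_maps` (`aloud`, `silent`).
#' @export
analyze_subject <- function(subject, design, radius = 3, min_voxels = 10L,
                            seed = 1L) {
  runs <- subject$runs
  if (is.null(runs)) {
    runs <- simulate_subject_bold(subject$truth, subject$events,
                                  n_vols = design$n_vols, tr = design$tr,
                                  noise_sd = design$noise_sd,
                                  ar1 = design$ar1,
                                  seed = child_seed(seed, 6L, subject$id))
  }
  trials <- lapply(seq_along(runs), function(r) {
    des <- build_design_matrix(subject$events[[r]], n_vols = design$n_vols,
                               tr = design$tr)
    fit_lsa(runs[[r]], des)
  })
  items <- average_item_patterns(trials, item_order = subject$lexicon$word)
  items$conditions <- subject$lexicon$condition
  items <- subtract_condition_mean(items)
  out <- lapply(c(aloud = "aloud", silent = "silent"), function(cond) {
    run_searchlight(filter_condition(items, cond), subject$models[[cond]],
                    radius = radius, min_voxels = min_voxels)
  })
  out
}

#' Group Bayes-factor analysis of subject beta maps
#'
#' The group arm of the pipeline. For each of the five hypothesis models:
#' stacks the subjects' aloud and silent beta maps; computes right-tailed
#' within-condition JZS Bayes maps and the two-sided paired between-condition
#' map; thresholds all three at `bf_floor`; splits the between map into
#' directional contrasts masked by the minuend condition's within map; and
#' extracts 26-connected clusters of at least `min_extent` voxels from the
#' within maps and both directional maps.
#'
#' @param subject_betas list over subjects of named lists of `beta_maps`
#'   (`aloud`, `silent`), as returned by [analyze_subject()].
#' @param bf_floor evidence threshold for all maps.
#' @param min_extent minimum cluster extent in voxels.
#' @param models model tags to analyse; defaults to those present.
#' @return A `group_results` list: `within` (thresholded `bf_map` per model
#'   and condition), `between`, `contrasts` (`aloud_gt_silent`,
#'   `silent_gt_aloud` per model), and `clusters`, a tibble of all cluster
#'   rows tagged by `model` and `map`.
#' @export
group_analysis <- function(subject_betas, bf_floor = 3.0, min_extent = 20L,
                           models = NULL) {
  models <- models %||% names(subject_betas[[1]]$aloud$maps)
  within <- list()
  between <- list()
  contrasts <- list()
  cluster_rows <- list()
  for (mdl in models) {
    stack_a <- group_stack(lapply(subject_betas, function(s) s$aloud), mdl)
    stack_s <- group_stack(lapply(subject_betas, function(s) s$silent), mdl)
    wa <- threshold_map(within_condition_maps(stack_a), floor = bf_floor)
    ws <- threshold_map(within_condition_maps(stack_s), floor = bf_floor)
    bt <- threshold_map(between_condition_map(stack_a, stack_s), floor = bf_floor)
    dc <- directional_contrast(bt, stack_a, stack_s, wa, ws)
    within[[mdl]] <- list(aloud = wa, silent = ws)
    between[[mdl]] <- bt
    contrasts[[mdl]] <- list(aloud_gt_silent = dc$a_gt_b,
                             silent_gt_aloud = dc$b_gt_a)
    for (nm in c("aloud", "silent")) {
      cl <- extract_clusters(within[[mdl]][[nm]], min_extent = min_extent)
      if (nrow(cl)) cluster_rows[[length(cluster_rows) + 1L]] <-
          dplyr::bind_cols(tibble(model = mdl, map = nm), cl)
    }
    for (nm in c("aloud_gt_silent", "silent_gt_aloud")) {
      cl <- extract_clusters(contrasts[[mdl]][[nm]], min_extent = min_extent)
      if (nrow(cl)) cluster_rows[[length(cluster_rows) + 1L]] <-
          dplyr::bind_cols(tibble(model = mdl, map = nm), cl)
    }
  }
  empty <- tibble(model = character(), map = character(),
                  cluster_id = integer(), extent_voxels = integer(),
                  mean_bf10 = numeric(), max_bf10 = numeric(),
                  x_mm = numeric(), y_mm = numeric(), z_mm = numeric())
  structure(
    list(within = within, between = between, contrasts = contrasts,
         clusters = if (length(cluster_rows)) dplyr::bind_rows(cluster_rows) else empty),
    class = "group_results"
  )
}

#' @export
print.group_results <- function(x, ...) {
  cat(sprintf("<group_results> models: %s\n", paste(names(x$within), collapse = ", ")))
  cat(sprintf("%d cluster(s) across all maps\n", nrow(x$clusters)))
  invisible(x)
}

#' Run a full synthetic study end to end
#'
#' Generates a synthetic dataset (streaming BOLD per subject to bound
#' memory), estimates every subject's beta maps, and runs the group
#' analysis.
#'
#' @inheritParams make_dataset
#' @inheritParams group_analysis
#' @param radius searchlight radius.
#' @param min_voxels minimum sphere size.
#' @return List with `dataset` (BOLD omitted), `subject_betas`, and
#'   `group` (a `group_results`).
#' @export
run_study <- function(n_subjects = 12L, dims = c(24L, 24L, 16L),
                      mask = ellipsoid_mask(dims), plant_specs = list(),
                      seed = 1L, noise_sd = 0.5, ar1 = 0, radius = 3,
                      min_voxels = 10L, bf_floor = 3.0, min_extent = 20L,
                      lex = NULL) {
  ds <- make_dataset(n_subjects = n_subjects, dims = dims, mask = mask,
                     plant_specs = plant_specs, seed = seed,
                     noise_sd = noise_sd, ar1 = ar1, lex = lex,
                     keep_bold = FALSE)
  subject_betas <- lapply(ds$subjects, function(subj) {
    analyze_subject(subj, ds$design, radius = radius,
                    min_voxels = min_voxels, seed = ds$seed)
  })
  grp <- group_analysis(subject_betas, bf_floor = bf_floor,
                        min_extent = min_extent)
  list(dataset = ds, subject_betas = subject_betas, group = grp)
}

#' Overlap between a cluster map and a reference region
#'
#' Dice coefficient between the defined voxels of a thresholded map
#' (optionally restricted to clusters surviving the extent threshold) and a
#' reference region.
#'
#' @param map a thresholded `bf_map`.
#' @param region 3D logical array.
#' @param min_extent if given, only voxels in clusters of at least this
#'   extent count.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(map, region, min_extent = NULL) {
  a <- !is.na(map)
  if (!is.null(min_extent)) {
    vox <- which(a)
    if (length(vox)) {
      labels <- label_components(vox, dim(map), 26L)
      tabs <- tabulate(labels)
      a <- array(FALSE, dim(map))
      a[vox[tabs[labels] >= min_extent]] <- TRUE
    }
  }
  b <- as.logical(region)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
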