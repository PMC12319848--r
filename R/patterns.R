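#' BOLD run container
#'
#' Wraps a 4D BOLD array with its acquisition metadata: repetition time,
#' 3D brain mask, and voxel-to-mm affine.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param tr repetition time, seconds.
#' @param mask 3D logical array matching the spatial dimensions.
#' @param affine 4 x 4 voxel-to-mm transform; defaults to 3.75 mm isotropic
#'   voxels at the origin.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr, mask, affine = default_affine()) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array.")
  if (tr <= 0) abort("`tr` must be positive.")
  mask <- array(as.logical(mask), dim = dim(data)[1:3])
  if (!any(mask)) abort("Mask is empty.")
  structure(list(data = data, tr = tr, mask = mask, affine = affine),
            class = "bold_run")
}

default_affine <- function(voxel_mm = 3.75) {
  a <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  a
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d, %d volumes, TR %.3g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Fit a least-squares-all single-trial GLM
#'
#' Ordinary least squares of every in-mask voxel time series on the full
#' LSA design (all trial regressors plus intercept and nuisance columns,
#' fitted jointly). Returns the per-trial coefficients only — the
#' single-trial activation pattern estimates — with intercept and nuisance
#' coefficients discarded. Optionally removes a per-voxel linear trend
#' before fitting (off by default; a stand-in for high-pass filtering when
#' the input is real rather than simulated data).
#'
#' @param run a [bold_run()].
#' @param design a [build_design_matrix()] result; its time dimension must
#'   match the run.
#' @param detrend remove a per-voxel linear trend first.
#' @return A `trial_patterns` object: list with `beta` (trials x voxels),
#'   `words`, `conditions`, `voxels` (linear indices into the volume),
#'   `geometry`.
#' @export
fit_lsa <- function(run, design, detrend = FALSE) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "design_matrix"))
  X <- design$X
  n_vols <- nrow(X)
  if (dim(run$data)[4] != n_vols) {
    abort("Run and design disagree on the number of volumes.")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("Design matrix is rank deficient.")
  vox <- which(run$mask)
  Y <- t(matrix(run$data, prod(dim(run$data)[1:3]), n_vols)[vox, , drop = FALSE])
  if (detrend) {
    tt <- seq_len(n_vols)
    Y <- qr.resid(qr(cbind(1, tt)), Y) + matrix(colMeans(Y), n_vols,
                                                ncol(Y), byrow = TRUE)
  }
  B <- qr.coef(qx, Y)
  structure(
    list(beta = B[design$trial_idx, , drop = FALSE],
         words = design$labels,
         conditions = design$conditions,
         voxels = vox,
         geometry = list(dim = dim(run$data)[1:3], affine = run$affine)),
    class = "trial_patterns"
  )
}

#' Average single-trial patterns into item patterns
#'
#' Pools trial patterns across runs and averages, for every unique word, the
#' coefficient maps of that word's trials (one per run; four in the default
#' design). Every item must have the same repetition count. Item order
#' follows `item_order` if given, otherwise the sorted unique word list.
#'
#' @param trials a `trial_patterns` object or a list of them (one per run)
#'   sharing voxel geometry.
#' @param item_order optional character vector fixing item order.
#' @return An `item_patterns` object: list with `beta` (items x voxels),
#'   `items`, `conditions` (per item), `voxels`, `geometry`,
#'   `centered = FALSE`.
#' @export
average_item_patterns <- function(trials, item_order = NULL) {
  if (inherits(trials, "trial_patterns")) trials <- list(trials)
  vox <- trials[[1]]$voxels
  for (tp in trials) {
    if (!identical(tp$voxels, vox)) abort("Runs disagree on voxel geometry.")
  }
  beta <- do.call(rbind, lapply(trials, `[[`, "beta"))
  words <- unlist(lapply(trials, `[[`, "words"), use.names = FALSE)
  conds <- unlist(lapply(trials, `[[`, "conditions"), use.names = FALSE)
  counts <- table(words)
  if (length(unique(as.integer(counts))) != 1L) {
    bad <- names(counts)[counts != max(counts)]
    abort(sprintf("Unequal repetition counts; offending word(s): %s",
                  paste(bad, collapse = ", ")))
  }
  items <- if (is.null(item_order)) sort(unique(words)) else item_order
  if (!setequal(items, unique(words))) abort("`item_order` must cover exactly the observed words.")
  avg <- do.call(rbind, lapply(items, function(w) {
    colMeans(beta[words == w, , drop = FALSE])
  }))
  item_cond <- vapply(items, function(w) conds[match(w, words)], character(1))
  structure(
    list(beta = avg, items = items, conditions = unname(item_cond),
         voxels = vox, geometry = trials[[1]]$geometry, centered = FALSE),
    class = "item_patterns"
  )
}

#' @export
print.item_patterns <- function(x, ...) {
  cat(sprintf("<item_patterns> %d items x %d voxels (%scentered)\n",
              nrow(x$beta), ncol(x$beta), if (x$centered) "" else "not "))
  invisible(x)
}

#' Subtract the condition-mean activation pattern
#'
#' Removes, at every voxel, the mean value across items — the "cocktail
#' blank" — so that the residual patterns carry only item-specific
#' structure. When the object holds items from both conditions the mean is
#' computed and removed within each condition separately. Idempotent; after
#' centering, per-voxel means within each condition are zero to 1e-9.
#'
#' @param items an `item_patterns` object with at least 2 items per
#'   condition.
#' @return The centered `item_patterns` (`centered = TRUE`).
#' @export
subtract_condition_mean <- function(items) {
  stopifnot(inherits(items, "item_patterns"))
  beta <- items$beta
  for (cond in unique(items$conditions)) {
    rows <- which(items$conditions == cond)
    if (length(rows) < 2L) {
      abort(sprintf("Condition '%s' has a single item; centering is degenerate.", cond))
    }
    mu <- colMeans(beta[rows, , drop = FALSE])
    beta[rows, ] <- sweep(beta[rows, , drop = FALSE], 2L, mu)
  }
  items$beta <- beta
  items$centered <- TRUE
  items
}

#' Restrict item patterns to one condition
#'
#' @param items an `item_patterns` object.
#' @param condition condition label to keep.
#' @return An `item_patterns` object holding that condition's items only.
#' @export
filter_condition <- function(items, condition) {
  rows <- which(items$conditions == condition)
  if (!length(rows)) abort(sprintf("No items in condition '%s'.", condition))
  items$beta <- items$beta[rows, , drop = FALSE]
  items$items <- items$items[rows]
  items$conditions <- items$conditions[rows]
  items
}
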