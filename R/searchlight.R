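#' Integer offsets of a spherical searchlight
#'
#' All integer (dx, dy, dz) offsets with Euclidean norm at most `radius`, in
#' lexicographic order. Radius 3 — the default searchlight — yields 123
#' offsets.
#'
#' @param radius sphere radius in voxel units, >= 0.
#' @return Integer matrix with columns dx, dy, dz.
#' @export
#' @examples
#' nrow(sphere_offsets(3))  # 123
sphere_offsets <- function(radius) {
  if (!is.finite(radius) || radius < 0) abort("`radius` must be >= 0.")
  r <- floor(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)[, c("dx", "dy", "dz")]
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Neural dissimilarity matrix of a pattern set
#'
#' Pairwise Pearson correlation distances (1 minus the Pearson correlation)
#' between item activation patterns; the local "neural RDM" computed within
#' each searchlight sphere.
#'
#' @param patterns items x voxels numeric matrix with at least 3 rows; no
#'   item pattern may be constant.
#' @return Square symmetric matrix with zero diagonal, entries in \[0, 2\].
#' @export
neural_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 3L) abort("Need at least 3 item patterns.")
  correlation_distance_matrix(patterns, what = "item pattern")
}

#' Regress a neural RDM on hypothesis model RDMs
#'
#' The vectorised neural RDM and each vectorised model RDM are z-scored
#' (sample standardisation) and the neural vector is regressed on the five
#' model vectors jointly by ordinary least squares, with an intercept. The
#' returned coefficients — the searchlight betas — measure each model's
#' unique contribution to the local pattern geometry with the other models
#' partialled out.
#'
#' @param neural vectorised neural RDM.
#' @param models matrix with one column per vectorised model RDM (or a list
#'   of vectors / `model_rdm`s).
#' @return Named numeric vector of model coefficients.
#' @export
rdm_regression <- function(neural, models) {
  if (is.list(models)) {
    models <- do.call(cbind, lapply(models, function(m) {
      if (inherits(m, "model_rdm")) rdm_vectorize(m) else as.numeric(m)
    }))
  }
  models <- as.matrix(models)
  if (length(neural) != nrow(models)) abort("Vector lengths disagree.")
  zn <- zscore_strict(neural, "neural RDM vector")
  Z <- apply(models, 2L, zscore_strict, label = "model RDM vector")
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("Model regressors are collinear.")
  coefs <- qr.coef(qx, zn)[-1L]
  names(coefs) <- colnames(models)
  coefs
}

zscore_strict <- function(v, label = "vector") {
  s <- sd(v)
  if (!is.finite(s) || s == 0) abort(sprintf("Zero-variance %s.", label))
  (v - mean(v)) / s
}

#' Whole-volume searchlight RSA
#'
#' For every in-mask voxel, collects the item patterns in the spherical
#' neighbourhood (sphere intersected with the mask, truncated at volume
#' boundaries), computes the neural RDM, and regresses it on the five
#' hypothesis models, writing each model's beta at the centre voxel.
#' Spheres with fewer than `min_voxels` members, or whose neural RDM is
#' degenerate (a constant item pattern or zero-variance RDM vector), yield
#' `NA` at the centre in all maps.
#'
#' @param items a single-condition `item_patterns` object (normally
#'   mean-centered; see [subtract_condition_mean()]).
#' @param models named list of `model_rdm`s whose item lists match
#'   `items$items` (same words, any order is an error — order must agree).
#' @param radius searchlight radius in voxels.
#' @param min_voxels minimum sphere size; smaller (edge) spheres are
#'   invalid.
#' @return A `beta_maps` object: list of 3D arrays (one per model, `NA`
#'   outside the mask), plus `condition`, `geometry`, `radius`.
#' @export
run_searchlight <- function(items, models, radius = 3, min_voxels = 10L) {
  stopifnot(inherits(items, "item_patterns"))
  n_items <- length(items$items)
  for (m in models) {
    if (!identical(rdm_items(m), items$items)) {
      abort("Model item lists must match the pattern item list (same order).")
    }
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, rdm_measure, character(1))
  }
  dims <- items$geometry$dim
  P <- items$beta
  # z-scored model design, shared by every sphere of this condition
  Z <- vapply(models, function(m) zscore_strict(rdm_vectorize(m), "model RDM vector"),
              numeric(n_items * (n_items - 1L) / 2L))
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("Model regressors are collinear.")
  # (X'X)^-1 X' as an explicit projector so each sphere is a single matmul
  pinv <- solve(crossprod(X), t(X))

  nb <- neighbour_columns(items$voxels, dims, radius)
  lt <- lower_tri_index(n_items)
  n_models <- length(models)
  betas <- matrix(NA_real_, length(items$voxels), n_models)
  for (v in seq_along(items$voxels)) {
    cols <- nb[[v]]
    if (length(cols) < min_voxels) next
    Xp <- P[, cols, drop = FALSE]
    Xc <- Xp - rowMeans(Xp)
    ss <- sqrt(rowSums(Xc * Xc))
    if (any(ss == 0)) next
    cm <- tcrossprod(Xc / ss)
    dvec <- 1 - cm[lt]
    s <- sd(dvec)
    if (!is.finite(s) || s == 0) next
    zn <- (dvec - mean(dvec)) / s
    betas[v, ] <- (pinv %*% zn)[-1L]
  }
  maps <- lapply(seq_len(n_models), function(k) {
    vol <- array(NA_real_, dims)
    vol[items$voxels] <- betas[, k]
    vol
  })
  names(maps) <- names(models)
  structure(
    list(maps = maps, condition = unique(items$conditions),
         geometry = items$geometry, radius = radius,
         items = items$items),
    class = "beta_maps"
  )
}

#' @export
print.beta_maps <- function(x, ...) {
  cat(sprintf("<beta_maps> %s: models %s, %s volume\n",
              paste(x$condition, collapse = "/"),
              paste(names(x$maps), collapse = ", "),
              paste(x$geometry$dim, collapse = " x ")))
  invisible(x)
}

# linear indices of the lower triangle (row-major pair order), matching
# rdm_vectorize()
lower_tri_index <- function(n) {
  p <- lower_pairs(n)
  (p[, "j"] - 1L) * n + p[, "i"]
}

# for each mask voxel: columns (into the pattern matrix) of its in-mask
# sphere neighbours
neighbour_columns <- function(voxels, dims, radius) {
  off <- sphere_offsets(radius)
  lookup <- array(NA_integer_, dims)
  lookup[voxels] <- seq_along(voxels)
  coords <- arrayInd(voxels, dims)
  n_off <- nrow(off)
  lapply(seq_along(voxels), function(v) {
    xyz <- coords[v, ]
    nx <- xyz[1] + off[, 1]; ny <- xyz[2] + off[, 2]; nz <- xyz[3] + off[, 3]
    ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
      nz >= 1L & nz <= dims[3]
    cols <- lookup[cbind(nx[ok], ny[ok], nz[ok])]
    cols[!is.na(cols)]
  })
}
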