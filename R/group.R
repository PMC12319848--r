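#' Stack per-subject beta maps for group inference
#'
#' Collects one model/condition beta map from every subject into a
#' subjects x voxels matrix over the shared mask.
#'
#' @param subject_betas list of `beta_maps` objects, one per subject, with
#'   identical geometry.
#' @param model model tag to extract.
#' @return A `group_stack`: list with `mat` (subjects x voxels), `voxels`,
#'   `geometry`, `model`, `condition`.
#' @export
group_stack <- function(subject_betas, model) {
  if (length(subject_betas) < 2L) abort("Need at least 2 subjects.")
  geo <- subject_betas[[1]]$geometry
  vols <- lapply(subject_betas, function(b) {
    if (!identical(b$geometry$dim, geo$dim)) abort("Subjects disagree on geometry.")
    m <- b$maps[[model]]
    if (is.null(m)) abort(sprintf("No beta map for model '%s'.", model))
    m
  })
  # voxels defined (non-NA) in every subject: complete-case group analysis
  defined <- Reduce(`&`, lapply(vols, function(v) !is.na(v)))
  vox <- which(defined)
  mat <- do.call(rbind, lapply(vols, function(v) v[vox]))
  structure(
    list(mat = mat, voxels = vox, geometry = geo, model = model,
         condition = subject_betas[[1]]$condition),
    class = "group_stack"
  )
}

#' Voxelwise JZS Bayes-factor map for one condition
#'
#' At every voxel with complete data across subjects, performs a one-sample
#' JZS Bayes t-test of the hypothesis that the group-mean searchlight beta
#' exceeds zero (right-tailed by default, matching the within-condition
#' decodability question). Voxels with zero between-subject variance are
#' set missing.
#'
#' @param stack a [group_stack()].
#' @param tail `"right"` (default) or `"two"`.
#' @param rscale Cauchy prior scale.
#' @return A `bf_map` object (3D array of BF10 with metadata attributes).
#' @export
within_condition_maps <- function(stack, tail = "right", rscale = sqrt(2) / 2) {
  stopifnot(inherits(stack, "group_stack"))
  bf <- bf_from_stack_t(stack$mat, tail = tail, rscale = rscale)
  new_bf_map(bf, stack, tag = "within", tail = tail)
}

#' Voxelwise paired JZS Bayes-factor map between conditions
#'
#' Two-sided paired Bayes t-test at every voxel of the hypothesis that
#' searchlight betas differ between two conditions (subjects paired).
#'
#' @param stack_a,stack_b [group_stack()]s for the two conditions, same
#'   subjects in the same order.
#' @inheritParams within_condition_maps
#' @return A `bf_map` with tag `"between"`.
#' @export
between_condition_map <- function(stack_a, stack_b, rscale = sqrt(2) / 2) {
  stopifnot(inherits(stack_a, "group_stack"), inherits(stack_b, "group_stack"))
  if (nrow(stack_a$mat) != nrow(stack_b$mat)) abort("Subject counts differ.")
  common <- intersect(stack_a$voxels, stack_b$voxels)
  da <- stack_a$mat[, match(common, stack_a$voxels), drop = FALSE]
  db <- stack_b$mat[, match(common, stack_b$voxels), drop = FALSE]
  st <- stack_a
  st$mat <- da - db
  st$voxels <- common
  bf <- bf_from_stack_t(st$mat, tail = "two")
  new_bf_map(bf, st, tag = "between", tail = "two")
}

# per-voxel t statistics -> JZS BF; NA where variance is zero
bf_from_stack_t <- function(mat, tail = "right", rscale = sqrt(2) / 2) {
  n <- nrow(mat)
  mu <- colMeans(mat)
  s <- apply(mat, 2L, sd)
  t_stat <- ifelse(s > 0, mu / (s / sqrt(n)), NA_real_)
  vapply(t_stat, function(tv) {
    if (!is.finite(tv)) return(NA_real_)
    jzs_bf_t(tv, n, tail = tail, rscale = rscale)
  }, numeric(1))
}

new_bf_map <- function(bf_values, stack, tag, tail) {
  vol <- array(NA_real_, stack$geometry$dim)
  vol[stack$voxels] <- bf_values
  structure(vol,
            tag = tag, tail = tail, model = stack$model,
            condition = stack$condition, n_subjects = nrow(stack$mat),
            thresholded = FALSE, affine = stack$geometry$affine,
            class = c("bf_map", "array"))
}

#' @export
print.bf_map <- function(x, ...) {
  cat(sprintf("<bf_map> %s %s (%s-tailed), n = %d, %d defined voxel(s)%s\n",
              attr(x, "tag"), attr(x, "model") %||% "", attr(x, "tail"),
              attr(x, "n_subjects"), sum(!is.na(x)),
              if (attr(x, "thresholded")) ", thresholded" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a Bayes-factor map at an evidence floor
#'
#' Voxels with BF10 below `floor` are set missing; the threshold is
#' inclusive (a voxel at exactly the floor is retained) and the operation
#' is idempotent. The conventional floor 3.0 keeps voxels with at least
#' "moderate" evidence.
#'
#' @param map a `bf_map`.
#' @param floor evidence threshold.
#' @return The thresholded `bf_map`.
#' @export
threshold_map <- function(map, floor = 3.0) {
  stopifnot(inherits(map, "bf_map"))
  map[!is.na(map) & map < floor] <- NA_real_
  attr(map, "thresholded") <- TRUE
  map
}

#' Directional contrast maps with minuend masking
#'
#' Splits a thresholded between-condition Bayes map into two directional
#' maps using the sign of the group mean difference d = mean(A) - mean(B),
#' and masks each directional map by the thresholded within-condition map
#' of its minuend condition: a voxel enters A > B only when the between
#' evidence survives, d > 0 strictly, and information was actually
#' decodable in A (within-A map defined there). This excludes differences
#' driven entirely by negative values in the subtrahend condition. The two
#' outputs are disjoint; voxels with d exactly 0 enter neither.
#'
#' @param between thresholded between-condition `bf_map`.
#' @param stack_a,stack_b [group_stack()]s for the minuend (A) and
#'   subtrahend (B) conditions.
#' @param within_a,within_b thresholded within-condition `bf_map`s.
#' @return Named list of two `bf_map`s: `a_gt_b` and `b_gt_a`.
#' @export
directional_contrast <- function(between, stack_a, stack_b, within_a, within_b) {
  for (m in list(between, within_a, within_b)) {
    stopifnot(inherits(m, "bf_map"))
    if (!attr(m, "thresholded")) abort("Maps must be thresholded first.")
    if (!identical(dim(m), dim(between))) abort("Map geometries differ.")
  }
  d <- array(NA_real_, dim(between))
  common <- intersect(stack_a$voxels, stack_b$voxels)
  da <- colMeans(stack_a$mat[, match(common, stack_a$voxels), drop = FALSE])
  db <- colMeans(stack_b$mat[, match(common, stack_b$voxels), drop = FALSE])
  d[common] <- da - db
  a_gt_b <- between
  a_gt_b[!(!is.na(d) & d > 0 & !is.na(within_a))] <- NA_real_
  b_gt_a <- between
  b_gt_a[!(!is.na(d) & d < 0 & !is.na(within_b))] <- NA_real_
  attr(a_gt_b, "tag") <- "contrast"
  attr(b_gt_a, "tag") <- "contrast"
  attr(a_gt_b, "condition") <- paste0(cond_label(stack_a), ">", cond_label(stack_b))
  attr(b_gt_a, "condition") <- paste0(cond_label(stack_b), ">", cond_label(stack_a))
  list(a_gt_b = a_gt_b, b_gt_a = b_gt_a)
}

cond_label <- function(stack) paste(stack$condition, collapse = "/")

#' Extract suprathreshold clusters from a Bayes map
#'
#' Finds connected components of defined (suprathreshold) voxels under
#' 26-neighbour connectivity, drops components smaller than `min_extent`,
#' and reports, per cluster: extent in voxels, mean and maximum BF10, and
#' the BF-weighted centre of gravity mapped to mm via the affine. Rows are
#' sorted by mean BF10, descending.
#'
#' @param map a thresholded `bf_map`.
#' @param min_extent minimum cluster extent in voxels.
#' @param affine 4 x 4 voxel-to-mm transform; defaults to the map's.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return A tibble with columns `cluster_id`, `extent_voxels`,
#'   `mean_bf10`, `max_bf10`, `x_mm`, `y_mm`, `z_mm` (possibly 0 rows).
#' @export
extract_clusters <- function(map, min_extent = 20L, affine = NULL,
                             connectivity = 26L) {
  stopifnot(inherits(map, "bf_map"))
  if (!attr(map, "thresholded")) abort("Cluster extraction expects a thresholded map.")
  affine <- affine %||% attr(map, "affine") %||% default_affine()
  dims <- dim(map)
  vox <- which(!is.na(map))
  empty <- tibble(cluster_id = integer(), extent_voxels = integer(),
                  mean_bf10 = numeric(), max_bf10 = numeric(),
                  x_mm = numeric(), y_mm = numeric(), z_mm = numeric())
  if (!length(vox)) return(empty)
  labels <- label_components(vox, dims, connectivity)
  tabs <- tabulate(labels)
  keep <- which(tabs >= min_extent)
  if (!length(keep)) return(empty)
  rows <- purrr::map_dfr(seq_along(keep), function(k) {
    members <- vox[labels == keep[k]]
    bf <- map[members]
    xyz0 <- arrayInd(members, dims) - 1L  # 0-based voxel coords
    w <- bf / sum(bf)
    cog_vox <- colSums(xyz0 * w)
    cog_mm <- as.numeric(affine %*% c(cog_vox, 1))[1:3]
    tibble(extent_voxels = length(members), mean_bf10 = mean(bf),
           max_bf10 = max(bf), x_mm = cog_mm[1], y_mm = cog_mm[2],
           z_mm = cog_mm[3])
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$mean_bf10))
  dplyr::bind_cols(tibble(cluster_id = seq_len(nrow(rows))), rows)
}

# connected-component labelling over a voxel subset (flood fill)
label_components <- function(vox, dims, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) abort("`connectivity` must be 6 or 26.")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  off <- as.matrix(g)
  inset <- array(0L, dims)
  inset[vox] <- seq_along(vox)
  coords <- arrayInd(vox, dims)
  labels <- integer(length(vox))
  current <- 0L
  for (s in seq_along(vox)) {
    if (labels[s] != 0L) next
    current <- current + 1L
    queue <- s
    head_ptr <- 1L
    labels[s] <- current
    while (head_ptr <= length(queue)) {
      v <- queue[[head_ptr]]
      head_ptr <- head_ptr + 1L
      xyz <- coords[v, ]
      nx <- xyz[1] + off[, 1]; ny <- xyz[2] + off[, 2]; nz <- xyz[3] + off[, 3]
      ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
        nz >= 1L & nz <= dims[3]
      nb <- inset[cbind(nx[ok], ny[ok], nz[ok])]
      nb <- nb[nb != 0L]
      fresh <- nb[labels[nb] == 0L]
      if (length(fresh)) {
        labels[fresh] <- current
        queue <- c(queue, fresh)
      }
    }
  }
  labels
}

#' Tidy a Bayes-factor map into a voxel table
#'
#' @param x a `bf_map`.
#' @param ... unused.
#' @return Tibble with voxel indices (`x`, `y`, `z`, 1-based) and `bf10`
#'   for every defined voxel.
#' @export
tidy.bf_map <- function(x, ...) {
  vox <- which(!is.na(x))
  xyz <- arrayInd(vox, dim(x))
  tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], bf10 = as.numeric(x[vox]))
}

#' Axial slice mosaic of a Bayes-factor map
#'
#' @param object a `bf_map`.
#' @param slices z slices to draw; defaults to every 2nd slice.
#' @param ... unused.
#' @return A ggplot object (log10 BF10 colour scale).
#' @export
autoplot.bf_map <- function(object, slices = NULL, ...) {
  dims <- dim(object)
  slices <- slices %||% seq(1L, dims[3], by = 2L)
  df <- tidy.bf_map(object)
  df <- dplyr::filter(df, .data$z %in% slices)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = log10(.data$bf10))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s %s BF10 map", attr(object, "condition"),
                                  attr(object, "model") %||% ""),
                  fill = "log10 BF10") +
    ggplot2::theme_minimal()
}
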