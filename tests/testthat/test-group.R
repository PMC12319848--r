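# helpers: build beta_maps / group stacks directly from arrays
mk_betas <- function(vol_list, condition = "aloud", dims = dim(vol_list[[1]])) {
  structure(list(maps = vol_list, condition = condition,
                 geometry = list(dim = dims, affine = diag(c(2, 2, 2, 1))),
                 radius = 3, items = NULL),
            class = "beta_maps")
}
mk_stack <- function(mat, dims, vox = seq_len(prod(dims)),
                     condition = "aloud", model = "m1") {
  structure(list(mat = mat, voxels = vox,
                 geometry = list(dim = dims, affine = diag(c(2, 2, 2, 1))),
                 model = model, condition = condition),
            class = "group_stack")
}

test_that("group stacking keeps complete-case voxels only", {
  dims <- c(3L, 3L, 2L)
  set.seed(1)
  subs <- lapply(1:4, function(s) {
    v <- array(rnorm(prod(dims)), dims)
    if (s == 2) v[2, 2, 1] <- NA
    mk_betas(list(m1 = v))
  })
  st <- group_stack(subs, "m1")
  expect_equal(nrow(st$mat), 4)
  expect_equal(length(st$voxels), prod(dims) - 1)
  expect_false(array(seq_len(prod(dims)), dims)[2, 2, 1] %in% st$voxels)
  expect_error(group_stack(subs[1], "m1"), "at least 2")
  expect_error(group_stack(subs, "nope"), "No beta map")
})

test_that("within-condition map computes right-tailed BFs voxelwise", {
  dims <- c(2L, 2L, 1L)
  set.seed(21)
  mat <- matrix(rnorm(12 * 4), 12, 4)
  mat[, 2] <- mat[, 2] + 2       # strong positive effect
  mat[, 3] <- 5                  # zero variance -> missing
  st <- mk_stack(mat, dims)
  bf <- within_condition_maps(st)
  expect_s3_class(bf, "bf_map")
  expect_equal(bf[2, 1, 1], jzs_bf_one_sample(mat[, 2], tail = "right"))
  expect_true(is.na(bf[1, 2, 1]))  # the zero-variance voxel
  expect_gt(bf[2, 1, 1], 10)
})

test_that("between-condition map is the paired two-sided BF of the difference", {
  dims <- c(2L, 1L, 1L)
  set.seed(5)
  a <- matrix(rnorm(10 * 2, 1), 10, 2)
  b <- matrix(rnorm(10 * 2), 10, 2)
  bf <- between_condition_map(mk_stack(a, dims), mk_stack(b, dims))
  expect_equal(bf[1, 1, 1], jzs_bf_paired(a[, 1], b[, 1]))
  expect_equal(attr(bf, "tail"), "two")
})

test_that("thresholding is inclusive at the floor and idempotent", {
  dims <- c(2L, 2L, 1L)
  vol <- array(c(3.0, 2.99, 10, 0.5), dims)
  bf <- readrsa:::new_bf_map(as.numeric(vol), mk_stack(matrix(0, 2, 4), dims),
                             tag = "within", tail = "right")
  th <- threshold_map(bf, 3.0)
  expect_equal(th[1, 1, 1], 3.0)     # exactly at floor: retained
  expect_true(is.na(th[2, 1, 1]))    # 2.99: removed
  expect_equal(th[1, 2, 1], 10)
  expect_equal(as.numeric(threshold_map(th, 3.0)), as.numeric(th))
  expect_true(attr(th, "thresholded"))
})

test_that("directional contrasts are disjoint and respect the minuend mask", {
  dims <- c(5L, 1L, 1L)
  n <- 8
  # five voxels: (1) d>0 + within_a ok; (2) d>0, within_a missing;
  # (3) d<0 + within_s ok; (4) d = 0; (5) below between threshold
  a <- matrix(c(rep(1, n), rep(0, n), rep(-1, n), rep(0.5, n), rep(0, n)), n)
  s <- matrix(c(rep(-1, n), rep(-2, n), rep(1, n), rep(0.5, n), rep(0, n)), n)
  set.seed(2)
  jit <- matrix(rnorm(n * 5, sd = 0.05), n)
  sa <- mk_stack(a + jit, dims)
  ss <- mk_stack(s - jit, dims, condition = "silent")
  wa <- threshold_map(within_condition_maps(sa), 3)
  ws <- threshold_map(within_condition_maps(ss), 3)
  bt <- threshold_map(between_condition_map(sa, ss), 3)
  dc <- directional_contrast(bt, sa, ss, wa, ws)
  gt <- dc$a_gt_b; lt <- dc$b_gt_a
  expect_false(any(!is.na(gt) & !is.na(lt)))          # disjoint
  expect_true(!is.na(gt[1, 1, 1]))                    # voxel 1 in aloud>silent
  expect_true(is.na(gt[2, 1, 1]) && is.na(lt[2, 1, 1]))  # minuend mask veto
  expect_true(!is.na(lt[3, 1, 1]))                    # voxel 3 in silent>aloud
  expect_true(is.na(gt[4, 1, 1]) && is.na(lt[4, 1, 1]))  # d == 0 tie
  expect_true(is.na(gt[5, 1, 1]) && is.na(lt[5, 1, 1]))
})

test_that("cluster extraction drops small components and reports weighted COGs", {
  dims <- c(12L, 12L, 8L)
  vol <- array(NA_real_, dims)
  # 25-voxel blob with a single peak
  blob <- as.matrix(expand.grid(x = 3:7, y = 3:7, z = 4))
  peak <- c(5, 5, 4)
  for (r in seq_len(nrow(blob))) {
    p <- blob[r, ]
    vol[p[1], p[2], p[3]] <- 3 + 50 * exp(-sum((p - peak)^2) / 2)
  }
  # a second, far-away 2-voxel component (below min extent)
  vol[11, 11, 7] <- 9
  vol[11, 12, 7] <- 9
  st <- mk_stack(matrix(0, 2, prod(dims)), dims)
  bf <- readrsa:::new_bf_map(as.numeric(vol), st, "within", "right")
  bf <- threshold_map(bf, 3)
  tab <- extract_clusters(bf, min_extent = 20)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$extent_voxels, 25)
  expect_equal(tab$max_bf10, max(vol, na.rm = TRUE))
  expect_lte(tab$mean_bf10, tab$max_bf10)
  members <- blob[, 1] + (blob[, 2] - 1) * dims[1] +
    (blob[, 3] - 1) * dims[1] * dims[2]
  cog <- oracle_weighted_centroid(vol, members)
  expect_equal(c(tab$x_mm, tab$y_mm, tab$z_mm), unname(cog * 2), tolerance = 1e-8)
  # single suprathreshold voxel -> empty table
  lone <- readrsa:::new_bf_map(c(5, rep(NA, prod(dims) - 1)), st, "within", "right")
  expect_equal(nrow(extract_clusters(threshold_map(lone, 3), 20)), 0)
})

test_that("two separated blobs yield two clusters under 26-connectivity", {
  dims <- c(14L, 6L, 6L)
  vol <- array(NA_real_, dims)
  vol[1:3, 1:3, 1:3] <- 4    # 27 voxels
  vol[6:9, 1:3, 1:3] <- 5    # 36 voxels, gap of 2 at x = 4:5
  st <- mk_stack(matrix(0, 2, prod(dims)), dims)
  bf <- threshold_map(readrsa:::new_bf_map(as.numeric(vol), st, "within", "right"), 3)
  tab <- extract_clusters(bf, min_extent = 20)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$extent_voxels, c(27, 36))
  # diagonal touch merges under 26- but not 6-connectivity
  vol2 <- array(NA_real_, dims)
  vol2[1:3, 1:3, 1:3] <- 4
  vol2[4:6, 4:6, 4:6] <- 4
  bf2 <- threshold_map(readrsa:::new_bf_map(as.numeric(vol2), st, "within", "right"), 3)
  expect_equal(nrow(extract_clusters(bf2, min_extent = 20, connectivity = 26L)), 1)
  expect_equal(nrow(extract_clusters(bf2, min_extent = 20, connectivity = 6L)), 2)
})

test_that("planted and null group stacks behave as expected", {
  dims <- c(4L, 4L, 2L)
  nvox <- prod(dims)
  set.seed(31)
  planted <- matrix(rnorm(12 * nvox, mean = 1), 12)  # effect size d = 1
  null <- matrix(rnorm(12 * nvox), 12)
  bf_p <- within_condition_maps(mk_stack(planted, dims))
  bf_n <- within_condition_maps(mk_stack(null, dims))
  expect_gte(mean(bf_p >= 3, na.rm = TRUE), 0.8)
  expect_lte(mean(bf_n >= 3, na.rm = TRUE), 0.1)
})
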