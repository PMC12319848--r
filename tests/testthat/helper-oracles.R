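# Independent oracles used across the suite. Each recomputes a quantity by a
# different route than the implementation: exhaustive enumeration, closed
# forms, fine-grid (non-adaptive) quadrature, or naive per-voxel loops.

# exhaustive-alignment edit distance: recursively enumerate all monotone
# alignments (match/substitute, insert, delete) and take the minimum cost
oracle_edit_distance <- function(a, b, ft, indel = 1) {
  f <- ncol(ft)
  subcost <- function(p, q) sum(ft[p, ] != ft[q, ]) / f
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    if (i > length(a)) return((length(b) - j + 1) * indel)
    if (j > length(b)) return((length(a) - i + 1) * indel)
    min(rec(i + 1, j + 1) + subcost(a[i], b[j]),
        rec(i + 1, j) + indel,
        rec(i, j + 1) + indel)
  }
  rec(1, 1) / max(length(a), length(b))
}

# open-bigram counts by explicit double loop over index pairs
oracle_bigram_counts <- function(word) {
  ch <- strsplit(word, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (j in seq_along(ch)) {
      if (i < j) out <- c(out, paste0(ch[i], ch[j]))
    }
  }
  table(out)
}

# Pearson correlation distance by the textbook formula (no cor())
oracle_pearson_distance <- function(x, y) {
  n <- length(x)
  xc <- x - sum(x) / n
  yc <- y - sum(y) / n
  1 - sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# two-sided JZS BF via the g-mixture representation (fine trapezoid grid);
# a genuinely different formula from the delta-space adaptive integral the
# implementation uses
oracle_jzs_two_g <- function(t_stat, n, rscale = sqrt(2) / 2, K = 200001L) {
  nu <- n - 1
  u <- seq(1e-10, 1 - 1e-10, length.out = K)
  g <- u / (1 - u)
  lognum <- -0.5 * log1p(n * g) -
    (nu + 1) / 2 * log1p(t_stat^2 / ((1 + n * g) * nu)) +
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    rscale^2 / (2 * g) - 2 * log1p(-u)
  iv <- exp(lognum)
  num <- (sum(iv) - (iv[1] + iv[K]) / 2) * (u[2] - u[1])
  num / (1 + t_stat^2 / nu)^(-(nu + 1) / 2)
}

# one-sided (or two-sided) JZS BF by fine-grid trapezoid over the effect
# size, using the Cauchy-to-uniform substitution delta = rscale * tan(theta)
oracle_jzs_tail <- function(t_stat, n, tail = "right", rscale = sqrt(2) / 2,
                            K = 40001L) {
  nu <- n - 1
  lims <- switch(tail,
    right = c(0, pi / 2),
    left = c(-pi / 2, 0),
    two = c(-pi / 2, pi / 2))
  th <- seq(lims[1] + 1e-9, lims[2] - 1e-9, length.out = K)
  iv <- suppressWarnings(dt(t_stat, nu, ncp = sqrt(n) * rscale * tan(th))) / pi
  m1 <- (sum(iv) - (iv[1] + iv[K]) / 2) * (th[2] - th[1])
  if (tail != "two") m1 <- 2 * m1
  m1 / dt(t_stat, nu)
}

# JZS correlation BF (regression g-prior) by fine trapezoid grid
oracle_cor_bf_jzs <- function(r, n, K = 400001L) {
  u <- seq(1e-10, 1 - 1e-10, length.out = K)
  g <- u / (1 - u)
  lg <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
    1.5 * log(g) - n / (2 * g) - 2 * log1p(-u)
  iv <- exp(lg)
  sqrt(n / 2) / gamma(0.5) * (sum(iv) - (iv[1] + iv[K]) / 2) * (u[2] - u[1])
}

# uniform-prior correlation BF with the hypergeometric factor evaluated by
# its Euler integral representation (vs. the implementation's power series)
oracle_cor_bf_uniform <- function(r, n, K = 50001L) {
  log_hyp_euler <- function(z) {
    c0 <- n - 0.5
    f <- function(t) t^(-0.5) * (1 - t)^(c0 - 1.5) * (1 - z * t)^(-0.5)
    lgamma(c0) - lgamma(0.5) - lgamma(c0 - 0.5) +
      log(integrate(f, 0, 1, rel.tol = 1e-12)$value)
  }
  l0 <- log_hyp_euler(0.5)
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = K)
  lv <- vapply(rho, function(p) {
    (n - 1) / 2 * log1p(-p^2) - (n - 1.5) * log1p(-p * r) +
      log_hyp_euler((1 + p * r) / 2) - l0
  }, numeric(1))
  iv <- exp(lv)
  0.5 * (sum(iv) - (iv[1] + iv[K]) / 2) * (rho[2] - rho[1])
}

# ordinary least squares by explicit normal equations
oracle_normal_equations <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# brute-force searchlight: an independent per-voxel loop that recomputes
# sphere membership, the neural RDM (via cor()), z-scoring (via scale()) and
# the regression (via lm()) from scratch
oracle_searchlight <- function(items, models, radius = 3, min_voxels = 10) {
  dims <- items$geometry$dim
  n_items <- length(items$items)
  # column-major lower-triangle pair order, used consistently for the neural
  # and model vectors (OLS is invariant to observation order)
  vecs <- sapply(models, function(m) unclass(m)[lower.tri(unclass(m))])
  out <- lapply(models, function(m) array(NA_real_, dims))
  vol_lookup <- array(NA_integer_, dims)
  vol_lookup[items$voxels] <- seq_along(items$voxels)
  for (v in seq_along(items$voxels)) {
    ctr <- arrayInd(items$voxels[v], dims)
    cols <- integer(0)
    for (dx in -3:3) for (dy in -3:3) for (dz in -3:3) {
      if (dx^2 + dy^2 + dz^2 > radius^2) next
      p <- ctr + c(dx, dy, dz)
      if (any(p < 1) || any(p > dims)) next
      cc <- vol_lookup[p[1], p[2], p[3]]
      if (!is.na(cc)) cols <- c(cols, cc)
    }
    if (length(cols) < min_voxels) next
    pats <- items$beta[, cols, drop = FALSE]
    if (any(apply(pats, 1, sd) == 0)) next
    cm <- cor(t(pats))
    dvec <- (1 - cm)[lower.tri(cm)]
    if (sd(dvec) == 0) next
    df <- data.frame(y = as.numeric(scale(dvec)), apply(vecs, 2, scale))
    fit <- lm(y ~ ., data = df)
    b <- coef(fit)[-1]
    for (k in seq_along(models)) {
      out[[k]][items$voxels[v]] <- b[k]
    }
  }
  names(out) <- names(models)
  out
}

# intensity-weighted centroid of a labelled blob, 0-based voxel coords
oracle_weighted_centroid <- function(vol, members) {
  xyz <- arrayInd(members, dim(vol)) - 1
  w <- vol[members] / sum(vol[members])
  colSums(xyz * w)
}

# small helper: a toy single-condition item_patterns object over a volume
make_test_items <- function(beta, dims, mask = array(TRUE, dims),
                            condition = "aloud") {
  vox <- which(mask)
  stopifnot(ncol(beta) == length(vox))
  items <- sprintf("w%02d", seq_len(nrow(beta)))
  structure(
    list(beta = beta, items = items,
         conditions = rep(condition, nrow(beta)), voxels = vox,
         geometry = list(dim = dims, affine = diag(c(3.75, 3.75, 3.75, 1))),
         centered = FALSE),
    class = "item_patterns"
  )
}

# toy model RDMs over a given item list from seeded random symmetric matrices
make_test_models <- function(items, n_models = 5, seed = 1) {
  set.seed(seed)
  n <- length(items)
  out <- lapply(seq_len(n_models), function(k) {
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    model_rdm(m, items, measure = paste0("m", k))
  })
  names(out) <- paste0("m", seq_len(n_models))
  out
}
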