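#' Representational dissimilarity matrices
#'
#' A `model_rdm` is a square, symmetric, zero-diagonal matrix of pairwise
#' dissimilarities over an ordered list of items (here, words), tagged with
#' the measure that produced it. Hypothesis models for a 15-word condition
#' are 15 x 15; exemplar models over a full 30-word stimulus set are 30 x 30.
#'
#' @param m numeric square matrix of dissimilarities.
#' @param items character vector of item labels, one per row/column.
#' @param measure tag naming the dissimilarity measure, one of
#'   `"visual"`, `"orthographic"`, `"phonological"`, `"semantic"`,
#'   `"articulatory"`, or another descriptive string.
#'
#' @return An object of class `model_rdm`: the matrix with `items` as
#'   dimnames and attributes `items` and `measure`.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2)
#' model_rdm(m, c("apple", "banana"), "toy")
model_rdm <- function(m, items, measure = "custom") {
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix.")
  n <- nrow(m)
  if (ncol(m) != n) abort("`m` must be square.")
  if (length(items) != n) abort("`items` must have one label per row of `m`.")
  if (any(!is.finite(m))) abort("RDM entries must all be finite.")
  if (any(m < -1e-12)) abort("RDM entries must be non-negative.")
  if (max(abs(m - t(m))) > 1e-8) abort("RDM must be symmetric.")
  if (max(abs(diag(m))) > 1e-8) abort("RDM must have a zero diagonal.")
  m[m < 0] <- 0
  diag(m) <- 0
  m <- (m + t(m)) / 2
  dimnames(m) <- list(items, items)
  structure(m, items = as.character(items), measure = measure,
            class = c("model_rdm", "matrix", "array"))
}

#' @export
print.model_rdm <- function(x, ...) {
  cat(sprintf("<model_rdm> measure: %s, %d items\n",
              attr(x, "measure"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], digits = 3)
  if (nrow(x) > 6L) cat(sprintf("... (%d x %d)\n", nrow(x), ncol(x)))
  invisible(x)
}

rdm_items <- function(x) attr(x, "items")
rdm_measure <- function(x) attr(x, "measure")

#' Vectorize an RDM to its unique off-diagonal entries
#'
#' Extracts the lower-triangle entries (excluding the diagonal) in row-major
#' order: (2,1), (3,1), (3,2), (4,1), ... This is the shared convention used
#' when neural and hypothesis RDMs are entered into regressions or
#' correlated with one another; the result has length n(n-1)/2.
#'
#' @param rdm a `model_rdm` or a plain symmetric numeric matrix.
#' @return Numeric vector of length `n * (n - 1) / 2`.
#' @export
#' @examples
#' m <- model_rdm(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3), c("a", "b", "c"))
#' rdm_vectorize(m)  # d21, d31, d32
rdm_vectorize <- function(rdm) {
  m <- unclass(rdm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("`rdm` must be square.")
  if (max(abs(m - t(m))) > 1e-8) abort("`rdm` must be symmetric.")
  tm <- t(m)
  tm[upper.tri(tm)]
}

# lower-triangle (row-major) index pairs for an n x n matrix, as a 2-col matrix
lower_pairs <- function(n) {
  i <- rep(seq_len(n), times = seq_len(n) - 1L)
  j <- unlist(lapply(seq_len(n), function(k) seq_len(k - 1L)), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Turn an RDM into a tidy pair table
#'
#' @param x a `model_rdm`.
#' @param ... unused.
#' @return A tibble with columns `item_a`, `item_b`, `dissimilarity`, one row
#'   per unordered item pair (lower triangle, row-major order).
#' @export
tidy.model_rdm <- function(x, ...) {
  items <- rdm_items(x)
  p <- lower_pairs(length(items))
  tibble(
    item_a = items[p[, "i"]],
    item_b = items[p[, "j"]],
    dissimilarity = rdm_vectorize(x)
  )
}

#' Heatmap of a dissimilarity matrix
#'
#' @param object a `model_rdm`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.model_rdm <- function(object, ...) {
  items <- rdm_items(object)
  df <- tidyr::expand_grid(item_a = items, item_b = items)
  df$dissimilarity <- as.vector(t(unclass(object)))
  df$item_a <- factor(df$item_a, levels = rev(items))
  df$item_b <- factor(df$item_b, levels = items)
  ggplot2::ggplot(df, ggplot2::aes(.data$item_b, .data$item_a,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      title = sprintf("%s dissimilarity", rdm_measure(object)),
      x = NULL, y = NULL, fill = "dissimilarity"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

# Pearson correlation distance matrix (1 - r) between rows of `x`.
# Errors if any row is constant (correlation undefined).
correlation_distance_matrix <- function(x, what = "row") {
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("Pearson correlation undefined: constant %s(s) %s.",
                  what, paste(which(sds == 0), collapse = ", ")))
  }
  d <- 1 - cor(t(x))
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Write / read an RDM as TSV with a JSON sidecar
#'
#' The matrix is stored as a TSV with a header row of item names; the sidecar
#' (`<path>.json`) records the measure tag and item order.
#'
#' @param rdm a `model_rdm`.
#' @param path output TSV path.
#' @return `write_rdm_tsv()` returns `path` invisibly; `read_rdm_tsv()`
#'   returns a `model_rdm`.
#' @export
write_rdm_tsv <- function(rdm, path) {
  df <- as.data.frame(unclass(rdm))
  names(df) <- rdm_items(rdm)
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(measure = rdm_measure(rdm), items = rdm_items(rdm)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @export
read_rdm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df)
  model_rdm(m, items = side$items, measure = side$measure)
}
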