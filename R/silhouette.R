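# Bundled fixture font: an original 5x7 binary bitmap glyph set for the 26
# lowercase letters, defined in source so rendering is bit-identical on every
# platform. Stimuli in the modelled experiment were lowercase words; only
# geometry (which pixels are ink) matters for the visual dissimilarity model.
glyph_strings <- list(
  a = c(".....", ".....", ".###.", "....#", ".####", "#...#", ".####"),
  b = c("#....", "#....", "####.", "#...#", "#...#", "#...#", "####."),
  c = c(".....", ".....", ".####", "#....", "#....", "#....", ".####"),
  d = c("....#", "....#", ".####", "#...#", "#...#", "#...#", ".####"),
  e = c(".....", ".....", ".###.", "#...#", "#####", "#....", ".###."),
  f = c("..##.", ".#..#", ".#...", "###..", ".#...", ".#...", ".#..."),
  g = c(".....", ".####", "#...#", "#...#", ".####", "....#", ".###."),
  h = c("#....", "#....", "####.", "#...#", "#...#", "#...#", "#...#"),
  i = c("..#..", ".....", ".##..", "..#..", "..#..", "..#..", ".###."),
  j = c("...#.", ".....", "..##.", "...#.", "...#.", "#..#.", ".##.."),
  k = c("#....", "#....", "#..#.", "#.#..", "##...", "#.#..", "#..#."),
  l = c(".##..", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  m = c(".....", ".....", "##.#.", "#.#.#", "#.#.#", "#.#.#", "#.#.#"),
  n = c(".....", ".....", "####.", "#...#", "#...#", "#...#", "#...#"),
  o = c(".....", ".....", ".###.", "#...#", "#...#", "#...#", ".###."),
  p = c(".....", "####.", "#...#", "#...#", "####.", "#....", "#...."),
  q = c(".....", ".####", "#...#", "#...#", ".####", "....#", "....#"),
  r = c(".....", ".....", "#.##.", "##...", "#....", "#....", "#...."),
  s = c(".....", ".....", ".####", "#....", ".###.", "....#", "####."),
  t = c(".#...", ".#...", "###..", ".#...", ".#...", ".#..#", "..##."),
  u = c(".....", ".....", "#...#", "#...#", "#...#", "#...#", ".####"),
  v = c(".....", ".....", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  w = c(".....", ".....", "#.#.#", "#.#.#", "#.#.#", "#.#.#", ".#.#."),
  x = c(".....", ".....", "#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
  y = c(".....", "#...#", "#...#", ".####", "....#", "#...#", ".###."),
  z = c(".....", ".....", "#####", "...#.", "..#..", ".#...", "#####")
)

glyph_width <- 5L
glyph_height <- 7L

# glyph as a 0/1 matrix (rows = pixel rows)
glyph_matrix <- function(ch) {
  rows <- glyph_strings[[ch]]
  if (is.null(rows)) abort(sprintf("No glyph for character '%s' in the fixture font.", ch))
  do.call(rbind, lapply(strsplit(rows, ""), function(r) as.integer(r == "#")))
}

#' Rendering configuration for word silhouettes
#'
#' Controls how words are rasterised to binary silhouette images before the
#' visual dissimilarity model is computed. Words are rendered in the bundled
#' lowercase bitmap fixture font, centred on a fixed-size canvas so that all
#' silhouettes share one geometry.
#'
#' @param canvas_width,canvas_height canvas size in pixels. The default
#'   64 x 11 canvas fits words up to 10 letters in the 5 x 7 fixture font.
#' @param letter_spacing blank columns between adjacent glyphs.
#' @param threshold binarisation threshold in (0, 1) applied to normalised
#'   pixel intensity. The fixture font is already binary, so any threshold in
#'   (0, 1) yields the same silhouette; the parameter exists so greyscale
#'   fonts can be substituted.
#' @return A list of class `render_config`.
#' @export
render_config <- function(canvas_width = 64L, canvas_height = 11L,
                          letter_spacing = 1L, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (canvas_height < glyph_height) abort("canvas too short for the fixture font.")
  structure(
    list(canvas_width = as.integer(canvas_width),
         canvas_height = as.integer(canvas_height),
         letter_spacing = as.integer(letter_spacing),
         threshold = threshold),
    class = "render_config"
  )
}

#' Render a word as a binary silhouette image
#'
#' Rasterises `word` in the bundled bitmap font, centred horizontally and
#' vertically on the canvas, and binarises at `cfg$threshold`. The result is
#' the vectorised silhouette (rows concatenated, row-major), containing only
#' 0 and 1; rendering is fully deterministic for a fixed configuration.
#'
#' @param word a lowercase alphabetic string.
#' @param cfg a [render_config()].
#' @return Integer vector of length `canvas_width * canvas_height`.
#' @export
#' @examples
#' sil <- render_silhouette("salt")
#' sum(sil)  # ink pixel count
render_silhouette <- function(word, cfg = render_config()) {
  if (!is.character(word) || length(word) != 1L || !nzchar(word) ||
      !grepl("^[a-zA-Z]+$", word)) {
    abort("`word` must be a single non-empty alphabetic string.")
  }
  word <- tolower(word)
  chars <- strsplit(word, "")[[1]]
  glyphs <- lapply(chars, glyph_matrix)
  n <- length(chars)
  word_w <- n * glyph_width + (n - 1L) * cfg$letter_spacing
  if (word_w > cfg$canvas_width) {
    abort(sprintf("Canvas width %d too small for '%s' (needs %d pixels).",
                  cfg$canvas_width, word, word_w))
  }
  canvas <- matrix(0L, cfg$canvas_height, cfg$canvas_width)
  x0 <- (cfg$canvas_width - word_w) %/% 2L
  y0 <- (cfg$canvas_height - glyph_height) %/% 2L
  for (k in seq_len(n)) {
    xs <- x0 + (k - 1L) * (glyph_width + cfg$letter_spacing)
    canvas[y0 + seq_len(glyph_height), xs + seq_len(glyph_width)] <- glyphs[[k]]
  }
  # row-major vectorisation (rows concatenated)
  as.integer(t(canvas) >= cfg$threshold)
}

#' Visual dissimilarity model from word silhouettes
#'
#' Builds the visual hypothesis RDM: each word is rendered to a vectorised
#' binary silhouette image and entry (i, j) is the correlation distance
#' `1 - Pearson(silhouette_i, silhouette_j)`.
#'
#' @param words character vector of at least two distinct rendering targets.
#' @param cfg a [render_config()].
#' @return A [model_rdm()] with measure `"visual"`.
#' @export
visual_rdm <- function(words, cfg = render_config()) {
  if (length(words) < 2L) abort("Need at least two words.")
  sils <- do.call(rbind, lapply(words, render_silhouette, cfg = cfg))
  d <- correlation_distance_matrix(sils, what = "silhouette")
  model_rdm(d, items = words, measure = "visual")
}
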