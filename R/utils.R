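# Internal geometry helpers shared across modules.
# Conventions: images are matrices indexed [row, col]; a pixel's position in
# degrees of visual angle is (row * pitch, col * pitch); all logs are natural.

# 8-connected component membership for a set of pixels given as an
# n x 2 matrix of (row, col). Returns an integer vector of length n.
label_components <- function(px) {
  n <- nrow(px)
  if (n <= 1L) return(rep(1L, n))
  key <- paste(px[, 1], px[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    hit <- lookup[paste(px[, 1] + offs[k, 1], px[, 2] + offs[k, 2])]
    ok <- !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, unname(hit[ok]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  as.integer(igraph::components(g)$membership)
}

# Mean luminance of pixels of `label` lying within `band_px` (Euclidean)
# of any pixel in `side_px` (n x 2 row/col matrix).
band_mean <- function(image, regions, side_px, label, band_px = 2L) {
  offs <- expand.grid(dr = -band_px:band_px, dc = -band_px:band_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= band_px^2, ]
  rows <- outer(side_px[, 1], offs$dr, `+`)
  cols <- outer(side_px[, 2], offs$dc, `+`)
  keep <- rows >= 1 & rows <= nrow(image) & cols >= 1 & cols <= ncol(image)
  lin <- unique((cols[keep] - 1L) * nrow(image) + rows[keep])
  lin <- lin[regions[lin] == label]
  mean(image[lin])
}

#' Centroid of a labelled region
#'
#' @param stim A [luminance_stimulus()] object.
#' @param label Integer region label.
#' @return Numeric `c(row, col)` centroid in degrees of visual angle.
#' @export
region_centroid <- function(stim, label) {
  idx <- which(stim$regions == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("region label ", label, " not present in stimulus")
  colMeans(idx) * stim$pitch
}

# Crack midpoints of an edge boundary, in degrees: k x 2 matrix (row, col).
boundary_midpoints <- function(boundary, pitch) {
  (boundary$a + boundary$b) / 2 * pitch
}

clamp01 <- function(x) pmin(1, pmax(0, x))
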