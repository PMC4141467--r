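# V1 stage: directed steps in log luminance at region boundaries.
#
# An "edge" is one connected boundary component between two regions. Its two
# luminances are sampled as means over a 2-px band just inside each side, so
# shallow gradients within a region do not corrupt the local step. The step
# is the natural log of the luminance ratio; boundaries are also classified
# as sharp (candidate reflectance edge) or gradual (candidate illumination
# gradient) from their 10-90% transition width along the boundary normal.

#' Extract edges from a stimulus
#'
#' Finds every 4-neighbour label change in the region map, groups the
#' boundary pixel pairs into connected components per region pair, and
#' returns one edge per component with its near-boundary mean luminances,
#' directed log-luminance step, sharpness class, and a top-down gain
#' (initialised to 1).
#'
#' @param stim A [luminance_stimulus()].
#' @param band_px Width in pixels of the near-boundary sampling band.
#' @param width_threshold Sharpness threshold in deg passed to
#'   [classify_edge_sharpness()].
#' @return An object of class `"edge_set"`: a list with `edges` (data frame
#'   with columns `id`, `region_a`, `region_b`, `lum_a`, `lum_b`, `log_step`
#'   (`log(lum_b / lum_a)`), `sharpness`, `gain`, `n_pix`, `length_deg`),
#'   `boundaries` (per edge, matrices `a` and `b` of paired boundary pixels),
#'   and `pitch`.
#' @export
extract_edges <- function(stim, band_px = 2L, width_threshold = 0.5) {
  lab <- stim$regions
  nr <- nrow(lab); nc <- ncol(lab)
  vert <- which(lab[-nr, , drop = FALSE] != lab[-1, , drop = FALSE],
                arr.ind = TRUE)
  horz <- which(lab[, -nc, drop = FALSE] != lab[, -1, drop = FALSE],
                arr.ind = TRUE)
  p1 <- rbind(vert, horz)
  p2 <- rbind(cbind(vert[, 1] + 1L, vert[, 2]),
              cbind(horz[, 1], horz[, 2] + 1L))
  if (nrow(p1) == 0L) {
    return(structure(list(edges = empty_edge_df(), boundaries = list(),
                          pitch = stim$pitch), class = "edge_set"))
  }
  l1 <- lab[p1]; l2 <- lab[p2]
  swap <- l1 > l2
  tmp <- p1[swap, , drop = FALSE]; p1[swap, ] <- p2[swap, ]; p2[swap, ] <- tmp
  la <- pmin(l1, l2); lb <- pmax(l1, l2)
  pair_key <- paste(la, lb)
  ids <- integer(0)
  rows <- list(); bounds <- list()
  next_id <- 1L
  for (key in unique(pair_key)) {
    sel <- which(pair_key == key)
    apx <- p1[sel, , drop = FALSE]; bpx <- p2[sel, , drop = FALSE]
    uni <- unique(apx)
    comp_of_unique <- label_components(uni)
    ukey <- paste(uni[, 1], uni[, 2])
    comp <- comp_of_unique[match(paste(apx[, 1], apx[, 2]), ukey)]
    for (cc in sort(unique(comp))) {
      cs <- comp == cc
      a <- apx[cs, , drop = FALSE]; b <- bpx[cs, , drop = FALSE]
      lum_a <- band_mean(stim$image, lab, unique(a), la[sel][1], band_px)
      lum_b <- band_mean(stim$image, lab, unique(b), lb[sel][1], band_px)
      if (lum_a <= 0 || lum_b <= 0)
        stop("sampled boundary luminance is not positive")
      bnd <- list(a = a, b = b)
      rows[[next_id]] <- data.frame(
        id = next_id, region_a = la[sel][1], region_b = lb[sel][1],
        lum_a = lum_a, lum_b = lum_b, log_step = log(lum_b / lum_a),
        sharpness = classify_edge_sharpness(stim, bnd, width_threshold),
        gain = 1, n_pix = nrow(a), length_deg = nrow(a) * stim$pitch,
        stringsAsFactors = FALSE)
      bounds[[next_id]] <- bnd
      next_id <- next_id + 1L
    }
  }
  structure(list(edges = do.call(rbind, rows), boundaries = bounds,
                 pitch = stim$pitch), class = "edge_set")
}

empty_edge_df <- function() {
  data.frame(id = integer(0), region_a = integer(0), region_b = integer(0),
             lum_a = numeric(0), lum_b = numeric(0), log_step = numeric(0),
             sharpness = character(0), gain = numeric(0), n_pix = integer(0),
             length_deg = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.edge_set <- function(x, ...) {
  cat("<edge_set> ", nrow(x$edges), " edge(s)\n", sep = "")
  print(x$edges, ...)
  invisible(x)
}

#' Classify a boundary as sharp or gradual
#'
#' Measures the distance over which 10% to 90% of the luminance change is
#' traversed along the boundary normal (median over sampled boundary pixels).
#' Transitions at most `width_threshold` wide are candidate reflectance
#' edges (`"sharp"`); wider transitions are candidate illumination gradients
#' (`"gradient"`), which the selection stage down-weights.
#'
#' @param stim A [luminance_stimulus()].
#' @param edge A boundary descriptor: either an element of an
#'   [extract_edges()] `boundaries` list, or an `edge_set` together with
#'   `id`.
#' @param width_threshold Transition-width threshold, deg. The default 0.5
#'   deg reflects the scale of the lowest spatial-frequency channels
#'   (about 0.5 cycle/deg).
#' @param id Edge id when `edge` is an `edge_set`.
#' @return `"sharp"` or `"gradient"`.
#' @export
classify_edge_sharpness <- function(stim, edge, width_threshold = 0.5,
                                    id = NULL) {
  if (inherits(edge, "edge_set")) {
    if (is.null(id)) stop("supply the edge `id` when passing an edge_set")
    edge <- edge$boundaries[[id]]
  }
  a <- edge$a; b <- edge$b
  n <- nrow(a)
  take <- unique(round(seq(1, n, length.out = min(n, 25L))))
  K <- as.integer(ceiling(width_threshold / stim$pitch)) + 2L
  widths <- vapply(take, function(i) {
    dr <- b[i, 1] - a[i, 1]; dc <- b[i, 2] - a[i, 2]
    ts <- seq.int(-K + 1L, K)
    rr <- a[i, 1] + ts * dr; cc <- a[i, 2] + ts * dc
    ok <- rr >= 1 & rr <= nrow(stim$image) & cc >= 1 & cc <= ncol(stim$image)
    if (sum(ok) < 2L) return(NA_real_)
    v <- stim$image[cbind(rr[ok], cc[ok])]
    tt <- ts[ok]
    total <- v[length(v)] - v[1]
    if (total == 0) return(0)
    f <- (v - v[1]) / total
    (cross_time(tt, f, 0.9) - cross_time(tt, f, 0.1)) * stim$pitch
  }, numeric(1))
  widths <- widths[!is.na(widths)]
  if (!length(widths))
    stop("degenerate boundary: fewer than 2 px of normal extent")
  if (stats::median(widths) <= width_threshold) "sharp" else "gradient"
}

# first upward crossing of `level` in the fractional profile, linearly
# interpolated
cross_time <- function(t, f, level) {
  idx <- which(f >= level)[1]
  if (is.na(idx)) return(t[length(t)])
  if (idx == 1L) return(t[1])
  t[idx - 1] + (level - f[idx - 1]) / (f[idx] - f[idx - 1]) *
    (t[idx] - t[idx - 1])
}

#' Weber fraction at an edge
#'
#' The luminance ratio at an edge is the Weber fraction plus one, so
#' `weber_fraction(e) == exp(log_step) - 1`.
#'
#' @param edges An `edge_set` from [extract_edges()].
#' @param ids Optional edge ids (default: all edges).
#' @return Numeric vector `lum_b / lum_a - 1`.
#' @export
weber_fraction <- function(edges, ids = NULL) {
  df <- edges$edges
  if (!is.null(ids)) df <- df[match(ids, df$id), , drop = FALSE]
  df$lum_b / df$lum_a - 1
}

#' Serialise an edge set to CSV
#'
#' One row per edge: regions, mean luminances (cd/m^2), natural-log step,
#' sharpness, gain, and boundary length in deg.
#'
#' @param edges An `edge_set`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_edge_csv <- function(edges, path) {
  df <- edges$edges[, c("id", "region_a", "region_b", "lum_a", "lum_b",
                        "log_step", "sharpness", "gain", "length_deg")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
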