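# V4 stage: spatial integration of gain-, polarity- and distance-weighted
# steps in log luminance, either along selected paths (scalar lightness for
# a target region) or over the whole pixel grid (separate lightness L(x)
# and darkness D(x) channel maps).

#' Model configuration
#'
#' Collects the tunable constants of the edge-integration model.
#'
#' @param w_inc Weight for steps whose light side points toward the target
#'   (default 1/3, the post-logarithm trace of a cube-root ON-channel
#'   compression).
#' @param w_dec Weight for steps whose dark side points toward the target
#'   (default 1: linear OFF channel).
#' @param kernel Distance-weight family: `"exponential"` `exp(-d / tau)`,
#'   `"linear"` `max(0, 1 - d / range_cutoff)`, `"log_linear"`
#'   `max(0, 1 - log_b * log10(1 + d / log_d0))`, or `"uniform"` (identically
#'   1). All except `"uniform"` are clipped to 0 beyond `range_cutoff`.
#' @param tau Space constant of the exponential kernel, deg. The default
#'   `10 / log(20)` (about 3.34 deg) calibrates the kernel so that contextual
#'   influence falls to 5% of its peak at 10 deg, a concrete reading of the
#'   psychophysical finding that induction declines with distance up to
#'   about 10 deg.
#' @param range_cutoff Hard spatial cutoff, deg (default 10).
#' @param log_b,log_d0 Slope and scale of the log-linear kernel. The
#'   defaults put that kernel, too, at 5% of peak at 10 deg.
#' @param ideal_observer If `TRUE`, forces `w_inc = w_dec = 1` and a uniform
#'   kernel: the unweighted retinex limit in which path sums telescope to
#'   `log(L_target / L_background)`.
#' @param g_illum Residual gain of edges interpreted as illumination edges
#'   (default 0: the ideal observer excludes them entirely).
#' @param g_gradient Residual gain of gradient-classified (blurry) edges
#'   (default 0: full exclusion of candidate illumination gradients).
#' @param anchor_rule Default anchoring rule for reflectance estimates.
#' @param R_white Reflectance assigned to the anchor region (conventional
#'   white paper, 0.9).
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(w_inc = 1 / 3, w_dec = 1,
                         kernel = c("exponential", "linear", "log_linear",
                                    "uniform"),
                         tau = 10 / log(20), range_cutoff = 10,
                         log_b = 0.95 / log10(11), log_d0 = 1,
                         ideal_observer = FALSE, g_illum = 0, g_gradient = 0,
                         anchor_rule = c("highest_reflectance",
                                         "highest_luminance"),
                         R_white = 0.9) {
  kernel <- match.arg(kernel)
  anchor_rule <- match.arg(anchor_rule)
  if (ideal_observer) {
    w_inc <- 1; w_dec <- 1; kernel <- "uniform"
  }
  if (w_inc <= 0 || w_dec <= 0) stop("polarity weights must be positive")
  if (tau <= 0 || range_cutoff <= 0) stop("kernel scales must be positive")
  if (g_illum < 0 || g_illum > 1 || g_gradient < 0 || g_gradient > 1)
    stop("residual gains must lie in [0, 1]")
  if (R_white <= 0 || R_white > 1) stop("R_white must lie in (0, 1]")
  structure(list(w_inc = w_inc, w_dec = w_dec, kernel = kernel, tau = tau,
                 range_cutoff = range_cutoff, log_b = log_b, log_d0 = log_d0,
                 ideal_observer = ideal_observer, g_illum = g_illum,
                 g_gradient = g_gradient, anchor_rule = anchor_rule,
                 R_white = R_white),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> w_inc =", signif(x$w_inc, 4),
      " w_dec =", signif(x$w_dec, 4), "\n")
  cat("  kernel:", x$kernel,
      if (x$kernel == "exponential") paste0("(tau = ", signif(x$tau, 4),
                                            " deg)"),
      " cutoff:", x$range_cutoff, "deg\n")
  if (x$ideal_observer) cat("  ideal-observer preset (retinex limit)\n")
  invisible(x)
}

#' Distance weight of a contextual edge
#'
#' @param d Distance(s) from the edge, deg (must be non-negative).
#' @param config A [model_config()].
#' @return Weights in \[0, 1\]; `distance_weight(0, config)` is 1 for every
#'   kernel, and every kernel except `"uniform"` is 0 beyond
#'   `range_cutoff`.
#' @export
distance_weight <- function(d, config = model_config()) {
  if (any(d < 0)) stop("distances must be non-negative")
  w <- switch(config$kernel,
              uniform = rep(1, length(d)),
              exponential = exp(-d / config$tau),
              linear = pmax(0, 1 - d / config$range_cutoff),
              log_linear = pmax(0, 1 - config$log_b *
                                  log10(1 + d / config$log_d0)))
  if (config$kernel != "uniform") w[d > config$range_cutoff] <- 0
  dim(w) <- dim(d)
  w
}

# Distance (deg) from an edge to a target region for path sums. An edge
# incident to the target abuts it, so its distance is 0; otherwise the
# distance is from the target point (by default the region centroid) to the
# nearest boundary crack midpoint.
edge_target_distance <- function(edges, edge_id, target, target_point) {
  k <- match(edge_id, edges$edges$id)
  if (target %in% c(edges$edges$region_a[k], edges$edges$region_b[k]))
    return(0)
  mid <- boundary_midpoints(edges$boundaries[[k]], edges$pitch)
  sqrt(min((mid[, 1] - target_point[1])^2 + (mid[, 2] - target_point[2])^2))
}

#' Integrated lightness along selected paths
#'
#' For each path the directed log-luminance step crossed toward the target
#' at every edge is multiplied by that edge's top-down gain, its polarity
#' weight (`w_inc` for a step up in luminance toward the target, `w_dec` for
#' a step down), and its distance weight, and the products are summed. A
#' wide-mode selection yields the single path's sum; narrow-mode
#' pseudo-paths are combined by an unweighted mean, so narrow and wide
#' outputs stay on comparable scales.
#'
#' @param paths A path list from [select_paths()].
#' @param edges The `edge_set` the paths refer to (after any gain control).
#' @param config A [model_config()].
#' @param target_point `c(row, col)` point in deg that distances are
#'   measured to (usually the target centroid; see
#'   [region_centroid()]).
#' @return Scalar integrated lightness (Lambda), with per-path sums in the
#'   `"per_path"` attribute.
#' @export
path_lightness <- function(paths, edges, config = model_config(),
                           target_point) {
  if (length(paths) == 0L) stop("no paths supplied")
  df <- edges$edges
  per <- vapply(paths, function(p) {
    target <- p$regions[length(p$regions)]
    total <- 0
    for (j in seq_along(p$edge_ids)) {
      k <- match(p$edge_ids[j], df$id)
      if (is.na(k)) stop("path references an edge missing from the edge set")
      toward <- p$regions[j + 1]
      delta <- if (df$region_b[k] == toward) df$log_step[k] else -df$log_step[k]
      if (delta == 0 || df$gain[k] == 0) next
      w <- if (delta > 0) config$w_inc else config$w_dec
      d <- edge_target_distance(edges, p$edge_ids[j], target, target_point)
      total <- total + df$gain[k] * w * distance_weight(d, config) * delta
    }
    total
  }, numeric(1))
  mode <- attr(paths, "mode")
  lambda <- if (identical(mode, "narrow")) mean(per) else per[[1]]
  attr(lambda, "per_path") <- per
  lambda
}

#' Lightness and darkness channel maps
#'
#' Computes, for every pixel, the summed activation of model V4 lightness
#' neurons (`L`) and darkness neurons (`D`). An edge contributes to `L` at
#' pixels its light side faces and to `D` at pixels its dark side faces,
#' scaled by its gain, the polarity weight, the distance weight at the
#' pixel's distance from the nearest boundary pixel of the edge, and the
#' absolute log step. "Faces" is defined by region reachability: a pixel is
#' faced by a side if its region can be reached from that side's region
#' without recrossing the edge, so induction from an outer border reaches
#' enclosed interiors (filling-in as a byproduct of edge integration).
#'
#' @param edges An `edge_set` (after any gain control).
#' @param stim The [luminance_stimulus()] the edges were extracted from.
#' @param config A [model_config()].
#' @return An object of class `"channel_maps"` with non-negative matrices
#'   `L` and `D` and the pixel `pitch`.
#' @export
compute_channel_maps <- function(edges, stim, config = model_config()) {
  nr <- nrow(stim$regions); nc <- ncol(stim$regions)
  L <- D <- matrix(0, nr, nc)
  df <- edges$edges
  if (nrow(df) == 0L)
    return(structure(list(L = L, D = D, pitch = stim$pitch),
                     class = "channel_maps"))
  g <- build_region_graph(stim, edges)
  for (k in seq_len(nrow(df))) {
    if (df$gain[k] <= 0 || df$log_step[k] == 0) next
    bnd <- edges$boundaries[[df$id[k]]]
    seed <- matrix(1, nr, nc)
    seed[bnd$a] <- 0
    seed[bnd$b] <- 0
    dmap <- as.matrix(EBImage::distmap(seed)) * stim$pitch
    wmap <- distance_weight(dmap, config) * df$gain[k] * abs(df$log_step[k])
    arc <- which(igraph::edge_attr(g, "edge_id") == df$id[k])
    g2 <- igraph::delete_edges(g, arc)
    comp <- igraph::components(g2)$membership
    light_is_a <- df$lum_a[k] > df$lum_b[k]
    for (side in c("light", "dark")) {
      lab <- if (xor(side == "light", light_is_a)) df$region_b[k]
             else df$region_a[k]
      facing <- as.integer(names(comp)[comp == comp[[as.character(lab)]]])
      fm <- matrix(stim$regions %in% facing, nr, nc)
      if (side == "light") L[fm] <- L[fm] + config$w_inc * wmap[fm]
      else                 D[fm] <- D[fm] + config$w_dec * wmap[fm]
    }
  }
  structure(list(L = L, D = D, pitch = stim$pitch), class = "channel_maps")
}

#' @export
print.channel_maps <- function(x, ...) {
  cat("<channel_maps> ", nrow(x$L), "x", ncol(x$L), " px\n", sep = "")
  cat("  L range [", signif(min(x$L), 4), ", ", signif(max(x$L), 4),
      "]; D range [", signif(min(x$D), 4), ", ", signif(max(x$D), 4),
      "]\n", sep = "")
  invisible(x)
}
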