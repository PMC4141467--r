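# V2 + top-down stage: region adjacency graph, border-ownership path
# selection, and attentional/interpretation gain control.
#
# Border ownership is not simulated mechanistically; it is realised as the
# path-selection rule such circuits are taken to implement: integration runs
# only along direct (shortest) paths from the common background to the
# target. A narrow attentional spotlight instead compares the target to each
# immediately adjacent region across each of its borders.

#' Build the region adjacency graph
#'
#' One node per region label, one arc per extracted edge (parallel arcs are
#' kept when a region pair shares several disjoint boundary components).
#'
#' @param stim A [luminance_stimulus()] (supplies the label set and the
#'   background label).
#' @param edges An `edge_set` extracted from the same region map.
#' @return An undirected [igraph::igraph] with vertex names equal to region
#'   labels, edge attributes `edge_id` and `n_pix`, and graph attribute
#'   `background`.
#' @export
build_region_graph <- function(stim, edges) {
  labs <- sort(unique(as.vector(stim$regions)))
  df <- edges$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(df$region_a),
               to = as.character(df$region_b),
               edge_id = df$id, n_pix = df$n_pix),
    directed = FALSE,
    vertices = data.frame(name = as.character(labs)))
  if (!igraph::is_connected(g))
    stop("region map is disconnected: no integration path exists between ",
         "some regions")
  g <- igraph::set_graph_attr(g, "background", stim$background)
  g
}

#' Attentional spotlight / edge-interpretation specification
#'
#' @param mode `"wide"` (compare each target to the common background along
#'   direct paths), `"narrow"` (compare the target to each immediately
#'   adjacent region), or `"custom"` (additionally weight edges by a spatial
#'   mask).
#' @param mask For `"custom"`: a numeric matrix in \[0, 1\], same shape as
#'   the stimulus; each edge's gain is multiplied by the mean mask value over
#'   its boundary pixels.
#' @param interpretation Global interpretation of luminance steps:
#'   `"reflectance"` (gain 1) or `"illumination"` (gain `g_illum` from the
#'   model config, default 0).
#' @param edge_interpretation Optional named list overriding the
#'   interpretation for specific edges, e.g. `list("3" = "illumination")`
#'   keyed by edge id.
#' @return An object of class `"spotlight"`.
#' @export
spotlight <- function(mode = c("wide", "narrow", "custom"), mask = NULL,
                      interpretation = c("reflectance", "illumination"),
                      edge_interpretation = list()) {
  mode <- match.arg(mode)
  interpretation <- match.arg(interpretation)
  if (mode == "custom") {
    if (is.null(mask)) stop("custom mode requires a spatial mask")
    if (any(mask < 0 | mask > 1)) stop("mask values must lie in [0, 1]")
  }
  structure(list(mode = mode, mask = mask, interpretation = interpretation,
                 edge_interpretation = edge_interpretation),
            class = "spotlight")
}

#' Select integration paths for a target region
#'
#' Wide mode returns the direct path from the background to the target:
#' the shortest path in the region graph, with ties broken by maximising the
#' total boundary length of the crossed edges (and, among parallel arcs, the
#' longest shared boundary). Borders between sibling regions equidistant
#' from the background are never crossed. Narrow mode returns one
#' single-step pseudo-path per boundary component of the target region, each
#' treating the adjacent region as the local background.
#'
#' @param graph A region graph from [build_region_graph()].
#' @param target Target region label (must differ from the background).
#' @param spot A [spotlight()]; only its `mode` matters here.
#' @return A list of integration paths (class `"integration_path"`, each
#'   with `regions`, an ordered label vector ending at the target, and
#'   `edge_ids`, the edge crossed at each step), with attribute `mode`.
#' @export
select_paths <- function(graph, target, spot = spotlight("wide")) {
  bg <- igraph::graph_attr(graph, "background")
  if (target == bg) stop("target must differ from the background region")
  if (!as.character(target) %in% igraph::V(graph)$name)
    stop("unknown target region ", target)
  if (spot$mode == "narrow") {
    arcs <- igraph::incident(graph, as.character(target))
    paths <- lapply(seq_along(arcs), function(i) {
      ends <- igraph::ends(graph, arcs[i])
      other <- setdiff(as.integer(ends), as.integer(target))
      if (length(other) == 0L) other <- as.integer(target)  # self-loop guard
      structure(list(regions = c(other, as.integer(target)),
                     edge_ids = igraph::edge_attr(graph, "edge_id", arcs[i])),
                class = "integration_path")
    })
    attr(paths, "mode") <- "narrow"
    return(paths)
  }
  sp <- igraph::all_shortest_paths(graph, from = as.character(bg),
                                   to = as.character(target))$res
  if (length(sp) == 0L) stop("no path from background to target")
  cand <- lapply(sp, function(vp) {
    regs <- as.integer(igraph::as_ids(vp))
    eids <- integer(length(regs) - 1L)
    score <- 0
    for (j in seq_len(length(regs) - 1L)) {
      arcs <- igraph::E(graph)[igraph::V(graph)[as.character(regs[j])] %--%
                                 igraph::V(graph)[as.character(regs[j + 1])]]
      npx <- igraph::edge_attr(graph, "n_pix", arcs)
      ids <- igraph::edge_attr(graph, "edge_id", arcs)
      best <- order(-npx, ids)[1]
      eids[j] <- ids[best]
      score <- score + npx[best]
    }
    list(regions = regs, edge_ids = eids, score = score)
  })
  scores <- vapply(cand, `[[`, numeric(1), "score")
  keys <- vapply(cand, function(p) paste(p$regions, collapse = ","),
                 character(1))
  best <- order(-scores, keys)[1]
  paths <- list(structure(cand[[best]][c("regions", "edge_ids")],
                          class = "integration_path"))
  attr(paths, "mode") <- "wide"
  paths
}

#' Apply top-down gains to an edge set
#'
#' Each edge's gain is recomputed from scratch as the product of the spatial
#' mask value at the edge (1 outside custom mode), the interpretation gain
#' (1 for a reflectance edge, `config$g_illum` for an illumination edge),
#' and the sharpness gain (1 for sharp edges, `config$g_gradient` for
#' gradient-classified edges), clamped to \[0, 1\]. The operation is
#' idempotent for a fixed spotlight and config.
#'
#' @param edges An `edge_set`.
#' @param spot A [spotlight()].
#' @param config A [model_config()] supplying `g_illum` and `g_gradient`.
#' @return The edge set with updated gains.
#' @export
apply_gain_field <- function(edges, spot = spotlight("wide"),
                             config = model_config()) {
  df <- edges$edges
  for (k in seq_len(nrow(df))) {
    m <- 1
    if (spot$mode == "custom") {
      bnd <- edges$boundaries[[df$id[k]]]
      pts <- rbind(bnd$a, bnd$b)
      m <- mean(spot$mask[pts])
    }
    interp <- spot$interpretation
    ov <- spot$edge_interpretation[[as.character(df$id[k])]]
    if (!is.null(ov)) interp <- ov
    gi <- if (identical(interp, "illumination")) config$g_illum else 1
    gs <- if (df$sharpness[k] == "gradient") config$g_gradient else 1
    df$gain[k] <- clamp01(m * gi * gs)
  }
  edges$edges <- df
  edges
}

#' Silence one edge
#'
#' Returns a copy of the edge set with the given edge's gain set to zero,
#' simulating flicker-masking adaptation of the edge-detector units that
#' encode it (the edge remains inspectable; it simply stops contributing).
#'
#' @param edges An `edge_set`.
#' @param edge_id Id of the edge to silence.
#' @return The modified edge set.
#' @export
mask_edge <- function(edges, edge_id) {
  k <- match(edge_id, edges$edges$id)
  if (is.na(k)) stop("unknown edge id ", edge_id)
  edges$edges$gain[k] <- 0
  edges
}

#' Find edges between two regions
#'
#' @param edges An `edge_set`.
#' @param region_a,region_b Region labels (order irrelevant).
#' @return Integer vector of edge ids (one per boundary component).
#' @export
find_edges <- function(edges, region_a, region_b) {
  df <- edges$edges
  lo <- min(region_a, region_b); hi <- max(region_a, region_b)
  df$id[df$region_a == lo & df$region_b == hi]
}

#' Serialise selected paths to CSV
#'
#' @param paths A path list from [select_paths()].
#' @param edges The `edge_set` the paths refer to.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_path_csv <- function(paths, edges, path) {
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (j in seq_along(p$edge_ids)) {
      k <- match(p$edge_ids[j], edges$edges$id)
      rows[[length(rows) + 1L]] <- data.frame(
        path = i, step = j, edge_id = p$edge_ids[j],
        from_region = p$regions[j], to_region = p$regions[j + 1],
        gain = edges$edges$gain[k])
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
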