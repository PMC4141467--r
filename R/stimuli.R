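# Synthetic achromatic stimuli: every display class used by the model is
# generated in-package as a luminance image (cd/m^2) plus an integer region
# label map, with the reflectance x illumination decomposition recorded where
# the stimulus is specified photometrically (L = R x I).

#' Construct a luminance stimulus
#'
#' Bundles a strictly positive luminance image with its angular calibration,
#' a region label map, and (optionally) the ground-truth decomposition of
#' luminance into reflectance and illumination, `L = R * I`.
#'
#' @param image Numeric matrix of luminances in cd/m^2; all values must be
#'   strictly positive so that log luminance is defined everywhere.
#' @param pitch Angular size of one pixel, deg/px.
#' @param regions Integer matrix of region labels, same shape as `image`.
#'   Region boundaries are pixel-aligned: each pixel belongs to exactly one
#'   region and a boundary is a 4-neighbour label change.
#' @param background Label of the designated common background region.
#' @param reflectance Optional matrix of reflectances in (0, 1].
#' @param illumination Optional matrix of illumination values (cd/m^2 scale).
#'   When both are given, `image` must equal `reflectance * illumination`
#'   to within 1e-9 relative error.
#' @param region_names Optional named integer vector mapping readable names
#'   (e.g. `"disk"`) to labels.
#' @param spec Optional list recording the generating parameters.
#' @return An object of class `"luminance_stimulus"`.
#' @export
luminance_stimulus <- function(image, pitch, regions, background,
                               reflectance = NULL, illumination = NULL,
                               region_names = NULL, spec = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  if (any(image <= 0)) stop("all luminances must be strictly positive")
  if (!identical(dim(image), dim(regions)))
    stop("`regions` must have the same shape as `image`")
  if (pitch <= 0) stop("`pitch` must be positive")
  storage.mode(regions) <- "integer"
  if (!background %in% regions)
    stop("background label ", background, " does not occur in the region map")
  if (!is.null(reflectance) && !is.null(illumination)) {
    if (any(reflectance <= 0) || any(reflectance > 1))
      stop("reflectances must lie in (0, 1]")
    rel <- abs(image - reflectance * illumination) / image
    if (max(rel) > 1e-9)
      stop("image does not equal reflectance * illumination")
  }
  structure(list(image = image, pitch = pitch, regions = regions,
                 background = as.integer(background),
                 reflectance = reflectance, illumination = illumination,
                 region_names = region_names, spec = spec),
            class = "luminance_stimulus")
}

#' @export
print.luminance_stimulus <- function(x, ...) {
  cat("<luminance_stimulus> ", nrow(x$image), "x", ncol(x$image),
      " px at ", x$pitch, " deg/px (",
      round(nrow(x$image) * x$pitch, 2), " deg field)\n", sep = "")
  cat("  regions:", paste(sort(unique(as.vector(x$regions))), collapse = " "),
      " background:", x$background, "\n")
  cat("  luminance range: [", signif(min(x$image), 4), ", ",
      signif(max(x$image), 4), "] cd/m^2\n", sep = "")
  if (!is.null(x$region_names))
    cat("  names:", paste(names(x$region_names), x$region_names,
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Look up a region label by name
#'
#' @param stim A [luminance_stimulus()].
#' @param name Region name as recorded by the generator (e.g. `"disk"`,
#'   `"annulus"`, `"paper3"`, `"frame"`).
#' @return Integer label.
#' @export
region_label <- function(stim, name) {
  if (is.null(stim$region_names) || !name %in% names(stim$region_names))
    stop("stimulus has no region named '", name, "'")
  unname(stim$region_names[[name]])
}

canvas_dims <- function(size_deg, pitch) {
  n <- round(size_deg / pitch)
  if (n < 8) stop("canvas too small")
  n
}

pixel_coords <- function(n) {
  # row/col coordinate matrices of pixel centres, in pixel units
  list(row = matrix(seq_len(n), n, n), col = matrix(seq_len(n), n, n, byrow = TRUE))
}

#' Disk-annulus display
#'
#' A disk surrounded by a concentric annulus on a uniform background; the
#' canonical stimulus for measuring edge integration across the inner
#' (disk/annulus) and outer (annulus/background) borders.
#'
#' @param disk_lum,annulus_lum,bg_lum Luminances in cd/m^2 (all > 0).
#' @param disk_radius,annulus_outer_radius Radii in deg;
#'   `0 < disk_radius < annulus_outer_radius`.
#' @param pitch Pixel size in deg/px.
#' @param size_deg Canvas side length in deg.
#' @param center Optional `c(row, col)` centre in deg (defaults to canvas
#'   centre).
#' @return A [luminance_stimulus()] with regions `background`, `annulus`,
#'   `disk` labelled 1, 2, 3.
#' @export
make_disk_annulus <- function(disk_lum, annulus_lum, bg_lum,
                              disk_radius = 1, annulus_outer_radius = 3,
                              pitch = 0.1, size_deg = 25.6, center = NULL) {
  if (any(c(disk_lum, annulus_lum, bg_lum) <= 0))
    stop("all luminances must be positive")
  if (!(disk_radius > 0 && disk_radius < annulus_outer_radius))
    stop("radii must satisfy 0 < disk_radius < annulus_outer_radius")
  n <- canvas_dims(size_deg, pitch)
  if (is.null(center)) center <- rep((n + 1) / 2 * pitch, 2)
  if (annulus_outer_radius > min(center, size_deg - center))
    stop("annulus does not fit inside the image")
  co <- pixel_coords(n)
  r <- sqrt((co$row * pitch - center[1])^2 + (co$col * pitch - center[2])^2)
  regions <- matrix(1L, n, n)
  regions[r <= annulus_outer_radius] <- 2L
  regions[r <= disk_radius] <- 3L
  image <- matrix(bg_lum, n, n)
  image[regions == 2L] <- annulus_lum
  image[regions == 3L] <- disk_lum
  luminance_stimulus(image, pitch, regions, background = 1L,
                     region_names = c(background = 1L, annulus = 2L, disk = 3L),
                     spec = list(kind = "disk_annulus", disk_lum = disk_lum,
                                 annulus_lum = annulus_lum, bg_lum = bg_lum,
                                 disk_radius = disk_radius,
                                 annulus_outer_radius = annulus_outer_radius,
                                 pitch = pitch, size_deg = size_deg,
                                 center = center))
}

#' Staircase-Gelb paper series
#'
#' A row of achromatic papers of graded reflectance under a common spotlight,
#' on a dim background, optionally insulated from the background by a white
#' frame. Each paper's luminance is `reflectance * spotlight_illum`; the
#' ground-truth `L = R * I` decomposition is recorded.
#'
#' @param reflectances Numeric vector (length >= 2) of paper reflectances in
#'   (0, 1]. Any order is allowed (scrambling support).
#' @param spotlight_illum Spotlight illumination, cd/m^2 scale.
#' @param bg_lum Background luminance in cd/m^2.
#' @param paper_size Side length of each (square) paper, deg.
#' @param gap Horizontal gap between papers, deg (default 0: abutting).
#' @param frame Optional list `list(reflectance=, thickness=)` describing a
#'   white insulating frame. The frame forms a constant-thickness ring around
#'   the whole row and fills any gaps, so papers touch the frame, never the
#'   background. Its reflectance must be at least the maximum paper
#'   reflectance so every frame-to-paper step is decremental.
#' @param pitch Pixel size, deg/px.
#' @param size_deg Canvas side length, deg.
#' @return A [luminance_stimulus()]; papers are named `paper1`, `paper2`, ...
#'   in the order given, the frame (if present) `frame`.
#' @export
make_staircase_gelb <- function(reflectances, spotlight_illum = 1000,
                                bg_lum = 1, paper_size = 3, gap = 0,
                                frame = NULL, pitch = 0.1, size_deg = 25.6) {
  np <- length(reflectances)
  if (np < 2) stop("need at least 2 papers")
  if (any(reflectances <= 0) || any(reflectances > 1))
    stop("reflectances must lie in (0, 1]")
  if (bg_lum <= 0 || spotlight_illum <= 0) stop("luminances must be positive")
  n <- canvas_dims(size_deg, pitch)
  w <- round(paper_size / pitch)
  gpx <- round(gap / pitch)
  if (gap > 0 && gpx < 1) stop("gap thinner than one pixel")
  tpx <- 0L
  if (!is.null(frame)) {
    if (frame$reflectance < max(reflectances))
      stop("frame reflectance must be >= every paper reflectance (insulation)")
    tpx <- round(frame$thickness / pitch)
    if (tpx < 1) stop("frame thinner than one pixel")
  }
  row_w <- np * w + (np - 1) * gpx
  if (row_w + 2 * tpx > n || w + 2 * tpx > n)
    stop("papers (plus frame) do not fit on the canvas")
  top <- floor((n - w) / 2) + 1L
  left0 <- floor((n - row_w) / 2) + 1L
  regions <- matrix(1L, n, n)
  refl <- matrix(bg_lum / spotlight_illum, n, n)
  if (bg_lum / spotlight_illum > 1)
    stop("background luminance exceeds the spotlight illumination")
  names_vec <- c(background = 1L)
  next_lab <- 2L
  if (!is.null(frame)) {
    regions[(top - tpx):(top + w - 1L + tpx),
            (left0 - tpx):(left0 + row_w - 1L + tpx)] <- next_lab
    refl[regions == next_lab] <- frame$reflectance
    names_vec <- c(names_vec, frame = next_lab)
    next_lab <- next_lab + 1L
  }
  for (i in seq_len(np)) {
    left <- left0 + (i - 1L) * (w + gpx)
    regions[top:(top + w - 1L), left:(left + w - 1L)] <- next_lab
    refl[regions == next_lab] <- reflectances[i]
    names_vec <- c(names_vec, stats::setNames(next_lab, paste0("paper", i)))
    next_lab <- next_lab + 1L
  }
  illum <- matrix(spotlight_illum, n, n)
  image <- refl * illum
  luminance_stimulus(image, pitch, regions, background = 1L,
                     reflectance = refl, illumination = illum,
                     region_names = names_vec,
                     spec = list(kind = "staircase_gelb",
                                 reflectances = reflectances,
                                 spotlight_illum = spotlight_illum,
                                 bg_lum = bg_lum, paper_size = paper_size,
                                 gap = gap, frame = frame, pitch = pitch,
                                 size_deg = size_deg))
}

#' Craik-O'Brien-Cornsweet edge
#'
#' A horizontal luminance profile with equal plateaus far from the centre and
#' two opposed exponential cusps meeting at a central step of height
#' `2 * cusp_amplitude`. The cusp decays with space constant `cusp_width / 3`.
#'
#' @param plateau_lum Plateau luminance, cd/m^2.
#' @param cusp_amplitude Cusp height, cd/m^2; must be < `plateau_lum`.
#' @param cusp_width Nominal cusp width, deg.
#' @param image_width Canvas side length, deg.
#' @param pitch Pixel size, deg/px.
#' @return A [luminance_stimulus()] with regions `left` (background) and
#'   `right` split at the central step.
#' @export
make_coc_edge <- function(plateau_lum, cusp_amplitude, cusp_width = 2,
                          image_width = 12.8, pitch = 0.1) {
  if (cusp_amplitude < 0) stop("cusp amplitude must be non-negative")
  if (plateau_lum - cusp_amplitude <= 0)
    stop("cusp amplitude must be smaller than the plateau luminance")
  n <- canvas_dims(image_width, pitch)
  half <- floor(n / 2)
  lambda <- cusp_width / 3
  col_deg <- (seq_len(n) - 0.5) * pitch
  edge_deg <- half * pitch  # crack between columns `half` and `half + 1`
  d <- abs(col_deg - edge_deg) - pitch / 2  # distance past the adjacent pixel
  prof <- ifelse(col_deg <= edge_deg,
                 plateau_lum - cusp_amplitude * exp(-pmax(0, d) / lambda),
                 plateau_lum + cusp_amplitude * exp(-pmax(0, d) / lambda))
  image <- matrix(prof, n, n, byrow = TRUE)
  regions <- matrix(rep(c(1L, 2L), c(half, n - half)), n, n, byrow = TRUE)
  luminance_stimulus(image, pitch, regions, background = 1L,
                     region_names = c(left = 1L, right = 2L),
                     spec = list(kind = "coc_edge", plateau_lum = plateau_lum,
                                 cusp_amplitude = cusp_amplitude,
                                 cusp_width = cusp_width,
                                 image_width = image_width, pitch = pitch))
}

#' Two disk-annulus patterns on a luminance-ramp background
#'
#' Places two identical disk-annulus patterns left and right of centre on a
#' background whose luminance ramps linearly with horizontal position. With
#' the annulus luminance lying between the two local background luminances,
#' the annulus/background log-luminance ratio has opposite sign on the two
#' sides while disk and annulus luminances are identical.
#'
#' @param disk_lum,annulus_lum Pattern luminances, cd/m^2.
#' @param bg_lum Background luminance at the canvas centre, cd/m^2.
#' @param ramp_slope Background slope in cd/m^2 per deg of horizontal
#'   position.
#' @param offset Horizontal distance of each pattern centre from the canvas
#'   centre, deg.
#' @param disk_radius,annulus_outer_radius Radii, deg.
#' @param pitch Pixel size, deg/px.
#' @param size_deg Canvas side, deg.
#' @return A [luminance_stimulus()] with regions `background`, `annulus_left`,
#'   `disk_left`, `annulus_right`, `disk_right`.
#' @export
make_gradient_background_pair <- function(disk_lum = 30, annulus_lum = 50,
                                          bg_lum = 50, ramp_slope = 2,
                                          offset = 6, disk_radius = 1,
                                          annulus_outer_radius = 2.5,
                                          pitch = 0.1, size_deg = 25.6) {
  if (any(c(disk_lum, annulus_lum, bg_lum) <= 0))
    stop("all luminances must be positive")
  if (!(disk_radius > 0 && disk_radius < annulus_outer_radius))
    stop("radii out of order")
  n <- canvas_dims(size_deg, pitch)
  co <- pixel_coords(n)
  xc <- (n + 1) / 2 * pitch
  image <- bg_lum + ramp_slope * (co$col * pitch - xc)
  if (any(image <= 0)) stop("ramp makes part of the background non-positive")
  regions <- matrix(1L, n, n)
  centers <- list(left = c(xc, xc - offset), right = c(xc, xc + offset))
  labs <- c(annulus_left = 2L, disk_left = 3L,
            annulus_right = 4L, disk_right = 5L)
  for (side in names(centers)) {
    ctr <- centers[[side]]
    if (annulus_outer_radius > min(ctr[2], size_deg - ctr[2], ctr[1],
                                   size_deg - ctr[1]))
      stop("pattern does not fit inside the image")
    r <- sqrt((co$row * pitch - ctr[1])^2 + (co$col * pitch - ctr[2])^2)
    a_lab <- labs[[paste0("annulus_", side)]]
    d_lab <- labs[[paste0("disk_", side)]]
    regions[r <= annulus_outer_radius] <- a_lab
    regions[r <= disk_radius] <- d_lab
    image[regions == a_lab] <- annulus_lum
    image[regions == d_lab] <- disk_lum
  }
  luminance_stimulus(image, pitch, regions, background = 1L,
                     region_names = c(background = 1L, labs),
                     spec = list(kind = "gradient_background_pair",
                                 disk_lum = disk_lum, annulus_lum = annulus_lum,
                                 bg_lum = bg_lum, ramp_slope = ramp_slope,
                                 offset = offset, disk_radius = disk_radius,
                                 annulus_outer_radius = annulus_outer_radius,
                                 pitch = pitch, size_deg = size_deg))
}

#' Simultaneous-contrast display
#'
#' Two identical gray test patches, one on a dark and one on a light half of
#' the canvas.
#'
#' @param patch_lum Test patch luminance, cd/m^2.
#' @param dark_lum,light_lum Surround luminances, cd/m^2.
#' @param patch_size Patch side length, deg.
#' @param pitch Pixel size, deg/px.
#' @param size_deg Canvas side, deg.
#' @return A [luminance_stimulus()]; the dark surround is the designated
#'   background.
#' @export
make_simultaneous_contrast <- function(patch_lum = 30, dark_lum = 5,
                                       light_lum = 90, patch_size = 3,
                                       pitch = 0.1, size_deg = 25.6) {
  if (any(c(patch_lum, dark_lum, light_lum) <= 0))
    stop("all luminances must be positive")
  n <- canvas_dims(size_deg, pitch)
  half <- floor(n / 2)
  w <- round(patch_size / pitch)
  if (w + 2 > half) stop("patch does not fit in one half of the canvas")
  regions <- matrix(rep(c(1L, 2L), c(half, n - half)), n, n, byrow = TRUE)
  image <- matrix(rep(c(dark_lum, light_lum), c(half, n - half)), n, n,
                  byrow = TRUE)
  top <- floor((n - w) / 2) + 1L
  lc <- floor((half - w) / 2) + 1L
  rc <- half + lc
  regions[top:(top + w - 1L), lc:(lc + w - 1L)] <- 3L
  regions[top:(top + w - 1L), rc:(rc + w - 1L)] <- 4L
  image[regions %in% c(3L, 4L)] <- patch_lum
  luminance_stimulus(image, pitch, regions, background = 1L,
                     region_names = c(dark_surround = 1L, light_surround = 2L,
                                      patch_on_dark = 3L, patch_on_light = 4L),
                     spec = list(kind = "simultaneous_contrast",
                                 patch_lum = patch_lum, dark_lum = dark_lum,
                                 light_lum = light_lum,
                                 patch_size = patch_size, pitch = pitch,
                                 size_deg = size_deg))
}
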