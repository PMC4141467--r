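# Shared fixtures, built in code. Tests use a 12.8 deg canvas (128 px at
# 0.1 deg/px) unless the default 25.6 deg field matters.

small_disk_annulus <- function(disk = 30, annulus = 90, bg = 10, ...) {
  make_disk_annulus(disk, annulus, bg, size_deg = 12.8, ...)
}

# Concentric squares (square "disk" in a square ring on a background).
# Along the central row the distance to the nearest boundary pixel is exact,
# which makes kernel-shape properties testable without circle pixelation.
square_annulus_stimulus <- function(disk_lum = 30, ring_lum = 90,
                                    bg_lum = 10, half_disk = 10L,
                                    half_ring = 30L, n = 128L, pitch = 0.1) {
  stopifnot(half_disk < half_ring, half_ring < n / 2)
  c0 <- n / 2L
  regions <- matrix(1L, n, n)
  regions[(c0 - half_ring):(c0 + half_ring),
          (c0 - half_ring):(c0 + half_ring)] <- 2L
  regions[(c0 - half_disk):(c0 + half_disk),
          (c0 - half_disk):(c0 + half_disk)] <- 3L
  image <- matrix(bg_lum, n, n)
  image[regions == 2L] <- ring_lum
  image[regions == 3L] <- disk_lum
  luminance_stimulus(image, pitch, regions, background = 1L,
                     region_names = c(background = 1L, annulus = 2L,
                                      disk = 3L))
}

# Two-region stimulus whose boundary is a horizontal luminance ramp of the
# given width (deg); used to exercise the sharpness classifier.
ramp_boundary_stimulus <- function(lo = 20, hi = 80, ramp_width = 5,
                                   n = 128L, pitch = 0.1) {
  half <- n / 2L
  x <- (seq_len(n) - 0.5) * pitch
  mid <- half * pitch
  f <- pmin(1, pmax(0, (x - (mid - ramp_width / 2)) / ramp_width))
  image <- matrix(lo + (hi - lo) * f, n, n, byrow = TRUE)
  regions <- matrix(rep(c(1L, 2L), each = half), n, n, byrow = TRUE)
  luminance_stimulus(image, pitch, regions, background = 1L)
}

default_cfg <- function(...) model_config(...)
ideal_cfg <- function() model_config(ideal_observer = TRUE)

disk_lambda <- function(stim, config = model_config(),
                        spot = spotlight("wide")) {
  region_lightness(stim, targets = region_label(stim, "disk"),
                   spot = spot, config = config)$lambda
}
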