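test_that("distance kernels are calibrated, monotone, and clipped", {
  cfg <- model_config()
  expect_equal(distance_weight(0, cfg), 1)
  # default calibration: 5% of peak at the 10-deg range limit
  expect_equal(distance_weight(10, cfg), 0.05, tolerance = 1e-12)
  expect_equal(kernel_range(cfg), 10, tolerance = 1e-6)
  for (k in c("exponential", "linear", "log_linear")) {
    ck <- model_config(kernel = k)
    d <- seq(0, 12, by = 0.05)
    w <- distance_weight(d, ck)
    expect_equal(w[1], 1)
    expect_true(all(diff(w) <= 1e-12))          # non-increasing
    expect_true(all(w[d > ck$range_cutoff] == 0))  # clipped past cutoff
    expect_lte(distance_weight(10, ck), 0.05 + 1e-9)
  }
  expect_equal(distance_weight(3, model_config(ideal_observer = TRUE)), 1)
  expect_error(distance_weight(-1, cfg), "non-negative")
})

test_that("model_config validates and the ideal preset overrides weights", {
  expect_error(model_config(w_inc = -1), "positive")
  expect_error(model_config(g_illum = 2), "\\[0, 1\\]")
  expect_error(model_config(R_white = 0), "R_white")
  io <- model_config(ideal_observer = TRUE)
  expect_equal(io$w_inc, 1)
  expect_equal(io$w_dec, 1)
  expect_equal(io$kernel, "uniform")
})

test_that("ideal-observer path sums telescope to log(L_target / L_bg)", {
  io <- ideal_cfg()
  # disk-annulus: two-step path collapses to the end ratio
  stim <- small_disk_annulus(10, 100, 1)
  expect_equal(disk_lambda(stim, io), log(10 / 1), tolerance = 1e-9)
  # randomized stimuli, fixed seed
  set.seed(42)
  for (i in 1:5) {
    lums <- exp(runif(3, log(1), log(500)))
    s <- small_disk_annulus(lums[1], lums[2], lums[3])
    expect_equal(disk_lambda(s, io), log(lums[1] / lums[3]),
                 tolerance = 1e-9)
    refl <- sort(runif(4, 0.05, 0.9))
    gelb <- make_staircase_gelb(refl, spotlight_illum = 1000, bg_lum = 1,
                                size_deg = 19.2)
    est <- region_lightness(gelb, spot = spotlight("wide"), config = io)
    expect_equal(est$lambda, log(est$luminance / 1), tolerance = 1e-9)
  }
})

test_that("default weights reproduce the hand-computed weighted path sum", {
  # decremental disk (bg 1, annulus 100, disk 10) with a uniform kernel:
  # (1/3) ln(100) - ln(10), from the polarity weights alone
  cfg <- model_config(kernel = "uniform")
  stim <- small_disk_annulus(10, 100, 1)
  expect_equal(disk_lambda(stim, cfg), (1 / 3) * log(100) - log(10),
               tolerance = 1e-9)
  # with the exponential kernel, only the non-abutting outer edge is
  # distance-discounted, at the centroid-to-border distance
  cfge <- model_config()
  e <- extract_edges(stim)
  outer <- find_edges(e, 1L, 2L)
  ctr <- region_centroid(stim, region_label(stim, "disk"))
  d_out <- edgelight:::edge_target_distance(e, outer,
                                            region_label(stim, "disk"), ctr)
  expect_equal(disk_lambda(stim, cfge),
               (1 / 3) * distance_weight(d_out, cfge) * log(100) - log(10),
               tolerance = 1e-9)
})

test_that("lightness is invariant to global luminance scaling", {
  stim <- small_disk_annulus(30, 90, 10)
  cfg <- model_config()
  base <- disk_lambda(stim, cfg)
  maps_base <- compute_channel_maps(
    apply_gain_field(extract_edges(stim), spotlight("wide"), cfg),
    stim, cfg)
  for (c_scale in c(0.2, 50)) {
    scaled <- luminance_stimulus(stim$image * c_scale, stim$pitch,
                                 stim$regions, stim$background,
                                 region_names = stim$region_names)
    expect_equal(disk_lambda(scaled, cfg), base, tolerance = 1e-9)
    maps <- compute_channel_maps(
      apply_gain_field(extract_edges(scaled), spotlight("wide"), cfg),
      scaled, cfg)
    expect_equal(maps$L, maps_base$L, tolerance = 1e-9)
    expect_equal(maps$D, maps_base$D, tolerance = 1e-9)
  }
})

test_that("darkness induction outweighs lightness induction threefold", {
  # mirrored contrast pair: disk at L*k and L/k on a uniform background L
  L <- 50; k <- 4
  inc <- make_disk_annulus(L * k, L, L, size_deg = 12.8)  # annulus = bg lum
  dec <- make_disk_annulus(L / k, L, L, size_deg = 12.8)
  cfg <- model_config()
  lam_inc <- disk_lambda(inc, cfg)
  lam_dec <- disk_lambda(dec, cfg)
  expect_equal(abs(lam_dec) / abs(lam_inc), cfg$w_dec / cfg$w_inc,
               tolerance = 1e-9)
  expect_equal(abs(lam_dec), 3 * abs(lam_inc), tolerance = 1e-9)
})

test_that("channel maps activate the correct polarity channels", {
  cfg <- model_config()
  # uniform image: both channels silent
  flat <- small_disk_annulus(50, 50, 50)
  mf <- compute_channel_maps(extract_edges(flat), flat, cfg)
  expect_true(all(mf$L == 0) && all(mf$D == 0))
  # decremental disk in incremental annulus: D from the inner edge and L
  # from the outer edge both reach the disk interior (filling-in)
  stim <- small_disk_annulus(30, 90, 10)
  m <- compute_channel_maps(extract_edges(stim), stim, cfg)
  disk <- stim$regions == 3L
  expect_true(all(m$D[disk] > 0))
  expect_true(all(m$L[disk] > 0))
  expect_true(all(m$L >= 0) && all(m$D >= 0))
  # double-increment display: no darkness-driving edges anywhere
  di <- small_disk_annulus(120, 60, 10)
  md <- compute_channel_maps(extract_edges(di), di, cfg)
  expect_true(all(md$D[di$regions == 3L] == 0))
})

test_that("disk AC decreases as the outer border moves away", {
  cfg <- model_config()
  demo <- run_annulus_width_demo(widths = c(0.5, 2), config = cfg)
  expect_lt(demo$disk_ac[demo$width == 2], demo$disk_ac[demo$width == 0.5])
  # a uniform kernel removes the distance dependence entirely
  flat_cfg <- model_config(kernel = "uniform")
  demo2 <- run_annulus_width_demo(widths = c(0.5, 2), config = flat_cfg)
  expect_equal(demo2$disk_ac[1], demo2$disk_ac[2], tolerance = 1e-9)
})

test_that("exponential kernel bows the disk interior, linear kernel does not", {
  # concentric squares: along the central row the distance transform is
  # exact, so the interior AC profile reflects the kernel shape alone
  stim <- square_annulus_stimulus()
  mid <- nrow(stim$image) / 2L
  interior <- function(cfg) {
    e <- apply_gain_field(extract_edges(stim), spotlight("wide"), cfg)
    ac <- compute_ac(compute_channel_maps(e, stim, cfg))
    cols <- which(stim$regions[mid, ] == 3L)
    ac$AC[mid, cols[2:(length(cols) - 1)]]
  }
  prof_exp <- interior(model_config(kernel = "exponential"))
  half <- prof_exp[1:(length(prof_exp) %/% 2)]
  # strictly increasing toward the centre, strictly curved (meniscus)
  expect_true(all(diff(half) > 0))
  expect_true(all(diff(diff(half)) < 0))
  prof_lin <- interior(model_config(kernel = "linear"))
  half_lin <- prof_lin[1:(length(prof_lin) %/% 2)]
  # linear kernel: straight (zero-curvature) interior profile
  expect_true(all(abs(diff(diff(half_lin))) < 1e-9))
})

test_that("circular decremental disk has its AC maximum at the centre", {
  cfg <- model_config()
  stim <- small_disk_annulus(30, 90, 10)
  e <- apply_gain_field(extract_edges(stim), spotlight("wide"), cfg)
  ac <- compute_ac(compute_channel_maps(e, stim, cfg))
  mid <- ceiling((nrow(ac$AC) + 1) / 2)
  cols <- which(stim$regions[mid, ] == 3L)
  prof <- ac$AC[mid, cols]
  ctr <- (length(prof) + 1) / 2
  expect_lte(abs(which.max(prof) - ctr), 1)
  expect_gt(prof[floor(ctr)], prof[1])
  expect_gt(prof[floor(ctr)], prof[length(prof)])
})
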