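test_that("region graphs capture stimulus topology", {
  stim <- small_disk_annulus(30, 90, 10)
  e <- extract_edges(stim)
  g <- build_region_graph(stim, e)
  expect_true(igraph::is_connected(g))
  expect_equal(sort(igraph::V(g)$name), c("1", "2", "3"))
  # bg -- annulus -- disk path graph: disk and bg are not adjacent
  expect_equal(igraph::distances(g, "1", "3")[1, 1], 2)

  # plain Gelb: bg adjacent to every paper, papers chained
  gelb <- make_staircase_gelb(default_gelb_reflectances(), size_deg = 19.2)
  gg <- build_region_graph(gelb, extract_edges(gelb))
  papers <- vapply(1:5, function(i)
    region_label(gelb, paste0("paper", i)), integer(1))
  for (p in papers)
    expect_equal(igraph::distances(gg, "1", as.character(p))[1, 1], 1)
  for (i in 1:4)
    expect_equal(igraph::distances(gg, as.character(papers[i]),
                                   as.character(papers[i + 1]))[1, 1], 1)

  # insulated Gelb: bg only touches the frame
  ins <- make_staircase_gelb(default_gelb_reflectances(), size_deg = 19.2,
                             frame = list(reflectance = 0.9, thickness = 1))
  gi <- build_region_graph(ins, extract_edges(ins))
  for (i in 1:5) {
    p <- as.character(region_label(ins, paste0("paper", i)))
    expect_equal(igraph::distances(gi, "1", p)[1, 1], 2)
  }
})

test_that("wide-field paths run from the background, skipping sibling borders", {
  stim <- small_disk_annulus(30, 90, 10)
  e <- extract_edges(stim)
  g <- build_region_graph(stim, e)
  p <- select_paths(g, region_label(stim, "disk"))
  expect_length(p, 1L)
  expect_equal(p[[1]]$regions, c(1L, 2L, 3L))
  expect_length(p[[1]]$edge_ids, 2L)

  gelb <- make_staircase_gelb(default_gelb_reflectances(), size_deg = 19.2)
  eg <- extract_edges(gelb)
  gg <- build_region_graph(gelb, eg)
  papers <- vapply(1:5, function(i)
    region_label(gelb, paste0("paper", i)), integer(1))
  inter_paper <- unlist(lapply(1:4, function(i)
    find_edges(eg, papers[i], papers[i + 1])))
  for (perm_target in papers) {
    pw <- select_paths(gg, perm_target)
    expect_equal(pw[[1]]$regions, c(1L, perm_target))
    # inter-paper borders never participate in wide mode
    expect_length(intersect(pw[[1]]$edge_ids, inter_paper), 0L)
  }

  ins <- make_staircase_gelb(default_gelb_reflectances(), size_deg = 19.2,
                             frame = list(reflectance = 0.9, thickness = 1))
  gi <- build_region_graph(ins, extract_edges(ins))
  pi1 <- select_paths(gi, region_label(ins, "paper3"))
  expect_equal(pi1[[1]]$regions,
               c(1L, region_label(ins, "frame"), region_label(ins, "paper3")))
})

test_that("narrow-field pseudo-paths match the target's distinct boundaries", {
  gelb <- make_staircase_gelb(default_gelb_reflectances(), size_deg = 19.2)
  eg <- extract_edges(gelb)
  gg <- build_region_graph(gelb, eg)
  # interior paper: left neighbour, right neighbour, bg above, bg below
  mid <- region_label(gelb, "paper3")
  pn <- select_paths(gg, mid, spotlight("narrow"))
  expect_equal(attr(pn, "mode"), "narrow")
  expect_length(pn, 4L)
  origins <- vapply(pn, function(p) p$regions[1], integer(1))
  expect_equal(sum(origins == 1L), 2L)  # bg twice (above and below)
  expect_setequal(setdiff(origins, 1L),
                  c(region_label(gelb, "paper2"),
                    region_label(gelb, "paper4")))
  # end paper: wrap-around bg border plus one neighbour
  pe <- select_paths(gg, region_label(gelb, "paper1"), spotlight("narrow"))
  expect_length(pe, 2L)
  # disk in an annulus: a single bounding edge
  stim <- small_disk_annulus(30, 90, 10)
  gd <- build_region_graph(stim, extract_edges(stim))
  expect_length(select_paths(gd, 3L, spotlight("narrow")), 1L)
})

test_that("select_paths rejects invalid targets", {
  stim <- small_disk_annulus(30, 90, 10)
  g <- build_region_graph(stim, extract_edges(stim))
  expect_error(select_paths(g, stim$background), "differ from the background")
  expect_error(select_paths(g, 99L), "unknown target")
})

test_that("gain field combines mask, interpretation and sharpness gains", {
  stim <- small_disk_annulus(30, 90, 10)
  e <- extract_edges(stim)
  cfg <- model_config()
  outer <- find_edges(e, 1L, 2L)
  inner <- find_edges(e, 2L, 3L)
  # identity case: mask 1, all sharp, reflectance mode
  e1 <- apply_gain_field(e, spotlight("wide"), cfg)
  expect_equal(e1$edges$gain, c(1, 1))
  # idempotence
  expect_equal(apply_gain_field(e1, spotlight("wide"), cfg)$edges$gain,
               e1$edges$gain)
  # illumination interpretation of the outer edge silences it only
  sp <- spotlight("wide", edge_interpretation =
                    setNames(list("illumination"), as.character(outer)))
  e2 <- apply_gain_field(e, sp, cfg)
  expect_equal(e2$edges$gain[e2$edges$id == outer], 0)
  expect_equal(e2$edges$gain[e2$edges$id == inner], 1)
  # a residual illumination gain is respected
  e3 <- apply_gain_field(e, sp, model_config(g_illum = 0.25))
  expect_equal(e3$edges$gain[e3$edges$id == outer], 0.25)
  # global illumination interpretation hits every edge
  e4 <- apply_gain_field(e, spotlight("wide",
                                      interpretation = "illumination"), cfg)
  expect_equal(e4$edges$gain, c(0, 0))
  # gradient-classified edges get g_gradient
  ramp <- ramp_boundary_stimulus(ramp_width = 5)
  er <- apply_gain_field(extract_edges(ramp), spotlight("wide"), cfg)
  expect_equal(er$edges$gain, 0)
  er2 <- apply_gain_field(extract_edges(ramp), spotlight("wide"),
                          model_config(g_gradient = 0.5))
  expect_equal(er2$edges$gain, 0.5)
  # custom spatial mask scales gains by boundary-mean mask value
  mask <- matrix(0, nrow(stim$image), ncol(stim$image))
  sp_custom <- spotlight("custom", mask = mask)
  e5 <- apply_gain_field(e, sp_custom, cfg)
  expect_equal(e5$edges$gain, c(0, 0))
  expect_error(spotlight("custom"), "mask")
  expect_error(spotlight("custom", mask = mask + 2), "\\[0, 1\\]")
})

test_that("mask_edge zeroes one gain and validates ids", {
  stim <- small_disk_annulus(30, 90, 10)
  e <- extract_edges(stim)
  outer <- find_edges(e, 1L, 2L)
  em <- mask_edge(e, outer)
  expect_equal(em$edges$gain[em$edges$id == outer], 0)
  expect_equal(sum(em$edges$gain), nrow(em$edges) - 1)
  expect_error(mask_edge(e, 999L), "unknown edge id")
})

test_that("paths serialise to CSV with gains and directions", {
  stim <- small_disk_annulus(30, 90, 10)
  e <- extract_edges(stim)
  g <- build_region_graph(stim, e)
  p <- select_paths(g, 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_path_csv(p, e, f)
  expect_equal(nrow(df), 2L)
  expect_equal(df$from_region, c(1L, 2L))
  expect_equal(df$to_region, c(2L, 3L))
  expect_true(file.exists(f))
})
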