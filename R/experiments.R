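# End-to-end experiments: each builds its stimuli, runs the pipeline, and
# returns the quantitative summaries the model is known for (power-law
# compression of the Gelb lightness scale, insulation, ideal-observer
# matching slopes, polarity-weight recovery, scrambling, annulus-width and
# contour-masking effects). Everything here is deterministic.

#' Fit a power law on a log-luminance axis
#'
#' Ordinary least squares of `y` (lightness, already on a log scale) on
#' `ln x`; the slope is the power-law exponent relating the underlying
#' quantities.
#'
#' @param x Positive predictor values (e.g. luminances in cd/m^2).
#' @param y Response on a log scale (e.g. integrated lightness).
#' @return An object of class `"power_law_fit"` with `slope` (the
#'   exponent), `intercept`, and `rss`.
#' @export
fit_power_law <- function(x, y) {
  if (any(x <= 0)) stop("x must be positive")
  if (length(unique(x)) < 2) stop("need at least 2 distinct x values")
  fit <- stats::lm(y ~ log(x))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 rss = sum(stats::resid(fit)^2)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> exponent =", signif(x$slope, 6),
      " intercept =", signif(x$intercept, 6),
      " RSS =", format(x$rss, digits = 3), "\n")
  invisible(x)
}

#' Staircase-Gelb series experiment
#'
#' Builds a staircase-Gelb stimulus, estimates every paper's integrated
#' lightness, and fits lightness against log luminance. In wide-field mode
#' with default weights the fitted exponent is `w_inc` (1/3, compression)
#' for the plain series and `w_dec` (1, linear) when an insulating white
#' frame separates the papers from the background.
#'
#' @param reflectances Paper reflectances; the default is 5 papers
#'   log-spaced from 0.03 to 0.9.
#' @param illum Spotlight illumination; the default (1000, against a
#'   background of `bg_lum = 1` cd/m^2) makes every paper a strong
#'   increment, as the compression result presupposes.
#' @param config A [model_config()].
#' @param insulated If `TRUE`, insert a white frame (reflectance
#'   `frame_reflectance`) between the papers and the background.
#' @param spotlight_mode `"wide"` or `"narrow"`.
#' @param bg_lum Background luminance, cd/m^2.
#' @param frame_reflectance,frame_thickness Frame parameters (used when
#'   `insulated`).
#' @param ... Further arguments to [make_staircase_gelb()].
#' @return A list with `table` (per-paper estimates incl. anchored
#'   reflectance), `fit` (a [fit_power_law()] object), `exponent`, and the
#'   stimulus.
#' @export
run_gelb_series <- function(reflectances = default_gelb_reflectances(),
                            illum = 1000, config = model_config(),
                            insulated = FALSE,
                            spotlight_mode = c("wide", "narrow"),
                            bg_lum = 1, frame_reflectance = 0.9,
                            frame_thickness = 1, ...) {
  spotlight_mode <- match.arg(spotlight_mode)
  frame <- if (insulated)
    list(reflectance = frame_reflectance, thickness = frame_thickness)
  stim <- make_staircase_gelb(reflectances, spotlight_illum = illum,
                              bg_lum = bg_lum, frame = frame, ...)
  papers <- vapply(seq_along(reflectances),
                   function(i) region_label(stim, paste0("paper", i)),
                   integer(1))
  est <- region_lightness(stim, targets = papers,
                          spot = spotlight(spotlight_mode), config = config,
                          anchor_rule = config$anchor_rule)
  fit <- fit_power_law(est$luminance, est$lambda)
  list(table = est, fit = fit, exponent = fit$slope, stimulus = stim)
}

#' Default Gelb paper reflectances
#'
#' Five reflectances log-spaced from 0.03 (charcoal) to 0.9 (white paper).
#' @return Numeric vector of length 5.
#' @export
default_gelb_reflectances <- function() {
  exp(seq(log(0.03), log(0.9), length.out = 5))
}

#' Ideal-observer disk-annulus matching
#'
#' Simulates the asymmetric matching task in which the luminance of the
#' context annulus around one (incremental) disk is varied and a matching
#' disk's luminance is adjusted until the two integrated lightnesses are
#' equal. Under the reflectance interpretation of the outer
#' (annulus/background) edge both edges are integrated with unit weights and
#' the match is a luminance match: slope 0 on log-log axes. Under the
#' illumination interpretation the outer edge's gain is zero and the match
#' is a ratio match: slope -1.
#'
#' Because integrated lightness is affine in the log of the matching disk's
#' luminance, the match is solved in closed form from two probe evaluations
#' of the pipeline.
#'
#' @param annulus_lums Varied annulus luminances; the default is 8 values
#'   log-spaced over one decade.
#' @param fixed List with the fixed luminances `disk` (varied-context side),
#'   `match_annulus` and `bg`, chosen so both disks stay increments.
#' @param interpretation `"reflectance"` or `"illumination"`, applied to
#'   every annulus/background edge.
#' @param config A [model_config()]; the default is the ideal-observer
#'   preset (unit weights, uniform kernel).
#' @param disk_radius,annulus_outer_radius,pitch,size_deg Geometry shared by
#'   both patterns.
#' @return A list with `results` (annulus luminance, matched luminance,
#'   target lightness), `fit` (log-log [fit_power_law()]), `slope`, and the
#'   `interpretation`.
#' @export
run_ideal_observer_matching <- function(
    annulus_lums = 10^seq(log10(5), log10(50), length.out = 8),
    fixed = list(disk = 100, match_annulus = 15, bg = 1),
    interpretation = c("reflectance", "illumination"),
    config = model_config(ideal_observer = TRUE),
    disk_radius = 1, annulus_outer_radius = 3, pitch = 0.1, size_deg = 12.8) {
  interpretation <- match.arg(interpretation)
  if (any(annulus_lums <= 0)) stop("annulus luminances must be positive")
  target_lambda <- function(disk, annulus) {
    stim <- make_disk_annulus(disk, annulus, fixed$bg,
                              disk_radius = disk_radius,
                              annulus_outer_radius = annulus_outer_radius,
                              pitch = pitch, size_deg = size_deg)
    edges <- extract_edges(stim)
    outer <- find_edges(edges, region_label(stim, "annulus"),
                        stim$background)
    spot <- spotlight("wide", interpretation = "reflectance",
                      edge_interpretation = stats::setNames(
                        as.list(rep(interpretation, length(outer))),
                        as.character(outer)))
    est <- region_lightness(stim, targets = region_label(stim, "disk"),
                            spot = spot, config = config, edges = edges)
    est$lambda
  }
  # lightness of the matching disk is affine in log disk luminance:
  # recover the affine map from two probes, then invert
  probe <- c(fixed$disk / 2, fixed$disk * 2)
  lam_probe <- vapply(probe, target_lambda, numeric(1),
                      annulus = fixed$match_annulus)
  beta <- (lam_probe[2] - lam_probe[1]) / (log(probe[2]) - log(probe[1]))
  alpha <- lam_probe[1] - beta * log(probe[1])
  if (beta == 0) stop("no positive solution: lightness insensitive to the ",
                      "matching disk luminance")
  matches <- vapply(annulus_lums, function(al) {
    lam <- target_lambda(fixed$disk, al)
    exp((lam - alpha) / beta)
  }, numeric(1))
  fit <- fit_power_law(annulus_lums, log(matches))
  list(results = data.frame(annulus_lum = annulus_lums,
                            matched_lum = matches),
       fit = fit, slope = fit$slope, interpretation = interpretation)
}

#' Recover the polarity-weight ratio from model-generated matches
#'
#' Generates a noiseless grid of disk-annulus stimuli whose inner
#' (disk/annulus) edges are all decrements toward the disk and whose outer
#' (annulus/background) edges are all increments, computes each disk's
#' integrated lightness, and regresses it on the two directed log edge
#' steps. After dividing out the known distance weight of the outer edge
#' (the polarity asymmetry is defined net of distance), the ratio of the
#' incremental to the decremental coefficient recovers `w_inc / w_dec`
#' exactly, because the generator is the fitted model.
#'
#' @param disk_lums,annulus_lums Grid of luminances; every annulus value
#'   must exceed `bg_lum` and every disk value must be below every annulus
#'   value.
#' @param bg_lum Background luminance.
#' @param config A [model_config()].
#' @param disk_radius,annulus_outer_radius,pitch,size_deg Shared geometry.
#' @return A list with `ratio` (`w_inc / w_dec`), the raw regression
#'   `coefficients` (decremental and incremental), and the design `table`.
#' @export
run_weight_recovery <- function(disk_lums = c(20, 40, 80),
                                annulus_lums = c(160, 240, 360),
                                bg_lum = 100, config = model_config(),
                                disk_radius = 1, annulus_outer_radius = 3,
                                pitch = 0.1, size_deg = 12.8) {
  if (any(annulus_lums <= bg_lum) || any(max(disk_lums) >= annulus_lums))
    stop("design must keep inner edges decremental and outer edges ",
         "incremental")
  grid <- expand.grid(disk = disk_lums, annulus = annulus_lums)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    stim <- make_disk_annulus(grid$disk[i], grid$annulus[i], bg_lum,
                              disk_radius = disk_radius,
                              annulus_outer_radius = annulus_outer_radius,
                              pitch = pitch, size_deg = size_deg)
    est <- region_lightness(stim, targets = region_label(stim, "disk"),
                            config = config)
    data.frame(disk = grid$disk[i], annulus = grid$annulus[i],
               step_inner = log(grid$disk[i] / grid$annulus[i]),
               step_outer = log(grid$annulus[i] / bg_lum),
               lambda = est$lambda)
  })
  tab <- do.call(rbind, rows)
  if (stats::sd(tab$step_inner) == 0 || stats::sd(tab$step_outer) == 0)
    stop("rank-deficient design: both edge steps must vary")
  fit <- stats::lm(lambda ~ step_inner + step_outer, data = tab)
  co <- stats::coef(fit)
  # outer-edge distance is fixed by the shared geometry; divide its weight
  # out so the ratio reflects polarity alone
  stim0 <- make_disk_annulus(disk_lums[1], annulus_lums[1], bg_lum,
                             disk_radius = disk_radius,
                             annulus_outer_radius = annulus_outer_radius,
                             pitch = pitch, size_deg = size_deg)
  edges0 <- extract_edges(stim0)
  outer_id <- find_edges(edges0, region_label(stim0, "annulus"),
                         stim0$background)[1]
  d_out <- edge_target_distance(edges0, outer_id,
                                region_label(stim0, "disk"),
                                region_centroid(stim0,
                                                region_label(stim0, "disk")))
  g_out <- distance_weight(d_out, config)
  ratio <- (unname(co["step_outer"]) / g_out) / unname(co["step_inner"])
  list(ratio = ratio,
       coefficients = c(decremental = unname(co["step_inner"]),
                        incremental = unname(co["step_outer"])),
       outer_distance_weight = g_out, table = tab)
}

#' Scrambling the Gelb paper order
#'
#' Computes each paper's integrated lightness before and after permuting the
#' paper order. In wide-field mode every paper is compared to the same
#' common background, so scrambling changes nothing; in narrow-field mode a
#' paper is compared to its immediate neighbours, so papers whose neighbours
#' change shift in lightness (the spatial-ordering effect).
#'
#' Note that permutations that preserve each paper's multiset of neighbour
#' log-luminance ratios (e.g. reversing an equally log-spaced series) leave
#' even narrow-mode lightness unchanged; the default permutation swaps two
#' interior papers, which does not.
#'
#' @param reflectances Paper reflectances in original order.
#' @param permutation Integer permutation of `seq_along(reflectances)`;
#'   the default swaps the two middle papers.
#' @param spotlight_mode `"wide"` or `"narrow"`.
#' @param config A [model_config()].
#' @param ... Further arguments to [run_gelb_series()] /
#'   [make_staircase_gelb()].
#' @return A data frame with one row per paper identity: `reflectance`,
#'   `lambda_before`, `lambda_after`, `max_change` attribute.
#' @export
run_scrambling <- function(reflectances = default_gelb_reflectances(),
                           permutation = swap_middle(length(reflectances)),
                           spotlight_mode = c("wide", "narrow"),
                           config = model_config(), ...) {
  spotlight_mode <- match.arg(spotlight_mode)
  if (!setequal(permutation, seq_along(reflectances)))
    stop("invalid permutation")
  before <- run_gelb_series(reflectances, config = config,
                            spotlight_mode = spotlight_mode, ...)
  after <- run_gelb_series(reflectances[permutation], config = config,
                           spotlight_mode = spotlight_mode, ...)
  # align by paper identity: paper i sits at position match(i, permutation)
  pos_after <- match(seq_along(reflectances), permutation)
  out <- data.frame(reflectance = reflectances,
                    lambda_before = before$table$lambda,
                    lambda_after = after$table$lambda[pos_after])
  attr(out, "max_change") <- max(abs(out$lambda_after - out$lambda_before))
  out
}

# permutation exchanging the two middle elements of 1..n
swap_middle <- function(n) {
  p <- seq_len(n)
  i <- floor(n / 2)
  p[c(i, i + 1L)] <- p[c(i + 1L, i)]
  p
}

#' Annulus-width demonstration
#'
#' Two identical decremental disks with equal-luminance annuli of different
#' widths. The contribution of the (lightness-inducing) annulus/background
#' border falls with its distance from the disk, so the disk inside the
#' wider annulus has strictly lower mean achromatic color.
#'
#' @param disk_lum,annulus_lum,bg_lum Luminances; the disk must be a
#'   decrement relative to the annulus.
#' @param widths Two distinct annulus widths, deg.
#' @param config A [model_config()].
#' @param disk_radius,pitch,size_deg Geometry.
#' @return A data frame with one row per width: `width`, `outer_radius`,
#'   `disk_ac` (mean achromatic color over disk pixels).
#' @export
run_annulus_width_demo <- function(disk_lum = 30, annulus_lum = 90,
                                   bg_lum = 10, widths = c(1, 3),
                                   config = model_config(),
                                   disk_radius = 1, pitch = 0.1,
                                   size_deg = 12.8) {
  if (disk_lum >= annulus_lum) stop("disk must be a decrement")
  rows <- lapply(widths, function(w) {
    stim <- make_disk_annulus(disk_lum, annulus_lum, bg_lum,
                              disk_radius = disk_radius,
                              annulus_outer_radius = disk_radius + w,
                              pitch = pitch, size_deg = size_deg)
    edges <- apply_gain_field(extract_edges(stim), spotlight("wide"), config)
    ac <- compute_ac(compute_channel_maps(edges, stim, config))
    disk <- stim$regions == region_label(stim, "disk")
    data.frame(width = w, outer_radius = disk_radius + w,
               disk_ac = mean(ac$AC[disk]))
  })
  do.call(rbind, rows)
}

#' Contour-masking (flicker adaptation) experiment
#'
#' Recomputes the achromatic color map after silencing one edge, simulating
#' selective flicker masking of its edge detectors. Masking the outer
#' (annulus/background) edge of a decremental disk removes its lightness
#' induction, darkening the disk; masking the inner (disk/annulus) edge
#' removes the darkness induction and the disk fills in toward the annulus
#' level.
#'
#' @param stim A [luminance_stimulus()].
#' @param edge_to_mask Edge id to silence (see [find_edges()]).
#' @param config A [model_config()].
#' @param spot A [spotlight()] applied before masking.
#' @return A list with `before` and `after` achromatic maps and `delta`, a
#'   data frame of per-region mean AC change.
#' @export
run_contour_masking <- function(stim, edge_to_mask,
                                config = model_config(),
                                spot = spotlight("wide")) {
  edges <- apply_gain_field(extract_edges(stim), spot, config)
  before <- compute_ac(compute_channel_maps(edges, stim, config))
  after <- compute_ac(compute_channel_maps(mask_edge(edges, edge_to_mask),
                                           stim, config))
  labs <- sort(unique(as.vector(stim$regions)))
  delta <- data.frame(
    region = labs,
    ac_before = vapply(labs, function(l) mean(before$AC[stim$regions == l]),
                       numeric(1)),
    ac_after = vapply(labs, function(l) mean(after$AC[stim$regions == l]),
                      numeric(1)))
  delta$change <- delta$ac_after - delta$ac_before
  list(before = before, after = after, delta = delta)
}

#' Calibrated range of the default distance kernel
#'
#' Solves `distance_weight(d, config) = level` for `d`, reporting the
#' distance at which contextual influence falls to `level` of its
#' zero-distance peak (5% by default).
#'
#' @param config A [model_config()].
#' @param level Fraction of peak weight.
#' @return Distance in deg.
#' @export
kernel_range <- function(config = model_config(), level = 0.05) {
  if (config$kernel == "uniform")
    stop("the uniform kernel never decays")
  f <- function(d) distance_weight(d, config) - level
  # bracket slightly past the hard cutoff, where the weight is clipped to 0
  stats::uniroot(f, c(0, config$range_cutoff * (1 + 1e-9)),
                 tol = 1e-12)$root
}
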