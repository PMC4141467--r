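# Configuration, serialisation and output plumbing.
# Units everywhere: angles in degrees, luminances in cd/m^2, logs natural.

config_defaults <- function() {
  list(
    model = list(w_inc = 1 / 3, w_dec = 1, kernel = "exponential",
                 tau = 10 / log(20), range_cutoff = 10,
                 log_b = 0.95 / log10(11), log_d0 = 1,
                 ideal_observer = FALSE, g_illum = 0, g_gradient = 0,
                 anchor_rule = "highest_reflectance", R_white = 0.9),
    stimulus = list(kind = "disk_annulus", disk_lum = 30, annulus_lum = 90,
                    bg_lum = 10, disk_radius = 1, annulus_outer_radius = 3,
                    pitch = 0.1, size_deg = 25.6),
    spotlight = list(mode = "wide", interpretation = "reflectance"),
    output = list(dir = ".", verbose = FALSE)
  )
}

#' Load a run configuration
#'
#' Reads a YAML file with sections `model`, `stimulus`, `spotlight` and
#' `output`, validates every value, fills documented defaults (an empty file
#' yields the full default configuration: `w_inc = 1/3`, `w_dec = 1`,
#' exponential kernel with `tau = 10/log(20)`, 10-deg cutoff), and fails
#' loudly on unknown keys.
#'
#' @param path Path to a YAML config file.
#' @return A validated list of class `"run_config"` whose `model` element is
#'   a [model_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defs <- config_defaults()
  bad <- setdiff(names(user), names(defs))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(user)) {
    badk <- setdiff(names(user[[sec]]), names(defs[[sec]]))
    if (sec == "stimulus") badk <- setdiff(badk, stimulus_keys())
    if (length(badk)) stop("unknown key(s) in [", sec, "]: ",
                           paste(badk, collapse = ", "))
  }
  cfg <- utils::modifyList(defs, user)
  cfg$model <- do.call(model_config, cfg$model)
  if (!cfg$stimulus$kind %in% c("disk_annulus", "simultaneous_contrast",
                                "staircase_gelb", "coc_edge",
                                "gradient_background_pair"))
    stop("unknown stimulus kind: ", cfg$stimulus$kind)
  if (!cfg$spotlight$mode %in% c("wide", "narrow", "custom"))
    stop("unknown spotlight mode: ", cfg$spotlight$mode)
  structure(cfg, class = "run_config")
}

stimulus_keys <- function() {
  c("reflectances", "spotlight_illum", "paper_size", "gap", "frame",
    "plateau_lum", "cusp_amplitude", "cusp_width", "image_width",
    "ramp_slope", "offset", "patch_lum", "dark_lum", "light_lum",
    "patch_size", "center")
}

#' Save a run configuration
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))` round
#' trips.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$model <- unclass(out$model)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Build the stimulus described by a run configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A [luminance_stimulus()].
#' @export
build_stimulus <- function(cfg) {
  s <- cfg$stimulus
  gen <- switch(s$kind,
                disk_annulus = make_disk_annulus,
                simultaneous_contrast = make_simultaneous_contrast,
                staircase_gelb = make_staircase_gelb,
                coc_edge = make_coc_edge,
                gradient_background_pair = make_gradient_background_pair)
  args <- s[names(s) %in% names(formals(gen))]
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(gen, args)
}

#' Write a matrix as a 16-bit portable graymap (PGM, P5)
#'
#' Values are linearly scaled to the 0..65535 range; the scaling is
#' returned (and recorded in JSON sidecars by [write_outputs()]) so the
#' physical values can be recovered.
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @param lo,hi Physical values mapped to 0 and 65535 (default: the matrix
#'   range; a constant matrix maps to 0).
#' @return List with `lo`, `hi` scaling, invisibly.
#' @export
write_pgm <- function(mat, path, lo = min(mat), hi = max(mat)) {
  scaled <- if (hi > lo) (mat - lo) / (hi - lo) else mat * 0
  v <- round(scaled * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(mat), nrow(mat)), con,
            eos = NULL)
  # row-major pixel order, 2 bytes per sample, big-endian
  vv <- as.integer(t(v))
  writeBin(as.raw(rbind(vv %/% 256L, vv %% 256L)), con)
  invisible(list(lo = lo, hi = hi))
}

#' Read a 16-bit binary PGM written by [write_pgm()]
#'
#' @param path PGM file path.
#' @return Integer matrix of raw 0..65535 samples.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "P5")) stop("not a binary PGM file")
  dims <- scan(con, n = 3, quiet = TRUE)
  raw <- readBin(con, "raw", n = 2 * dims[1] * dims[2])
  hi <- as.integer(raw[c(TRUE, FALSE)]); lo <- as.integer(raw[c(FALSE, TRUE)])
  matrix(hi * 256L + lo, nrow = dims[2], byrow = TRUE)
}

#' Write run results to a directory
#'
#' Dispatches on element type: data frames become CSV, matrices become
#' 16-bit PGM with the scaling recorded in the JSON summary, everything
#' else is collected into `summary.json`. Files are written atomically
#' (temp file + rename) and listed in `manifest.json` with MD5 content
#' hashes; deterministic results therefore produce byte-identical outputs.
#'
#' @param results Named list of results.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  atomic <- function(write_fun, final) {
    tmp <- paste0(final, ".tmp")
    write_fun(tmp)
    if (!file.rename(tmp, final)) stop("failed to write ", final)
    final
  }
  files <- character(0)
  summary <- list(units = list(angle = "deg", luminance = "cd/m^2",
                               log = "natural"),
                  schema_version = 1L)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      atomic(function(p) utils::write.csv(as.data.frame(x), p,
                                          row.names = FALSE), f)
      files <- c(files, f)
    } else if (is.matrix(x)) {
      f <- file.path(out_dir, paste0(nm, ".pgm"))
      sc <- NULL
      atomic(function(p) sc <<- write_pgm(x, p), f)
      summary[[nm]] <- list(file = basename(f), scale = sc)
      files <- c(files, f)
    } else {
      summary[[nm]] <- x
    }
  }
  fs <- file.path(out_dir, "summary.json")
  atomic(function(p) jsonlite::write_json(summary, p, auto_unbox = TRUE,
                                          digits = NA, pretty = TRUE), fs)
  files <- c(files, fs)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  fm <- file.path(out_dir, "manifest.json")
  atomic(function(p) jsonlite::write_json(manifest, p, pretty = TRUE), fm)
  invisible(manifest)
}
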