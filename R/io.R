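#' Write a simulated dataset as a curve archive
#'
#' The archive is a directory holding one two-column CSV per curve
#' (`distance_nm`, `force_pN`), a JSON manifest (schema version, units
#' declaration, per-curve metadata, file inventory with MD5 checksums,
#' scenario parameters) and the ground truth as JSON-lines.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir target directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_curve_archive <- function(dataset, dir) {
  dir.create(file.path(dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  files <- character(length(dataset$curves))
  meta <- vector("list", length(dataset$curves))
  for (i in seq_along(dataset$curves)) {
    cu <- dataset$curves[[i]]
    fn <- sprintf("curves/curve_%06d.csv", i)
    write.csv(data.frame(distance_nm = cu$distance, force_pN = cu$force),
              file.path(dir, fn), row.names = FALSE)
    files[i] <- fn
    meta[[i]] <- list(file = fn, curve_id = cu$curve_id,
                      pulling_speed_um_s = cu$pulling_speed,
                      contact_time_s = cu$contact_time)
  }
  sums <- unname(tools::md5sum(file.path(dir, files)))
  manifest <- list(
    schema_version = "1.0",
    units = list(distance = "nm", force = "pN", speed = "um/s",
                 time = "s", loading_rate = "pN/s"),
    n_curves = length(files),
    curves = meta,
    checksums = as.list(setNames(sums, files)),
    scenario = if (!is.null(dataset$scenario))
      unclass_scenario(dataset$scenario) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(dataset$truth)) {
    con <- file(file.path(dir, "truth.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(dataset$truth)))
      writeLines(jsonlite::toJSON(as.list(dataset$truth[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  invisible(dir)
}

unclass_scenario <- function(sc) {
  out <- unclass(sc)
  out$bond <- unclass(out$bond)
  out
}

#' Read a curve archive back into memory
#'
#' Verifies that every file listed in the manifest exists, then rebuilds
#' the [force_curve()] list and ground-truth data.frame.
#'
#' @param dir archive directory written by [write_curve_archive()].
#' @return list with `curves`, `truth` (NULL when absent), `manifest`.
#' @export
read_curve_archive <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  curves <- lapply(manifest$curves, function(m) {
    path <- file.path(dir, m$file)
    if (!file.exists(path)) stop("archive file missing: ", m$file)
    df <- read.csv(path)
    force_curve(df$distance_nm, df$force_pN,
                pulling_speed = m$pulling_speed_um_s,
                contact_time = m$contact_time_s, curve_id = m$curve_id)
  })
  tpath <- file.path(dir, "truth.jsonl")
  truth <- NULL
  if (file.exists(tpath)) {
    rows <- lapply(readLines(tpath), function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    truth <- do.call(rbind, rows)
  }
  list(curves = curves, truth = truth, manifest = manifest)
}

#' Write / read a rupture-events table as CSV
#'
#' Header: curve_id, rank, unbinding_force (pN),
#' effective_spring_constant (pN/nm), loading_rate (pN/s),
#' unbinding_length (nm), noise_sigma (pN).
#'
#' @param events a `rupture_events` data.frame.
#' @param path CSV path.
#' @return `read_events_csv` returns the `rupture_events` data.frame.
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("rupture_events", "data.frame")
  df
}

#' Height-map converters: float TIFF and whitespace-delimited text
#'
#' The text format carries the pixel size in a `# pixel_size_nm:` comment
#' line followed by one image row per line.  Round trips are lossless
#' within floating-point representation.
#'
#' @param img a [height_map()].
#' @param path file path.
#' @param pixel_size pixel size, nm (TIFF reader only; TIFF carries no
#'   calibrated pixel size).
#' @return readers return a [height_map()].
#' @export
write_heightmap_txt <- function(img, path) {
  stopifnot(inherits(img, "height_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm: %.17g", img$pixel_size), con)
  utils::write.table(format(img$heights, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_heightmap_txt
#' @export
read_heightmap_txt <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# pixel_size_nm:", first))
    stop("parse error at line 1 of ", path,
         ": expected '# pixel_size_nm:' header")
  px <- as.numeric(sub("^# pixel_size_nm:\\s*", "", first))
  m <- as.matrix(read.table(path, skip = 1))
  dimnames(m) <- NULL
  height_map(m, px)
}

#' @rdname write_heightmap_txt
#' @details TIFF float storage is normalized to `[0, 1]`; the affine
#'   calibration (offset, scale, pixel size) travels in a
#'   `<path>.meta.json` sidecar, which the reader applies when present.
#' @export
write_heightmap_tiff <- function(img, path) {
  stopifnot(inherits(img, "height_map"))
  h <- img$heights
  offset <- min(h)
  scale <- max(h) - offset
  if (scale == 0) scale <- 1
  tiff::writeTIFF((h - offset) / scale, path, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(
    list(offset_nm = offset, scale_nm = scale,
         pixel_size_nm = img$pixel_size),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heightmap_txt
#' @export
read_heightmap_tiff <- function(path, pixel_size = 1) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    m <- m * meta$scale_nm + meta$offset_nm
    pixel_size <- meta$pixel_size_nm
  }
  height_map(m, pixel_size)
}

#' Run the full pipeline from a YAML configuration
#'
#' Configuration sections: `seed`; `scenario` (any [sim_scenario()]
#' argument; `bond` as a k_off/x_beta/kBT list); `detection`
#' ([detect_ruptures()] arguments); `kinetics` (`radius_nm`,
#' `n_ligands`); `output` (directory).  Executes simulate -> detect ->
#' segment -> peak fits -> Bell-Evans fit -> two-bond overlay -> rate
#' summary, writes `results.json` plus a reproducibility record (config
#' checksum, seed, package version), and returns the result bundle.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory; overrides `output$dir` in the config.
#' @return list with `dataset`, `events`, `segments`, `fit`, `overlay`,
#'   `binding`, `results` (the JSON-ready summary).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing input file: ", config)
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  sc_args <- config$scenario
  if (is.null(sc_args)) stop("config stage 'scenario': section missing")
  if (!is.null(sc_args$bond))
    sc_args$bond <- do.call(bell_params, sc_args$bond)
  if (!is.null(config$seed)) sc_args$seed <- config$seed
  for (nm in c("pulling_speeds", "contact_times", "noise_sigma_range"))
    if (!is.null(sc_args[[nm]])) sc_args[[nm]] <- unlist(sc_args[[nm]])
  scenario <- do.call(sim_scenario, sc_args)
  dataset <- simulate_dataset(scenario)
  det_args <- config$detection %||% list()
  events <- do.call(detect_dataset, c(list(dataset$curves), det_args))
  binding <- binding_probability(events, length(dataset$curves))
  segs <- segment_by_loading_rate(events)
  segs <- lapply(segs, segment_peak_stats, events = events)
  fit <- fit_bell_evans(segs, kBT = scenario$bond$kBT)
  rates <- vapply(segs, `[[`, numeric(1), "rep_rate")
  overlay <- predict_double_bond_overlay(
    fit, exp(seq(log(min(rates)), log(max(rates)), length.out = 50)))
  results <- list(
    reproducibility = list(
      config_md5 = cfg_hash, seed = scenario$seed,
      package_version = as.character(utils::packageVersion("bondkin"))),
    binding_probability = binding,
    n_events = nrow(events),
    segments = lapply(segs, function(s)
      s[c("log10_lo", "log10_hi", "n", "rep_rate", "peak_mean", "peak_sd")]),
    bell_evans = list(k_off = fit$params$k_off,
                      x_beta = fit$params$x_beta,
                      se_log10_koff = fit$se_log10_koff,
                      se_xbeta = fit$se_xbeta,
                      n_segments = fit$n_segments))
  out_dir <- out_dir %||% config$output$dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_events_csv(events, file.path(out_dir, "events.csv"))
  }
  list(dataset = dataset, events = events, segments = segs, fit = fit,
       overlay = overlay, binding = binding, results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
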