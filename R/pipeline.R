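# Volume and parameter-map I/O plus end-to-end pipeline orchestration.
# Volumes are persisted as one-column CSVs (column-major order) next to a
# JSON sidecar carrying shape and geometry: plain text, diff-able, and
# byte-deterministic. Values are rounded to float32-equivalent precision
# on write (7 significant digits); statistics are computed in float64 in
# memory.

write_volume_csv <- function(arr, path) {
  data.table::fwrite(data.frame(value = signif(as.vector(arr), 8)), path,
                     na = "NaN")
  invisible(path)
}

read_volume_csv <- function(path, dims) {
  v <- data.table::fread(path)$value
  if (length(v) != prod(dims)) {
    stop("volume file length does not match the recorded shape",
         call. = FALSE)
  }
  array(v, dim = dims)
}

#' Write / read a parameter map as a plain-text directory
#'
#' The directory holds `meta.json` (shape, voxel size, format version)
#' and one CSV per volume (`t1_ms`, `t2_ms`, `m0_magnitude`, `score`,
#' `mask`). Masked-out voxels are written as NaN in the value volumes;
#' the mask itself is stored as 0/1. A missing mask file is read as
#' all-reported, with a warning.
#'
#' @param pmap a [parameter_map()].
#' @param path directory to create/overwrite.
#' @return `write_parameter_map` returns `path` invisibly;
#'   `read_parameter_map` returns a `parameter_map`.
#' @export
write_parameter_map <- function(pmap, path) {
  stopifnot(inherits(pmap, "parameter_map"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(pmap$t1_ms)
  jsonlite::write_json(
    list(format = "mrfmap-parameter-map", version = "1",
         shape = d, voxel_size_mm = pmap$voxel_size_mm),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  blank <- function(v) {
    v[!pmap$mask] <- NaN
    v
  }
  write_volume_csv(blank(pmap$t1_ms), file.path(path, "t1_ms.csv"))
  write_volume_csv(blank(pmap$t2_ms), file.path(path, "t2_ms.csv"))
  write_volume_csv(blank(pmap$m0_magnitude),
                   file.path(path, "m0_magnitude.csv"))
  write_volume_csv(blank(pmap$score), file.path(path, "score.csv"))
  write_volume_csv(pmap$mask * 1L, file.path(path, "mask.csv"))
  invisible(path)
}

#' @rdname write_parameter_map
#' @export
read_parameter_map <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "mrfmap-parameter-map")) {
    stop("not an mrfmap parameter-map directory", call. = FALSE)
  }
  dims <- as.integer(meta$shape)
  if (length(dims) != 3L) {
    stop("parameter map must be 3D (shape of length 3)", call. = FALSE)
  }
  mask_path <- file.path(path, "mask.csv")
  mask <- if (file.exists(mask_path)) {
    read_volume_csv(mask_path, dims) > 0
  } else {
    warning("mask volume missing; defaulting to all-reported",
            call. = FALSE)
    array(TRUE, dims)
  }
  parameter_map(
    t1_ms = read_volume_csv(file.path(path, "t1_ms.csv"), dims),
    t2_ms = read_volume_csv(file.path(path, "t2_ms.csv"), dims),
    m0_magnitude = read_volume_csv(file.path(path, "m0_magnitude.csv"),
                                   dims),
    score = read_volume_csv(file.path(path, "score.csv"), dims),
    mask = mask,
    voxel_size_mm = as.numeric(meta$voxel_size_mm))
}

#' Pipeline configuration
#'
#' Collects every knob of the simulate -> build-dict -> match -> qa-report
#' chain. All randomness derives from `seed`; per-session noise seeds are
#' offsets of it, and every seed used is recorded in the run manifest.
#'
#' @param out_dir output directory.
#' @param seed base integer seed.
#' @param n_timepoints schedule length (stand-in schedule via
#'   [default_schedule()]).
#' @param phantom a [phantom_spec()].
#' @param grid a [grid_spec()].
#' @param b1_subset B1 values to build the dictionary at (thinned subset
#'   for desk-scale runs).
#' @param rank SVD compression rank; `0` matches against the full
#'   dictionary.
#' @param noise_sd_frac acquisition noise SD as a fraction of peak m0.
#' @param b1_amplitude amplitude of the synthetic B1 field.
#' @param t1_mask_ms low-T1 masking threshold.
#' @param session_days integer days on which test-retest pairs are
#'   simulated.
#' @param build_dictionary build the dictionary (`TRUE`) or load it from
#'   `dictionary_path` (`FALSE`).
#' @param dictionary_path container path (written when building, read
#'   otherwise).
#' @param n_epg_states EPG truncation order.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_timepoints = 1500,
                            phantom = phantom_spec(),
                            grid = grid_spec(),
                            b1_subset = c(0.9, 1.0, 1.1),
                            rank = 50L, noise_sd_frac = 0.02,
                            b1_amplitude = 0.08, t1_mask_ms = 400,
                            session_days = 1L,
                            build_dictionary = TRUE,
                            dictionary_path = NULL,
                            n_epg_states = 30L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  if (!build_dictionary) {
    if (is.null(dictionary_path) || !dir.exists(dictionary_path)) {
      stop("build_dictionary = FALSE requires an existing dictionary_path",
           call. = FALSE)
    }
  }
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "mrf_grid"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_timepoints = n_timepoints, phantom = phantom,
                 grid = grid, b1_subset = b1_subset, rank = rank,
                 noise_sd_frac = noise_sd_frac,
                 b1_amplitude = b1_amplitude, t1_mask_ms = t1_mask_ms,
                 session_days = as.integer(session_days),
                 build_dictionary = isTRUE(build_dictionary),
                 dictionary_path = dictionary_path,
                 n_epg_states = n_epg_states),
            class = "pipeline_config")
}

# Up to `n` background ROI centers whose full disc is background in every
# slice, found by scanning a coarse candidate grid of the label volume.
find_background_rois <- function(label, voxel_size_mm, n = 4,
                                 diameter_mm = 8) {
  d <- dim(label)
  bg <- apply(label == 0, c(1, 2), all)
  r <- diameter_mm / 2
  step <- max(2, floor(r))
  found <- list()
  for (x in seq(r + 1, d[1] * voxel_size_mm[1] - r - 1, by = step)) {
    for (y in seq(r + 1, d[2] * voxel_size_mm[2] - r - 1, by = step)) {
      roi <- roi_spec(c(x, y), slices = 1L, diameter_mm = diameter_mm)
      member <- roi_membership(d[1:2], voxel_size_mm, roi)
      if (!any(member)) next
      if (!all(bg[member])) next
      clash <- any(vapply(found, function(f) {
        sum((f - c(x, y))^2) < (2 * r)^2
      }, logical(1)))
      if (!clash) found[[length(found) + 1L]] <- c(x, y)
      if (length(found) >= n) return(found)
    }
  }
  found
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> build-dict -> match -> qa-report on the digital
#' phantom, writing the dictionary container, parameter-map directories
#' (test and retest per session), the measurement table, the QA report
#' (CSV and JSON), and a manifest with config hash, seeds, package
#' version and an MD5 checksum for every output file. Identical config
#' and seed give byte-identical CSV reports. A stage failure is recorded
#' in the manifest (with a `.partial` marker file) instead of discarding
#' prior outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(
    package = "mrfmap",
    version = as.character(utils::packageVersion("mrfmap")),
    seed = config$seed,
    config_hash = config_hash(config),
    session_seeds = list(), stages = list(), files = character())
  partial <- file.path(config$out_dir, ".partial")
  file.create(partial)
  add_stage <- function(name, status, error = NULL) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, status = status, error = error)
  }
  fail <- function(stage, e) {
    add_stage(stage, "error", conditionMessage(e))
    finish(ok = FALSE)
  }
  finish <- function(ok) {
    files <- setdiff(list.files(config$out_dir, recursive = TRUE,
                                full.names = TRUE),
                     c(file.path(config$out_dir, "manifest.json"), partial))
    manifest$files <<- lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (ok) unlink(partial)
    invisible(manifest)
  }

  params <- default_schedule(config$n_timepoints)
  write_schedule_csv(params, file.path(config$out_dir, "schedule.csv"))

  # stage 1: simulate
  say("stage simulate: phantom %d x %d x %d, %d session(s)",
      config$phantom$shape[1], config$phantom$shape[2],
      config$phantom$n_slices, length(config$session_days))
  sessions <- NULL
  truth <- NULL
  b1 <- NULL
  res <- tryCatch({
    truth <- generate_phantom_truth(config$phantom)
    shp <- dim(truth$t1_ms)
    b1 <- generate_b1_field(shp, config$b1_amplitude, seed = config$seed)
    sessions <- lapply(config$session_days, function(day) {
      seeds <- config$seed + c(1000L, 2000L) + 2L * day
      manifest$session_seeds[[as.character(day)]] <<- seeds
      generate_test_retest_pair(truth, b1, params,
                                acquisition_noise(config$noise_sd_frac),
                                seeds = seeds,
                                n_epg_states = config$n_epg_states)
    })
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("simulate", res))
  add_stage("simulate", "ok")

  # stage 2: dictionary
  dict_path <- config$dictionary_path %||%
    file.path(config$out_dir, "dictionary")
  res <- tryCatch({
    if (config$build_dictionary) {
      say("stage build-dict: B1 subset {%s}",
          paste(config$b1_subset, collapse = ", "))
      dict <- build_dictionary(config$grid, params,
                               b1_subset = config$b1_subset,
                               n_epg_states = config$n_epg_states)
      if (config$rank > 0) dict <- compress_dictionary(dict, config$rank)
      write_dictionary(dict, dict_path)
    } else {
      say("stage build-dict: loading %s", dict_path)
      dict <- read_dictionary(dict_path)
    }
    dict
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("build-dict", res))
  dict <- res
  add_stage("build-dict", "ok")

  # stage 3: match
  maps <- list()
  res <- tryCatch({
    for (i in seq_along(sessions)) {
      day <- config$session_days[i]
      for (rep_id in c("test", "retest")) {
        say("stage match: day %d %s", day, rep_id)
        pm <- match_image(sessions[[i]][[rep_id]], b1, dict,
                          voxel_size_mm = truth$voxel_size_mm)
        pm <- apply_t1_mask(pm, config$t1_mask_ms)
        write_parameter_map(
          pm, file.path(config$out_dir,
                        sprintf("maps_day%03d_%s", day, rep_id)))
        maps[[sprintf("%d_%s", day, rep_id)]] <- pm
      }
    }
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("match", res))
  add_stage("match", "ok")

  # stage 4: qa-report
  res <- tryCatch({
    say("stage qa-report")
    vials <- config$phantom$vials
    vial_slices <- seq_len(min(6L, config$phantom$n_slices))
    fbg_centers <- find_background_rois(truth$label, truth$voxel_size_mm)
    rows <- list()
    for (i in seq_along(sessions)) {
      day <- config$session_days[i]
      for (rep_id in c("test", "retest")) {
        pm <- maps[[sprintf("%d_%s", day, rep_id)]]
        for (v in seq_len(nrow(vials))) {
          roi <- roi_spec(c(vials$x_mm[v], vials$y_mm[v]),
                          slices = vial_slices)
          m1 <- tryCatch(extract_roi_mean(pm, roi, "t1_ms"),
                         error = function(e) NULL)
          if (is.null(m1)) next  # fully masked vial (fat): excluded
          m2 <- extract_roi_mean(pm, roi, "t2_ms")
          rows[[length(rows) + 1L]] <- data.frame(
            session_day = day, repeat_id = rep_id,
            unit = sprintf("%s_vial%d", vials$material[v], v),
            roi_mean_t1 = m1$mean, roi_mean_t2 = m2$mean,
            temperature_C = 20)
        }
        for (k in seq_along(fbg_centers)) {
          roi <- roi_spec(fbg_centers[[k]], slices = 1L)
          m1 <- extract_roi_mean(pm, roi, "t1_ms")
          m2 <- extract_roi_mean(pm, roi, "t2_ms")
          rows[[length(rows) + 1L]] <- data.frame(
            session_day = day, repeat_id = rep_id,
            unit = sprintf("FBG_roi%d", k),
            roi_mean_t1 = m1$mean, roi_mean_t2 = m2$mean,
            temperature_C = 20)
        }
      }
    }
    tab <- validate_measurement_table(do.call(rbind, rows))
    write_measurement_csv(tab, file.path(config$out_dir,
                                         "measurements.csv"))
    mats <- config$phantom$materials
    reference <- do.call(rbind, lapply(unique(tab$unit), function(u) {
      mat <- sub("_(vial|roi)[0-9]+$", "", u)
      hit <- mats[mats$material == mat, ]
      if (!nrow(hit)) return(NULL)
      data.frame(unit = u, t1_ms = hit$t1_ms, t2_ms = hit$t2_ms)
    }))
    report <- qa_report(tab, reference = reference)
    data.table::fwrite(report, file.path(config$out_dir, "qa_report.csv"))
    jsonlite::write_json(report, file.path(config$out_dir, "qa_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("qa-report", res))
  add_stage("qa-report", "ok")

  finish(ok = TRUE)
}

config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x) {
    if (is.numeric(x)) signif(x, 12) else x
  }, how = "replace")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
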