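#' Circular region of interest for phantom analysis
#'
#' Vial ROIs are central 8 mm circles evaluated over several slices;
#' background (FBG) ROIs use the same geometry in the single clear slice.
#' Pixel membership is by pixel center within the radius — unambiguous on
#' a 1 mm grid, no partial-area weighting.
#'
#' @param center_xy_mm ROI center `c(x, y)` in mm.
#' @param slices slice indices the ROI spans.
#' @param diameter_mm ROI diameter in mm, default 8.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(center_xy_mm, slices, diameter_mm = 8) {
  if (diameter_mm <= 0) stop("diameter must be > 0", call. = FALSE)
  stopifnot(length(center_xy_mm) == 2L, length(slices) >= 1L)
  structure(list(center_xy_mm = as.numeric(center_xy_mm),
                 slices = as.integer(slices),
                 diameter_mm = diameter_mm),
            class = "roi_spec")
}

# Logical in-plane membership matrix of an ROI on the map's pixel grid.
roi_membership <- function(shape_xy, voxel_size_mm, roi) {
  cx <- (seq_len(shape_xy[1]) - 0.5) * voxel_size_mm[1]
  cy <- (seq_len(shape_xy[2]) - 0.5) * voxel_size_mm[2]
  r2 <- (roi$diameter_mm / 2)^2
  outer(cx, cy, function(a, b) {
    (a - roi$center_xy_mm[1])^2 + (b - roi$center_xy_mm[2])^2
  }) <= r2
}

#' ROI mean of a parameter map metric
#'
#' Mean over the unmasked member voxels across the ROI's slices. A fully
#' masked ROI (e.g., a fat vial after T1 masking) raises an error so the
#' caller can drop the unit from analysis explicitly.
#'
#' @param pmap a [parameter_map()].
#' @param roi an [roi_spec()].
#' @param metric which volume to average: `"t1_ms"`, `"t2_ms"`,
#'   `"m0_magnitude"` or `"score"`.
#' @return List with `mean` and `n_voxels`.
#' @export
extract_roi_mean <- function(pmap, roi, metric = c("t1_ms", "t2_ms",
                                                   "m0_magnitude", "score")) {
  stopifnot(inherits(pmap, "parameter_map"), inherits(roi, "roi_spec"))
  metric <- match.arg(metric)
  d <- dim(pmap$t1_ms)
  if (any(roi$slices < 1L) || any(roi$slices > d[3])) {
    stop("ROI slices outside the volume", call. = FALSE)
  }
  member <- roi_membership(d[1:2], pmap$voxel_size_mm, roi)
  if (!any(member)) stop("ROI contains no pixels", call. = FALSE)
  vol <- pmap[[metric]]
  vals <- unlist(lapply(roi$slices, function(z) {
    v <- vol[, , z][member]
    v[pmap$mask[, , z][member]]
  }))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    stop("ROI is fully masked (zero unmasked member voxels)", call. = FALSE)
  }
  list(mean = mean(vals), n_voxels = length(vals))
}

#' Test-retest variation (mean absolute pairwise percent difference)
#'
#' `Var = (1/N) * sum(|test_i - retest_i| / ((test_i + retest_i)/2)) * 100`
#' over the N paired measurements — the repeatability metric for
#' back-to-back repeated acquisitions.
#'
#' @param test,retest positive paired measurement vectors.
#' @return Percent variation (scalar, in `[0, 200]`).
#' @examples
#' test_retest_variation(100, 110)  # 9.5238...
#' @export
test_retest_variation <- function(test, retest) {
  test <- as.numeric(test)
  retest <- as.numeric(retest)
  if (length(test) != length(retest) || length(test) < 1L) {
    stop("need N >= 1 pairs of equal length", call. = FALSE)
  }
  if (any(test <= 0) || any(retest <= 0)) {
    stop("all measurements must be positive", call. = FALSE)
  }
  mean(abs(test - retest) / ((test + retest) / 2)) * 100
}

#' Longitudinal coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the mean, in
#' percent, across repeated sessions.
#'
#' @param values numeric vector, `n >= 2`, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean must be nonzero", call. = FALSE)
  sd(values) / m * 100
}

#' Signed percent deviation from a reference value
#'
#' @param measured measured value(s).
#' @param reference positive reference value.
#' @return `(measured - reference) / reference * 100`.
#' @export
percent_deviation <- function(measured, reference) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    stop("reference must be > 0", call. = FALSE)
  }
  (measured - reference) / reference * 100
}

#' Bland-Altman agreement summary of paired measurements
#'
#' Per-pair signed percent difference relative to the pair mean, the mean
#' difference, and limits of agreement at mean +/- 1.96 sample SD (SD
#' computed on the percent differences).
#'
#' @param test,retest paired measurement vectors, `N >= 2`.
#' @return List with `diff_pct`, `mean_pair`, `mean_diff`, `sd_diff`,
#'   `limits` (length-2, lower/upper).
#' @export
bland_altman <- function(test, retest) {
  test <- as.numeric(test)
  retest <- as.numeric(retest)
  if (length(test) != length(retest) || length(test) < 2L) {
    stop("need N >= 2 pairs", call. = FALSE)
  }
  mp <- (test + retest) / 2
  d <- (test - retest) / mp * 100
  m <- mean(d)
  s <- sd(d)
  list(diff_pct = d, mean_pair = mp, mean_diff = m, sd_diff = s,
       limits = c(lower = m - 1.96 * s, upper = m + 1.96 * s))
}

#' Per-region summary of a parameter map
#'
#' Mean, sample SD and volume of each labeled region, counting only
#' unmasked voxels. Volume uses the map's voxel geometry (0.005 cm^3 per
#' voxel at 1 x 1 x 5 mm). Empty (fully masked) regions are reported as
#' missing, not dropped.
#'
#' @param pmap a [parameter_map()].
#' @param labels integer 3D array aligned with the map; 0 = background.
#' @param metric volume to summarize (as in [extract_roi_mean()]).
#' @return data.frame with columns `label`, `mean`, `sd`, `n_voxels`,
#'   `volume_cm3`.
#' @export
region_summary <- function(pmap, labels, metric = c("t1_ms", "t2_ms",
                                                    "m0_magnitude", "score")) {
  stopifnot(inherits(pmap, "parameter_map"))
  metric <- match.arg(metric)
  if (!identical(dim(labels), dim(pmap$t1_ms))) {
    stop("label volume shape does not match the map", call. = FALSE)
  }
  voxel_cm3 <- prod(pmap$voxel_size_mm) / 1000
  vol <- pmap[[metric]]
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    sel <- labels == id & pmap$mask & is.finite(vol)
    v <- vol[sel]
    if (!length(v)) {
      data.frame(label = id, mean = NA_real_, sd = NA_real_,
                 n_voxels = 0L, volume_cm3 = 0)
    } else {
      data.frame(label = id, mean = mean(v),
                 sd = if (length(v) > 1) sd(v) else 0,
                 n_voxels = length(v),
                 volume_cm3 = length(v) * voxel_cm3)
    }
  })
  do.call(rbind, rows)
}

#' Linear age trend of region means
#'
#' Ordinary least squares of region means against age, with the
#' coefficient of determination and the two-sided p-value for a nonzero
#' slope from the t statistic (df = n - 2).
#'
#' @param ages participant ages (not all equal), `n >= 3`.
#' @param region_means mean relaxation time per participant.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
age_trend <- function(ages, region_means) {
  ages <- as.numeric(ages)
  region_means <- as.numeric(region_means)
  n <- length(ages)
  if (n < 3L || length(region_means) != n) {
    stop("need n >= 3 paired observations", call. = FALSE)
  }
  if (var(ages) == 0) stop("ages must not all be equal", call. = FALSE)
  fit <- lm(region_means ~ ages)
  slope <- unname(coef(fit)[2])
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((region_means - mean(region_means))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  # slope SE and p computed directly (summary.lm warns on perfect fits)
  se <- sqrt(rss / (n - 2) / sum((ages - mean(ages))^2))
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  p <- if (is.finite(tval)) 2 * pt(-abs(tval), df = n - 2) else
    if (slope == 0) 1 else 0
  list(slope = slope, intercept = unname(coef(fit)[1]),
       r_squared = r2, p_value = unname(p))
}

#' Long-format measurement table for QA statistics
#'
#' One row per (session day, repeat, unit): the ROI mean T1 and T2 of one
#' material or region in one acquisition, with optional room temperature.
#'
#' @param session_day integer study day.
#' @param repeat_id `"test"` or `"retest"`.
#' @param unit material or region name.
#' @param roi_mean_t1,roi_mean_t2 ROI means (ms), finite.
#' @param temperature_C optional.
#' @return data.frame of class `measurement_table`.
#' @export
measurement_table <- function(session_day, repeat_id, unit,
                              roi_mean_t1, roi_mean_t2,
                              temperature_C = NA_real_) {
  tab <- data.frame(session_day = as.integer(session_day),
                    repeat_id = as.character(repeat_id),
                    unit = as.character(unit),
                    roi_mean_t1 = as.numeric(roi_mean_t1),
                    roi_mean_t2 = as.numeric(roi_mean_t2),
                    temperature_C = as.numeric(temperature_C),
                    stringsAsFactors = FALSE)
  validate_measurement_table(tab)
}

validate_measurement_table <- function(tab) {
  if (is.null(tab$temperature_C)) tab$temperature_C <- NA_real_
  tab$temperature_C <- as.numeric(tab$temperature_C)
  if (!all(tab$repeat_id %in% c("test", "retest"))) {
    stop("repeat_id must be 'test' or 'retest'", call. = FALSE)
  }
  if (anyDuplicated(tab[, c("session_day", "repeat_id", "unit")])) {
    stop("(session_day, repeat_id, unit) must be unique", call. = FALSE)
  }
  if (any(!is.finite(tab$roi_mean_t1)) || any(!is.finite(tab$roi_mean_t2))) {
    stop("ROI means must be finite", call. = FALSE)
  }
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

#' Full QA report over a measurement table
#'
#' For every unit and both metrics: test-retest variation over the paired
#' sessions, longitudinal CV over session-level values (each session
#' contributes the mean of its test and retest ROI means unless
#' `cv_pool_repeats = TRUE`, which pools every repeat as its own value),
#' Bland-Altman summaries, and — when a reference table is given — the
#' signed percent deviation of the grand mean from the reference.
#'
#' @param tab a [measurement_table()] (or plain data.frame with its
#'   columns).
#' @param reference optional data.frame with columns `unit`, `t1_ms`,
#'   `t2_ms` of reference values.
#' @param cv_pool_repeats compute CV across all repeats instead of
#'   session means.
#' @return data.frame with one row per (unit, metric): columns `unit`,
#'   `metric`, `n_sessions`, `test_retest_variation_pct`, `cv_pct`,
#'   `mean_value`, `deviation_pct`, `ba_mean_diff_pct`,
#'   `ba_lower_pct`, `ba_upper_pct`.
#' @export
qa_report <- function(tab, reference = NULL, cv_pool_repeats = FALSE) {
  tab <- validate_measurement_table(as.data.frame(tab))
  units <- unique(tab$unit)
  out <- list()
  for (u in units) {
    sub <- tab[tab$unit == u, ]
    for (metric in c("t1", "t2")) {
      col <- paste0("roi_mean_", metric)
      wide <- merge(
        sub[sub$repeat_id == "test", c("session_day", col)],
        sub[sub$repeat_id == "retest", c("session_day", col)],
        by = "session_day", suffixes = c("_test", "_retest"))
      tv <- cv <- dev <- bam <- bal <- bau <- NA_real_
      if (nrow(wide) >= 1) {
        tv <- test_retest_variation(wide[[paste0(col, "_test")]],
                                    wide[[paste0(col, "_retest")]])
      }
      vals <- if (cv_pool_repeats) sub[[col]] else {
        if (nrow(wide) >= 1) {
          rowMeans(wide[, c(paste0(col, "_test"), paste0(col, "_retest"))])
        } else {
          tapply(sub[[col]], sub$session_day, mean)
        }
      }
      if (length(vals) >= 2) cv <- coefficient_of_variation(vals)
      if (nrow(wide) >= 2) {
        ba <- bland_altman(wide[[paste0(col, "_test")]],
                           wide[[paste0(col, "_retest")]])
        bam <- ba$mean_diff
        bal <- ba$limits[["lower"]]
        bau <- ba$limits[["upper"]]
      }
      if (!is.null(reference) && u %in% reference$unit) {
        ref <- reference[reference$unit == u, paste0(metric, "_ms")]
        dev <- percent_deviation(mean(sub[[col]]), ref)
      }
      out[[length(out) + 1L]] <- data.frame(
        unit = u, metric = toupper(metric), n_sessions = nrow(wide),
        test_retest_variation_pct = tv, cv_pct = cv,
        mean_value = mean(sub[[col]]), deviation_pct = dev,
        ba_mean_diff_pct = bam, ba_lower_pct = bal, ba_upper_pct = bau,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read / write a measurement table as CSV
#'
#' @param tab a [measurement_table()].
#' @param path CSV path.
#' @return `read_measurement_csv` returns a validated
#'   `measurement_table`.
#' @export
write_measurement_csv <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path)
  invisible(path)
}

#' @rdname write_measurement_csv
#' @export
read_measurement_csv <- function(path) {
  validate_measurement_table(as.data.frame(data.table::fread(path)))
}
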