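#' Voxelwise parameter map container
#'
#' Holds the matched T1/T2/M0/score volumes with a boolean reporting mask.
#' Geometry is the acquisition default: 1 x 1 mm in plane, 5 mm slices.
#'
#' @param t1_ms,t2_ms,m0_magnitude,score numeric 3D arrays of equal shape.
#' @param mask logical array of the same shape; `TRUE` marks reported
#'   voxels. Masked-out voxels keep their values in memory but are written
#'   to disk as NaN.
#' @param voxel_size_mm voxel edge lengths in mm, default `c(1, 1, 5)`.
#' @param b1_used optional array of the dictionary B1 value used per voxel.
#' @param m0_complex optional complex array (programmatic access to the
#'   complex scale; the map itself reports magnitude).
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(t1_ms, t2_ms, m0_magnitude, score, mask,
                          voxel_size_mm = c(1, 1, 5), b1_used = NULL,
                          m0_complex = NULL) {
  dims <- dim(t1_ms)
  if (is.null(dims) || length(dims) != 3L) {
    stop("parameter map volumes must be 3D arrays", call. = FALSE)
  }
  vols <- list(t1_ms = t1_ms, t2_ms = t2_ms, m0_magnitude = m0_magnitude,
               score = score, mask = mask)
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]), dims)) {
      stop("all parameter map volumes must share one shape", call. = FALSE)
    }
  }
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, m0_magnitude = m0_magnitude,
                 score = score, mask = mask,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 b1_used = b1_used, m0_complex = m0_complex),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$t1_ms)
  cat(sprintf("Parameter map %d x %d x %d (%g x %g x %g mm voxels)\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3]))
  cat(sprintf("  reported voxels: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

# Snap measured B1 values onto the dictionary's B1 axis.
# Values outside [0.6, 1.4] are clamped (with one warning); exact midpoints
# go to the lower grid value.
snap_b1 <- function(b1_measured, b1_values) {
  out_of_range <- b1_measured < 0.6 | b1_measured > 1.4
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d B1 value(s) outside [0.6, 1.4] clamped",
                    sum(out_of_range, na.rm = TRUE)), call. = FALSE)
    b1_measured <- pmin(pmax(b1_measured, 0.6), 1.4)
  }
  # nearest grid value; on ties (exact midpoint) the lower value wins
  idx <- findInterval(b1_measured, b1_values)
  idx[idx < 1L] <- 1L
  hi <- pmin(idx + 1L, length(b1_values))
  d_lo <- b1_measured - b1_values[idx]
  d_hi <- b1_values[hi] - b1_measured
  ifelse(d_hi < d_lo - 1e-12, hi, idx)
}

dict_is_compressed <- function(dict) inherits(dict, "mrf_compressed_dictionary")

# Row indices of all entries at the given B1 value (entries are B1-major,
# so the result is a contiguous block).
dict_b1_block <- function(dict, b1_value) {
  which(abs(dict$entries$b1_rel - b1_value) < 1e-9)
}

#' Match one pixel's signal evolution against the dictionary
#'
#' The measured per-pixel B1 fixes the B1 plane of the dictionary (snapped
#' to the nearest grid value, lower value on ties); within that plane the
#' entry maximizing the magnitude inner product `|<atom, signal>|` with
#' the L2-normalized signal is returned. Since atoms are unit norm, the
#' complex scale `m0 = <atom, signal_unnormalized>`. Ties break
#' deterministically to the lowest T1, then lowest T2.
#'
#' @param signal complex (or numeric) signal vector of length
#'   `n_timepoints`; must have positive norm.
#' @param b1_measured relative B1 at the pixel.
#' @param dict an `mrf_dictionary` or `mrf_compressed_dictionary`.
#' @return A list of class `mrf_match` with `t1_ms`, `t2_ms`, `b1_used`,
#'   `m0` (complex), `score` (normalized inner-product magnitude in
#'   `[0, 1]`).
#' @export
match_pixel <- function(signal, b1_measured, dict) {
  signal <- as.complex(signal)
  nrm <- sqrt(sum(Mod(signal)^2))
  if (!is.finite(nrm) || nrm <= 0) {
    stop("no-match: signal has zero norm", call. = FALSE)
  }
  if (nrow(dict$entries) < 1L) stop("dictionary is empty", call. = FALSE)
  b1_idx <- snap_b1(b1_measured, dict$b1_values)
  b1_used <- dict$b1_values[b1_idx]
  rows <- dict_b1_block(dict, b1_used)
  if (dict_is_compressed(dict)) {
    s <- project_signals(dict, matrix(signal, ncol = 1L))
    scores <- ip_mag_cpp(dict$coords[rows, , drop = FALSE], s)
    best <- which.max(scores)
    m0 <- sum(Conj(dict$coords[rows[best], ]) * s[, 1])
  } else {
    scores <- ip_mag_cpp(dict$atoms[rows, , drop = FALSE],
                         matrix(signal, ncol = 1L))
    best <- which.max(scores)
    m0 <- sum(Conj(dict$atoms[rows[best], ]) * signal)
  }
  structure(list(t1_ms = dict$entries$t1_ms[rows[best]],
                 t2_ms = dict$entries$t2_ms[rows[best]],
                 b1_used = b1_used, m0 = m0,
                 score = as.numeric(scores[best]) / nrm),
            class = "mrf_match")
}

#' Match a 4D image series into a parameter map
#'
#' Vectorized [match_pixel()]: voxels are grouped by their snapped B1
#' grid value and each group is scored against the corresponding
#' dictionary block with one dense product (chunked to bound memory).
#' Voxels with zero signal norm are masked rather than raising.
#'
#' @param series complex 4D array `x` by `y` by `slices` by `time`.
#' @param b1_map numeric 3D array of measured relative B1, spatially
#'   aligned with `series`.
#' @param dict an `mrf_dictionary` or `mrf_compressed_dictionary`.
#' @param voxel_size_mm voxel geometry recorded in the map.
#' @param chunk_size voxels scored per dense product.
#' @param verbose log per-slice progress via `message()`.
#' @return A [parameter_map()].
#' @export
match_image <- function(series, b1_map, dict, voxel_size_mm = c(1, 1, 5),
                        chunk_size = 2048L, verbose = FALSE) {
  d <- dim(series)
  if (length(d) != 4L) stop("series must be a 4D array", call. = FALSE)
  if (!identical(dim(b1_map), d[1:3])) {
    stop("b1_map shape does not match the series", call. = FALSE)
  }
  n_t <- d[4]
  if (dict_is_compressed(dict)) {
    if (nrow(dict$basis) != n_t) {
      stop("series time axis does not match the dictionary", call. = FALSE)
    }
  } else if (ncol(dict$atoms) != n_t) {
    stop("series time axis does not match the dictionary", call. = FALSE)
  }
  n_vox <- prod(d[1:3])
  sig <- matrix(as.complex(series), nrow = n_vox, ncol = n_t)
  norms <- sqrt(rowSums(Mod(sig)^2))
  ok <- is.finite(norms) & norms > 0

  t1 <- rep(NA_real_, n_vox)
  t2 <- rep(NA_real_, n_vox)
  m0c <- rep(NA_complex_, n_vox)
  score <- rep(NA_real_, n_vox)
  b1u <- rep(NA_real_, n_vox)

  b1_idx <- snap_b1(as.vector(b1_map), dict$b1_values)
  compressed <- dict_is_compressed(dict)

  for (gi in sort(unique(b1_idx[ok]))) {
    vox <- which(ok & b1_idx == gi)
    b1_val <- dict$b1_values[gi]
    rows <- dict_b1_block(dict, b1_val)
    block <- if (compressed) dict$coords[rows, , drop = FALSE]
             else dict$atoms[rows, , drop = FALSE]
    if (verbose) {
      message(sprintf("matching %d voxels at B1 = %.2f (%d entries)",
                      length(vox), b1_val, length(rows)))
    }
    for (start in seq(1L, length(vox), by = chunk_size)) {
      vv <- vox[start:min(start + chunk_size - 1L, length(vox))]
      s <- t(sig[vv, , drop = FALSE])          # time x voxel
      if (compressed) s <- project_signals(dict, s)
      sc <- ip_mag_cpp(block, s)               # entries x voxel
      best <- max.col(t(sc), ties.method = "first")
      pick <- rows[best]
      t1[vv] <- dict$entries$t1_ms[pick]
      t2[vv] <- dict$entries$t2_ms[pick]
      score[vv] <- sc[cbind(best, seq_along(vv))] / norms[vv]
      b1u[vv] <- b1_val
      ref <- if (compressed) dict$coords[pick, , drop = FALSE]
             else dict$atoms[pick, , drop = FALSE]
      m0c[vv] <- rowSums(Conj(ref) * t(s))
    }
  }

  shape3 <- d[1:3]
  parameter_map(
    t1_ms = array(t1, shape3), t2_ms = array(t2, shape3),
    m0_magnitude = array(Mod(m0c), shape3),
    score = array(score, shape3),
    mask = array(ok, shape3),
    voxel_size_mm = voxel_size_mm,
    b1_used = array(b1u, shape3),
    m0_complex = array(m0c, shape3))
}

#' Mask voxels with short T1
#'
#' The B1 mapping that feeds matching is unreliable below 400 ms T1, so
#' voxels with `t1_ms < threshold_ms` are removed from the reporting mask
#' (fat-like species in practice). Returns a new map; the input is not
#' modified.
#'
#' @param pmap a [parameter_map()].
#' @param threshold_ms masking threshold in ms, default 400.
#' @return A new `parameter_map` with the tightened mask.
#' @export
apply_t1_mask <- function(pmap, threshold_ms = 400) {
  stopifnot(inherits(pmap, "parameter_map"))
  if (!is.numeric(threshold_ms) || threshold_ms < 0) {
    stop("threshold_ms must be non-negative", call. = FALSE)
  }
  mask <- pmap$mask & !(is.finite(pmap$t1_ms) & pmap$t1_ms < threshold_ms)
  out <- pmap
  out$mask <- mask
  out
}
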