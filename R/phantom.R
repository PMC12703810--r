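#' Default material table for the digital vial phantom
#'
#' T1/T2 values for the PVP dilution series and the fibroglandular (FBG)
#' background are NMR reference values; the fat-mimic values are *not*
#' reference values — they are configurable defaults chosen only to fall
#' below the 400 ms masking threshold, since the real fat vials are masked
#' and never reported.
#'
#' @return data.frame with columns `material`, `t1_ms`, `t2_ms`, `m0`.
#' @export
material_table <- function() {
  data.frame(
    material = c("PVP0", "PVP10", "PVP25", "PVP40", "FBG", "fat"),
    t1_ms = c(2872, 2151, 1304, 656, 1321, 300),
    t2_ms = c(1217, 1245, 962, 472, 41, 60),
    m0 = 1,
    stringsAsFactors = FALSE)
}

# Default schematic vial layout (mm, within a 128 mm square FOV): one
# 0% PVP vial, two each of the other PVP dilutions, four fat mimics.
# The commercial phantom's true coordinates are not published; the layout
# is schematic and fully configurable.
default_vials <- function() {
  data.frame(
    material = c("PVP0", "PVP10", "PVP10", "PVP25", "PVP25",
                 "PVP40", "PVP40", "fat", "fat", "fat", "fat"),
    x_mm = c(64, 34, 94, 34, 94, 34, 94, 16, 112, 16, 112),
    y_mm = c(64, 34, 34, 64, 64, 94, 94, 64, 64, 104, 104),
    diameter_mm = 16,
    stringsAsFactors = FALSE)
}

#' Digital vial-phantom specification
#'
#' Describes a grid of cylindrical vials (16 mm diameter by default)
#' embedded in a background fill material, imaged at 1 x 1 x 5 mm voxels.
#'
#' @param shape in-plane matrix size `c(nx, ny)` (1 mm pixels).
#' @param n_slices number of 5 mm slices, default 7.
#' @param vials data.frame with columns `material`, `x_mm`, `y_mm`,
#'   `diameter_mm`; vials must not overlap and must fit in the FOV.
#' @param background background material name, default `"FBG"`.
#' @param materials material lookup table, see [material_table()].
#' @param voxel_size_mm voxel geometry, default `c(1, 1, 5)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128), n_slices = 7,
                         vials = default_vials(), background = "FBG",
                         materials = material_table(),
                         voxel_size_mm = c(1, 1, 5)) {
  stopifnot(length(shape) == 2L, all(shape >= 1), n_slices >= 1)
  if (nrow(vials) > 0) {
    need <- c("material", "x_mm", "y_mm", "diameter_mm")
    if (!all(need %in% names(vials))) {
      stop("vials needs columns material, x_mm, y_mm, diameter_mm",
           call. = FALSE)
    }
    unknown <- setdiff(c(vials$material, background), materials$material)
    if (length(unknown)) {
      stop("unknown material(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    r <- vials$diameter_mm / 2
    if (any(vials$x_mm - r < 0) || any(vials$x_mm + r > shape[1]) ||
        any(vials$y_mm - r < 0) || any(vials$y_mm + r > shape[2])) {
      stop("all vials must lie inside the field of view", call. = FALSE)
    }
    if (nrow(vials) > 1) {
      dd <- as.matrix(stats::dist(vials[, c("x_mm", "y_mm")]))
      lim <- outer(r, r, "+")
      diag(dd) <- Inf
      if (any(dd < lim - 1e-9)) {
        stop("vials overlap", call. = FALSE)
      }
    }
  }
  structure(list(shape = as.integer(shape), n_slices = as.integer(n_slices),
                 vials = vials, background = background,
                 materials = materials, voxel_size_mm = voxel_size_mm),
            class = "phantom_spec")
}

#' Rasterize the phantom ground truth
#'
#' Voxel membership is by voxel center: pixel `(i, j)` has center
#' `(i - 0.5, j - 0.5)` mm and belongs to the vial whose center lies
#' within its radius; all other voxels take the background material.
#' There is no partial-volume mixing. Vials extend through all slices.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `mrf_truth`: 3D arrays `t1_ms`, `t2_ms`, `m0`,
#'   integer `label` (0 = background, i = row of `spec$vials`), plus
#'   `voxel_size_mm` and the `spec`.
#' @export
generate_phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$n_slices
  cx <- seq_len(nx) - 0.5
  cy <- seq_len(ny) - 0.5
  mat <- spec$materials
  bg <- mat[mat$material == spec$background, ]
  slice_label <- matrix(0L, nx, ny)
  for (v in seq_len(nrow(spec$vials))) {
    vx <- spec$vials$x_mm[v]; vy <- spec$vials$y_mm[v]
    r2 <- (spec$vials$diameter_mm[v] / 2)^2
    inside <- outer(cx, cy, function(a, b) (a - vx)^2 + (b - vy)^2) <= r2
    slice_label[inside] <- v
  }
  vial_mat <- match(spec$vials$material, mat$material)
  # lookup by label + 1 (entry 1 = background)
  t1_lut <- c(bg$t1_ms, mat$t1_ms[vial_mat])
  t2_lut <- c(bg$t2_ms, mat$t2_ms[vial_mat])
  m0_lut <- c(bg$m0, mat$m0[vial_mat])
  t1_slice <- matrix(t1_lut[slice_label + 1L], nx, ny)
  t2_slice <- matrix(t2_lut[slice_label + 1L], nx, ny)
  m0_slice <- matrix(m0_lut[slice_label + 1L], nx, ny)
  rep3 <- function(m) array(rep(m, nz), dim = c(nx, ny, nz))
  structure(list(t1_ms = rep3(t1_slice), t2_ms = rep3(t2_slice),
                 m0 = rep3(m0_slice), label = rep3(slice_label),
                 voxel_size_mm = spec$voxel_size_mm, spec = spec),
            class = "mrf_truth")
}

#' Brain-like region specification
#'
#' Region T1/T2 defaults are population means for CSF (lateral
#' ventricles), cortical GM and cerebral WM at 3 T; target volumes here
#' are desk-scale stand-ins, not anatomical volumes.
#'
#' @param regions data.frame with columns `label` (unique positive
#'   integers), `name`, `volume_cm3` (> 0), `t1_ms`, `t2_ms`.
#' @param shape volume shape `c(nx, ny, n_slices)` at 1 x 1 x 5 mm voxels.
#' @param voxel_size_mm voxel geometry.
#' @return An object of class `brain_spec`.
#' @export
brain_spec <- function(regions = data.frame(
                         label = 1:3,
                         name = c("CSF", "GM", "WM"),
                         volume_cm3 = c(2, 6, 8),
                         t1_ms = c(3383, 1516, 1046),
                         t2_ms = c(453, 68, 46),
                         stringsAsFactors = FALSE),
                       shape = c(48, 48, 6),
                       voxel_size_mm = c(1, 1, 5)) {
  stopifnot(all(c("label", "name", "volume_cm3", "t1_ms", "t2_ms") %in%
                  names(regions)))
  if (anyDuplicated(regions$label) || any(regions$label <= 0)) {
    stop("region labels must be unique positive integers", call. = FALSE)
  }
  if (any(regions$volume_cm3 <= 0)) {
    stop("region volumes must be > 0", call. = FALSE)
  }
  voxel_cm3 <- prod(voxel_size_mm) / 1000
  need <- sum(round(regions$volume_cm3 / voxel_cm3))
  if (need > prod(shape)) {
    stop("total region volume does not fit the volume shape", call. = FALSE)
  }
  structure(list(regions = regions, shape = as.integer(shape),
                 voxel_size_mm = voxel_size_mm),
            class = "brain_spec")
}

#' Rasterize a brain-like ground truth of compact regions
#'
#' Each region is grown as the set of `n` free voxels nearest (in mm, so
#' ellipsoidal in voxel units) to a randomly placed center, giving compact
#' non-overlapping blobs whose voxel counts match the target volumes
#' exactly at the 5 mm^3 voxel granularity. Background voxels carry zero
#' proton density.
#'
#' @param spec a [brain_spec()].
#' @param seed integer RNG seed; identical seeds give identical volumes.
#' @param max_tries placement retries per region before failing.
#' @return An `mrf_truth` list (see [generate_phantom_truth()]); `label`
#'   holds the region labels.
#' @export
generate_brain_truth <- function(spec, seed = 1L, max_tries = 200L) {
  stopifnot(inherits(spec, "brain_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  vs <- spec$voxel_size_mm
  voxel_cm3 <- prod(vs) / 1000
  coords <- cbind(
    (rep(seq_len(nx), times = ny * nz) - 0.5) * vs[1],
    (rep(rep(seq_len(ny), each = nx), times = nz) - 0.5) * vs[2],
    (rep(seq_len(nz), each = nx * ny) - 0.5) * vs[3])
  label <- integer(nx * ny * nz)
  regions <- spec$regions[order(-spec$regions$volume_cm3), ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(regions))) {
    n_vox <- round(regions$volume_cm3[i] / voxel_cm3)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      center <- c(runif(1, 0, nx * vs[1]), runif(1, 0, ny * vs[2]),
                  runif(1, 0, nz * vs[3]))
      free <- which(label == 0L)
      if (length(free) < n_vox) break
      d2 <- (coords[free, 1] - center[1])^2 +
        (coords[free, 2] - center[2])^2 +
        (coords[free, 3] - center[3])^2
      pick <- free[order(d2)[seq_len(n_vox)]]
      # require the grown blob to be reasonably compact: its radius must
      # not exceed twice the equivalent-sphere radius (rejects centers
      # whose neighborhoods are fragmented by earlier regions)
      r_eq <- (3 * n_vox * prod(vs) / (4 * pi))^(1 / 3)
      if (sqrt(max(d2[order(d2)[seq_len(n_vox)]])) <= 2.5 * r_eq + max(vs)) {
        label[pick] <- regions$label[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place region '%s' (infeasible packing)",
                   regions$name[i]), call. = FALSE)
    }
  }
  idx <- match(label, spec$regions$label)
  t1 <- ifelse(is.na(idx), 0, spec$regions$t1_ms[idx])
  t2 <- ifelse(is.na(idx), 0, spec$regions$t2_ms[idx])
  m0 <- ifelse(is.na(idx), 0, 1)
  shp <- c(nx, ny, nz)
  structure(list(t1_ms = array(t1, shp), t2_ms = array(t2, shp),
                 m0 = array(m0, shp), label = array(label, shp),
                 voxel_size_mm = vs, spec = spec),
            class = "mrf_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Smooth relative-B1 transmit field
#'
#' Low-order (quadratic) polynomial field centered near 1.0 with seeded
#' random coefficients, scaled so the largest deviation from 1.0 equals
#' `amplitude`, then clipped to the physical range `[0.6, 1.4]`.
#'
#' @param shape volume shape `c(nx, ny, n_slices)`.
#' @param amplitude maximum deviation from 1.0 (must keep the field inside
#'   `[0.6, 1.4]`, i.e. `amplitude <= 0.4`); `0` gives a uniform field.
#' @param seed integer RNG seed.
#' @return 3D numeric array of relative B1 values.
#' @export
generate_b1_field <- function(shape, amplitude = 0.2, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (amplitude < 0 || amplitude > 0.4) {
    stop("amplitude must lie in [0, 0.4]", call. = FALSE)
  }
  if (amplitude == 0) return(array(1, dim = shape))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cf <- runif(6, -1, 1)
  u <- if (shape[1] > 1) seq(-1, 1, length.out = shape[1]) else 0
  v <- if (shape[2] > 1) seq(-1, 1, length.out = shape[2]) else 0
  w <- if (shape[3] > 1) seq(-1, 1, length.out = shape[3]) else 0
  g <- expand.grid(u = u, v = v, w = w)
  dev <- cf[1] * g$u + cf[2] * g$v + cf[3] * g$u^2 + cf[4] * g$v^2 +
    cf[5] * g$u * g$v + cf[6] * g$w
  m <- max(abs(dev))
  if (m > 0) dev <- dev / m * amplitude
  array(pmin(pmax(1 + dev, 0.6), 1.4), dim = shape)
}

#' Acquisition noise model
#'
#' Independent complex Gaussian noise added per voxel and time point in
#' image space (the spiral/coil reconstruction chain is out of the model).
#' The standard deviation is expressed as a fraction of the maximum proton
#' density in the truth volume.
#'
#' @param sd_frac per-channel noise SD as a fraction of peak `m0`.
#' @param seed integer RNG seed.
#' @return An object of class `acquisition_noise`.
#' @export
acquisition_noise <- function(sd_frac = 0.02, seed = 1L) {
  if (!is.numeric(sd_frac) || sd_frac < 0) {
    stop("sd_frac must be >= 0", call. = FALSE)
  }
  structure(list(sd_frac = sd_frac, seed = as.integer(seed)),
            class = "acquisition_noise")
}

# Noiseless forward model: EPG per voxel with its own (T1, T2, B1, m0).
# Voxels with m0 == 0 or non-positive relaxation times contribute zero
# signal. Returns a 4D complex array.
simulate_clean_series <- function(truth, b1, params, n_epg_states = 30L) {
  shp <- dim(truth$t1_ms)
  if (!identical(dim(b1), shp)) {
    stop("B1 volume shape does not match the truth", call. = FALSE)
  }
  n_t <- params$n_timepoints
  out <- array(complex(real = 0, imaginary = 0), dim = c(shp, n_t))
  live <- which(truth$m0 > 0)
  if (length(live)) {
    sig <- simulate_signal_batch(
      params, truth$t1_ms[live], truth$t2_ms[live], b1[live],
      truth$m0[live], n_epg_states = n_epg_states)
    flat <- matrix(out, nrow = prod(shp), ncol = n_t)
    flat[live, ] <- sig
    out <- array(flat, dim = c(shp, n_t))
  }
  out
}

#' Simulate a noisy MRF acquisition of a ground-truth volume
#'
#' Per voxel, the EPG signal at the voxel's `(T1, T2, B1, m0)` plus
#' i.i.d. complex Gaussian noise (see [acquisition_noise()]). Fully
#' reproducible given the noise seed.
#'
#' @param truth an `mrf_truth` list (see [generate_phantom_truth()]).
#' @param b1 3D array of relative B1, aligned with the truth.
#' @param params an [mrf_schedule()].
#' @param noise an [acquisition_noise()]; `NULL` for noiseless.
#' @param n_epg_states EPG truncation order.
#' @return Complex 4D array `x` by `y` by `slices` by `time`.
#' @export
simulate_acquisition <- function(truth, b1, params, noise = NULL,
                                 n_epg_states = 30L) {
  series <- simulate_clean_series(truth, b1, params, n_epg_states)
  if (!is.null(noise)) {
    series <- add_acquisition_noise(series, noise, m0_scale = max(truth$m0))
  }
  series
}

#' Add seeded complex Gaussian noise to a simulated series
#'
#' @param series complex 4D array.
#' @param noise an [acquisition_noise()].
#' @param m0_scale proton-density scale the SD fraction refers to.
#' @return The noisy series (same shape).
#' @export
add_acquisition_noise <- function(series, noise, m0_scale = 1) {
  stopifnot(inherits(noise, "acquisition_noise"))
  if (noise$sd_frac == 0) return(series)
  sdv <- noise$sd_frac * m0_scale
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  n <- length(series)
  series + array(complex(real = rnorm(n, sd = sdv),
                         imaginary = rnorm(n, sd = sdv)),
                 dim = dim(series))
}

#' Simulate a back-to-back test-retest pair
#'
#' Identical ground truth and B1 field, two independent noise
#' realizations — the synthetic analogue of repeating the acquisition
#' without moving the phantom.
#'
#' @inheritParams simulate_acquisition
#' @param noise an [acquisition_noise()]; its `seed` field is ignored in
#'   favor of `seeds`.
#' @param seeds pair of distinct integer seeds, one per repeat.
#' @return List with complex 4D arrays `test` and `retest`.
#' @export
generate_test_retest_pair <- function(truth, b1, params, noise,
                                      seeds = c(1L, 2L),
                                      n_epg_states = 30L) {
  stopifnot(length(seeds) == 2L)
  if (seeds[1] == seeds[2] && noise$sd_frac > 0) {
    warning("equal seeds produce a fully correlated test-retest pair",
            call. = FALSE)
  }
  clean <- simulate_clean_series(truth, b1, params, n_epg_states)
  m0s <- max(truth$m0)
  list(
    test = add_acquisition_noise(
      clean, acquisition_noise(noise$sd_frac, seeds[1]), m0s),
    retest = add_acquisition_noise(
      clean, acquisition_noise(noise$sd_frac, seeds[2]), m0s))
}
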