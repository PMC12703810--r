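#' Multi-resolution (T1, T2, B1) dictionary grid
#'
#' The grid uses coarser steps at longer relaxation times, mirroring how
#' the biological dynamic range is sampled in clinical fingerprinting
#' dictionaries: T1 from 10 to 4500 ms (steps 10/20/40/100 ms), T2 from 2
#' to 3000 ms (steps 2/5/10/50/100/200 ms), and a relative B1 axis from
#' 0.6 to 1.4 in steps of 0.01. Segment boundaries shared by two segments
#' appear exactly once on the axis.
#'
#' @param t1_segments,t2_segments list of `c(lo, hi, step)` triples in ms;
#'   segments must be sorted with non-overlapping interiors.
#' @param b1_values sorted ascending vector of relative B1 values within
#'   `[0.6, 1.4]`.
#' @param exclude_t2_gt_t1 drop combinations with T2 > T1? Default `FALSE`
#'   (fluid-like entries need T2 of the same order as T1).
#' @return An object of class `mrf_grid`.
#' @export
grid_spec <- function(t1_segments = list(c(10, 100, 10), c(100, 1000, 20),
                                         c(1000, 2000, 40), c(2000, 4500, 100)),
                      t2_segments = list(c(2, 100, 2), c(100, 150, 5),
                                         c(150, 300, 10), c(300, 800, 50),
                                         c(800, 1600, 100), c(1600, 3000, 200)),
                      b1_values = seq(0.6, 1.4, by = 0.01),
                      exclude_t2_gt_t1 = FALSE) {
  validate_segments(t1_segments, "t1_segments")
  validate_segments(t2_segments, "t2_segments")
  b1_values <- as.numeric(b1_values)
  if (is.unsorted(b1_values, strictly = TRUE) ||
      any(b1_values < 0.6 - 1e-9) || any(b1_values > 1.4 + 1e-9)) {
    stop("b1_values must be strictly increasing within [0.6, 1.4]",
         call. = FALSE)
  }
  structure(list(t1_segments = t1_segments, t2_segments = t2_segments,
                 b1_values = b1_values,
                 exclude_t2_gt_t1 = isTRUE(exclude_t2_gt_t1)),
            class = "mrf_grid")
}

validate_segments <- function(segments, what = "segments") {
  if (!is.list(segments) || length(segments) < 1L) {
    stop(what, " must be a non-empty list of c(lo, hi, step)", call. = FALSE)
  }
  m <- do.call(rbind, lapply(segments, as.numeric))
  if (ncol(m) != 3L) stop(what, " entries must be c(lo, hi, step)", call. = FALSE)
  if (any(m[, 1] >= m[, 2])) stop(what, ": each lo must be < hi", call. = FALSE)
  if (any(m[, 3] <= 0)) stop(what, ": each step must be > 0", call. = FALSE)
  if (is.unsorted(m[, 1])) stop(what, " must be sorted by lo", call. = FALSE)
  if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2] - 1e-9)) {
    stop(what, ": segment interiors overlap", call. = FALSE)
  }
  invisible(m)
}

#' Enumerate a multi-segment axis
#'
#' Returns the union over segments of `{lo, lo + step, ..., hi}`, with
#' boundary values shared by adjacent segments kept exactly once.
#'
#' @param segments list of `c(lo, hi, step)` triples.
#' @return Strictly increasing numeric vector.
#' @examples
#' build_axis(list(c(0, 10, 5)))  # 0 5 10
#' @export
build_axis <- function(segments) {
  validate_segments(segments)
  vals <- unlist(lapply(segments, function(s) {
    v <- seq(s[1], s[2] + s[3] * 1e-9, by = s[3])
    v[v <= s[2] + 1e-9]
  }))
  vals <- sort(vals)
  # drop duplicated shared boundaries
  vals[c(TRUE, diff(vals) > 1e-9)]
}

#' Build an MRF dictionary of simulated, normalized signal atoms
#'
#' Simulates one EPG signal evolution per `(T1, T2, B1)` grid combination
#' and L2-normalizes it, producing the atom matrix used for inner-product
#' matching. Entries are ordered B1-major, then T1, then T2 ascending;
#' this ordering is what makes argmax tie-breaking deterministic (lowest
#' T1, then lowest T2 wins).
#'
#' @param grid a [grid_spec()].
#' @param params an [mrf_schedule()].
#' @param b1_subset optional vector of B1 values to build instead of the
#'   full grid axis (all must lie within the grid's B1 range). A thinned
#'   subset keeps desk-scale builds tractable.
#' @param n_epg_states EPG truncation order passed to the simulator.
#' @return An object of class `mrf_dictionary` with fields `entries`
#'   (data.frame `t1_ms`, `t2_ms`, `b1_rel`), `atoms` (complex matrix,
#'   one unit-norm row per entry), `params`, `grid`, `b1_values`.
#' @export
build_dictionary <- function(grid, params, b1_subset = NULL,
                             n_epg_states = 30L) {
  stopifnot(inherits(grid, "mrf_grid"), inherits(params, "mrf_schedule"))
  t1_axis <- build_axis(grid$t1_segments)
  t2_axis <- build_axis(grid$t2_segments)
  b1s <- if (is.null(b1_subset)) grid$b1_values else sort(as.numeric(b1_subset))
  if (any(b1s < min(grid$b1_values) - 1e-9) ||
      any(b1s > max(grid$b1_values) + 1e-9)) {
    stop("b1_subset values must lie within the grid's B1 range",
         call. = FALSE)
  }
  base <- expand.grid(t2_ms = t2_axis, t1_ms = t1_axis,
                      KEEP.OUT.ATTRS = FALSE)  # t2 fastest, t1 next
  if (grid$exclude_t2_gt_t1) base <- base[base$t2_ms <= base$t1_ms, ]
  entries <- do.call(rbind, lapply(b1s, function(b) {
    data.frame(t1_ms = base$t1_ms, t2_ms = base$t2_ms, b1_rel = b)
  }))
  rownames(entries) <- NULL
  atoms <- simulate_signal_batch(params, entries$t1_ms, entries$t2_ms,
                                 entries$b1_rel, m0 = 1,
                                 n_epg_states = n_epg_states)
  norms <- row_norms_cpp(atoms)
  bad <- which(norms <= 0)
  if (length(bad)) {
    stop(sprintf(
      "atom with zero norm at entry %d (T1=%g, T2=%g, B1=%g): degenerate schedule",
      bad[1], entries$t1_ms[bad[1]], entries$t2_ms[bad[1]],
      entries$b1_rel[bad[1]]), call. = FALSE)
  }
  atoms <- row_scale_cpp(atoms, norms)
  structure(list(entries = entries, atoms = atoms, params = params,
                 grid = grid, b1_values = b1s),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d entries x %d time points\n",
              nrow(x$entries), ncol(x$atoms)))
  cat(sprintf("  T1 [%g, %g] ms, T2 [%g, %g] ms, B1 {%s}\n",
              min(x$entries$t1_ms), max(x$entries$t1_ms),
              min(x$entries$t2_ms), max(x$entries$t2_ms),
              paste(format(x$b1_values, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' SVD temporal compression of a dictionary
#'
#' Projects atoms onto the top `rank` right singular vectors of the atom
#' matrix (its principal temporal components), shrinking each evolution
#' from `n_timepoints` samples to `rank` coordinates while preserving the
#' inner products that drive matching.
#'
#' Conjugation convention: with atoms as rows of `A` and the basis `V`
#' (columns = right singular vectors of `A = U S V^H`), the stored
#' coordinates are `C = A Conj(V)`, so that the matching inner product
#' `<a, s> = sum(Conj(a) * s)` is computed in compressed space as
#' `Conj(C) (V^H s)` — identical to the full-space product up to
#' truncation error.
#'
#' @param dict an `mrf_dictionary`.
#' @param rank number of temporal components retained (default 50).
#' @return An object of class `mrf_compressed_dictionary` with fields
#'   `basis` (`n_timepoints x rank`, orthonormal columns), `coords`
#'   (`n_entries x rank`), `singular_values` (all, descending), plus the
#'   parent `entries`, `params`, `grid`, `b1_values`.
#' @export
compress_dictionary <- function(dict, rank = 50L) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  n_entries <- nrow(dict$entries)
  n_t <- ncol(dict$atoms)
  max_rank <- min(n_entries, n_t)
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1 || rank > max_rank) {
    stop(sprintf("rank must lie in [1, %d]", max_rank), call. = FALSE)
  }
  sv <- gram_basis_cpp(dict$atoms, as.integer(rank))
  coords <- cx_mm_cpp(dict$atoms, Conj(sv$basis))
  structure(list(entries = dict$entries, rank = as.integer(rank),
                 basis = sv$basis, coords = coords,
                 singular_values = sv$singular_values,
                 params = dict$params, grid = dict$grid,
                 b1_values = dict$b1_values),
            class = "mrf_compressed_dictionary")
}

#' @export
print.mrf_compressed_dictionary <- function(x, ...) {
  energy <- sum(x$singular_values[seq_len(x$rank)]^2) /
    sum(x$singular_values^2)
  cat(sprintf(
    "Compressed MRF dictionary: %d entries, rank %d (%.4f%% energy)\n",
    nrow(x$entries), x$rank, 100 * energy))
  invisible(x)
}

#' Project signals onto a compressed dictionary's temporal basis
#'
#' @param cdict an `mrf_compressed_dictionary`.
#' @param signals complex vector (one signal) or matrix with signals in
#'   columns (`n_timepoints x n_signals`).
#' @return Matrix of compressed coordinates (`rank x n_signals`).
#' @export
project_signals <- function(cdict, signals) {
  stopifnot(inherits(cdict, "mrf_compressed_dictionary"))
  if (is.null(dim(signals))) signals <- matrix(signals, ncol = 1L)
  if (nrow(signals) != nrow(cdict$basis)) {
    stop("signal length does not match the dictionary's time axis",
         call. = FALSE)
  }
  cx_ctmm_cpp(cdict$basis, signals)  # V^H S
}

#' Save / load a dictionary as a plain-text container
#'
#' The dictionary is persisted as a directory holding `meta.json` (format
#' version, grid, B1 values, schedule), `entries.csv`, and the atom matrix
#' split into `atoms_re.csv` / `atoms_im.csv` (and `basis_*`/`coords_*`
#' for compressed dictionaries). Plain text keeps the container portable
#' and byte-deterministic; it is intended for modest dictionaries, not
#' full clinical grids.
#'
#' @param dict an `mrf_dictionary` or `mrf_compressed_dictionary`.
#' @param path directory to create/overwrite.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns the restored object.
#' @export
write_dictionary <- function(dict, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  compressed <- inherits(dict, "mrf_compressed_dictionary")
  if (!compressed) stopifnot(inherits(dict, "mrf_dictionary"))
  meta <- list(
    format = "mrfmap-dictionary", version = "1",
    compressed = compressed,
    rank = if (compressed) dict$rank else NULL,
    b1_values = dict$b1_values,
    grid = list(t1_segments = dict$grid$t1_segments,
                t2_segments = dict$grid$t2_segments,
                b1_values = dict$grid$b1_values,
                exclude_t2_gt_t1 = dict$grid$exclude_t2_gt_t1),
    schedule = list(tr_ms = dict$params$tr_ms, fa_deg = dict$params$fa_deg,
                    ti_ms = dict$params$ti_ms, te_ms = dict$params$te_ms,
                    rf_phase_deg = dict$params$rf_phase_deg,
                    inv_eff = dict$params$inv_eff))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  data.table::fwrite(dict$entries, file.path(path, "entries.csv"))
  write_cx_matrix <- function(m, stem) {
    data.table::fwrite(as.data.table_matrix(Re(m)),
                       file.path(path, paste0(stem, "_re.csv")))
    data.table::fwrite(as.data.table_matrix(Im(m)),
                       file.path(path, paste0(stem, "_im.csv")))
  }
  if (compressed) {
    write_cx_matrix(dict$basis, "basis")
    write_cx_matrix(dict$coords, "coords")
    data.table::fwrite(data.frame(singular_value = dict$singular_values),
                       file.path(path, "singular_values.csv"))
  } else {
    write_cx_matrix(dict$atoms, "atoms")
  }
  invisible(path)
}

as.data.table_matrix <- function(m) {
  data.table::as.data.table(m)
}

read_cx_matrix <- function(path, stem) {
  re <- as.matrix(data.table::fread(file.path(path, paste0(stem, "_re.csv"))))
  im <- as.matrix(data.table::fread(file.path(path, paste0(stem, "_im.csv"))))
  matrix(complex(real = re, imaginary = im), nrow = nrow(re))
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "mrfmap-dictionary")) {
    stop("not an mrfmap dictionary container", call. = FALSE)
  }
  grid <- grid_spec(
    t1_segments = lapply(seq_len(nrow(meta$grid$t1_segments)),
                         function(i) meta$grid$t1_segments[i, ]),
    t2_segments = lapply(seq_len(nrow(meta$grid$t2_segments)),
                         function(i) meta$grid$t2_segments[i, ]),
    b1_values = meta$grid$b1_values,
    exclude_t2_gt_t1 = meta$grid$exclude_t2_gt_t1)
  params <- mrf_schedule(tr_ms = meta$schedule$tr_ms,
                         fa_deg = meta$schedule$fa_deg,
                         ti_ms = meta$schedule$ti_ms,
                         te_ms = meta$schedule$te_ms,
                         rf_phase_deg = meta$schedule$rf_phase_deg,
                         inv_eff = meta$schedule$inv_eff)
  entries <- as.data.frame(data.table::fread(file.path(path, "entries.csv")))
  if (isTRUE(meta$compressed)) {
    structure(list(entries = entries, rank = as.integer(meta$rank),
                   basis = read_cx_matrix(path, "basis"),
                   coords = read_cx_matrix(path, "coords"),
                   singular_values = data.table::fread(
                     file.path(path, "singular_values.csv"))$singular_value,
                   params = params, grid = grid,
                   b1_values = as.numeric(meta$b1_values)),
              class = "mrf_compressed_dictionary")
  } else {
    structure(list(entries = entries,
                   atoms = read_cx_matrix(path, "atoms"),
                   params = params, grid = grid,
                   b1_values = as.numeric(meta$b1_values)),
              class = "mrf_dictionary")
  }
}
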