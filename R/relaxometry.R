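#' Logarithmically spaced sampling times
#'
#' Geometric progression with exact endpoints, as used for
#' inversion-recovery TI schedules and spin-echo TE schedules in NMR
#' reference relaxometry.
#'
#' @param lo,hi positive endpoints, `lo < hi`.
#' @param n number of points, at least 2.
#' @return Numeric vector of length `n` with `out[1] == lo`,
#'   `out[n] == hi` and a constant ratio between neighbors.
#' @examples
#' log_spaced(1, 100, 3)  # 1 10 100
#' @export
log_spaced <- function(lo, hi, n) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo) {
    stop("need 0 < lo < hi", call. = FALSE)
  }
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  out <- exp(seq(log(lo), log(hi), length.out = n))
  out[1] <- lo
  out[n] <- hi
  out
}

#' Inversion-recovery sample
#'
#' @param ti_ms strictly increasing positive inversion times (ms);
#'   default: 20 log-spaced values from 50 to 15000 ms (the default span
#'   covers recovery of the slowest phantom material; the reference
#'   protocol specifies the count, not the range).
#' @param signal real (signed) signal values, one per TI.
#' @return Object of class `ir_sample`.
#' @export
ir_sample <- function(signal, ti_ms = log_spaced(50, 15000, 20)) {
  ti_ms <- as.numeric(ti_ms)
  signal <- as.numeric(signal)
  if (length(ti_ms) != length(signal)) {
    stop("ti_ms and signal must have equal length", call. = FALSE)
  }
  if (any(ti_ms <= 0) || is.unsorted(ti_ms, strictly = TRUE)) {
    stop("TIs must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(ti_ms = ti_ms, signal = signal), class = "ir_sample")
}

#' Single-echo spin-echo sample
#'
#' @param te_ms strictly increasing echo times (ms); default: 51
#'   log-spaced values from 2.026 to 2502 ms.
#' @param signal positive echo amplitudes, one per TE.
#' @return Object of class `se_sample`.
#' @export
se_sample <- function(signal, te_ms = log_spaced(2.026, 2502, 51)) {
  te_ms <- as.numeric(te_ms)
  signal <- as.numeric(signal)
  if (length(te_ms) != length(signal)) {
    stop("te_ms and signal must have equal length", call. = FALSE)
  }
  if (is.unsorted(te_ms, strictly = TRUE)) {
    stop("TEs must be strictly increasing", call. = FALSE)
  }
  structure(list(te_ms = te_ms, signal = signal), class = "se_sample")
}

fit_result <- function(estimate, amplitude, residual_norm, converged,
                       what) {
  structure(list(estimate = estimate, amplitude = amplitude,
                 residual_norm = residual_norm, converged = converged,
                 what = what),
            class = "relaxometry_fit")
}

#' @export
print.relaxometry_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("%s fit: %.4g ms (residual norm %.3g)\n", x$what,
                x$estimate, x$residual_norm))
  } else {
    cat(sprintf("%s fit: FAILED\n", x$what))
  }
  invisible(x)
}

#' Inversion-recovery T1 fit
#'
#' Nonlinear least squares for the three-parameter model
#' `S(TI) = a + b * exp(-TI / T1)` on signed signal (after inversion
#' `b < 0`, `a` is the recovered equilibrium). Initialization comes from a
#' log-linearized fit of `|S - a0|` against TI using the plateau value at
#' the longest TI as `a0`. A magnitude mode restores the sign lost in
#' magnitude data by flipping all points before the minimum.
#'
#' @param sample an [ir_sample()].
#' @param magnitude set `TRUE` if the signal is magnitude data (sign
#'   restored at the zero crossing before fitting).
#' @return A `relaxometry_fit` with `estimate` (T1, ms), `amplitude`
#'   (`c(a, b)`), `residual_norm`, `converged`.
#' @export
fit_ir_t1 <- function(sample, magnitude = FALSE) {
  stopifnot(inherits(sample, "ir_sample"))
  ti <- sample$ti_ms
  s <- sample$signal
  if (length(ti) < 4 || max(ti) / min(ti) < 10) {
    stop("need >= 4 points spanning at least a decade of TI", call. = FALSE)
  }
  if (magnitude) {
    # sign lost to the magnitude operation: the points before the zero
    # crossing recover their negative sign; whether the minimum itself
    # sits before or after the crossing is ambiguous, so both splits are
    # fitted and the lower-residual fit wins
    s_abs <- abs(s)
    i0 <- which.min(s_abs)
    fits <- lapply(unique(pmax(c(i0 - 1L, i0), 0L)), function(cut) {
      cand <- s_abs
      if (cut >= 1L) cand[1:cut] <- -cand[1:cut]
      fit_ir_t1(structure(list(ti_ms = ti, signal = cand),
                          class = "ir_sample"))
    })
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!any(ok)) return(fits[[1]])
    fits <- fits[ok]
    return(fits[[which.min(vapply(fits, `[[`, 0, "residual_norm"))]])
  }
  fail <- function() fit_result(NA_real_, c(a = NA_real_, b = NA_real_),
                                NA_real_, FALSE, "IR T1")
  a0 <- s[length(s)]
  r <- s - a0
  use <- abs(r) > max(abs(r)) * 1e-3
  if (sum(use) < 3 || max(abs(r)) == 0) return(fail())
  lf <- lm(log(abs(r[use])) ~ ti[use])
  slope <- coef(lf)[2]
  if (!is.finite(slope) || slope >= 0) return(fail())
  t1_0 <- unname(-1 / slope)
  b0 <- unname(sign(r[1]) * exp(coef(lf)[1]))
  fit <- tryCatch(
    nls(s ~ a + b * exp(-ti / t1),
        start = list(a = a0, b = b0, t1 = t1_0),
        # scaleOffset makes the convergence test well defined on
        # zero-residual (noiseless) data
        control = stats::nls.control(maxiter = 200, tol = 1e-8, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  est <- coef(fit)
  if (!is.finite(est[["t1"]]) || est[["t1"]] <= 0) return(fail())
  fit_result(unname(est[["t1"]]), c(a = unname(est[["a"]]),
                                    b = unname(est[["b"]])),
             sqrt(sum(stats::resid(fit)^2)), TRUE, "IR T1")
}

#' Spin-echo T2 fit
#'
#' Nonlinear least squares for the mono-exponential decay
#' `S(TE) = A * exp(-TE / T2)` (two parameters; no constant offset unless
#' `offset = TRUE`), initialized from a log-linear regression.
#'
#' @param sample an [se_sample()].
#' @param offset include a constant offset term `c` in the model.
#' @return A `relaxometry_fit` with `estimate` (T2, ms).
#' @export
fit_se_t2 <- function(sample, offset = FALSE) {
  stopifnot(inherits(sample, "se_sample"))
  te <- sample$te_ms
  s <- sample$signal
  if (length(te) < 3) stop("need >= 3 points", call. = FALSE)
  if (any(s <= 0) && !offset) {
    stop("spin-echo amplitudes must be positive", call. = FALSE)
  }
  fail <- function() fit_result(NA_real_, c(A = NA_real_), NA_real_,
                                FALSE, "SE T2")
  pos <- s > 0
  if (sum(pos) < 3) return(fail())
  lf <- lm(log(s[pos]) ~ te[pos])
  slope <- coef(lf)[2]
  if (!is.finite(slope) || slope >= 0) return(fail())
  t2_0 <- unname(-1 / slope)
  a_0 <- unname(exp(coef(lf)[1]))
  fit <- tryCatch(
    if (offset) {
      nls(s ~ A * exp(-te / t2) + cc,
          start = list(A = a_0, t2 = t2_0, cc = 0),
          control = stats::nls.control(maxiter = 200, tol = 1e-8, scaleOffset = 1))
    } else {
      nls(s ~ A * exp(-te / t2),
          start = list(A = a_0, t2 = t2_0),
          control = stats::nls.control(maxiter = 200, tol = 1e-8, scaleOffset = 1))
    },
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  est <- coef(fit)
  if (!is.finite(est[["t2"]]) || est[["t2"]] <= 0) return(fail())
  amp <- c(A = unname(est[["A"]]))
  if (offset) amp <- c(amp, c = unname(est[["cc"]]))
  fit_result(unname(est[["t2"]]), amp, sqrt(sum(stats::resid(fit)^2)),
             TRUE, "SE T2")
}

#' Read a relaxometry sample from CSV / write a fit as JSON
#'
#' The CSV needs columns `ti_ms,signal` (inversion recovery) or
#' `te_ms,signal` (spin echo); the column present decides the sample type.
#'
#' @param path CSV file path.
#' @return [ir_sample()] or [se_sample()].
#' @export
read_relaxometry_csv <- function(path) {
  tab <- data.table::fread(path)
  if ("ti_ms" %in% names(tab)) {
    ir_sample(tab$signal, ti_ms = tab$ti_ms)
  } else if ("te_ms" %in% names(tab)) {
    se_sample(tab$signal, te_ms = tab$te_ms)
  } else {
    stop("CSV must have a ti_ms or te_ms column plus signal", call. = FALSE)
  }
}

#' @rdname read_relaxometry_csv
#' @param fit a `relaxometry_fit`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "relaxometry_fit"))
  jsonlite::write_json(
    list(what = fit$what, estimate_ms = fit$estimate,
         amplitude = as.list(fit$amplitude),
         residual_norm = fit$residual_norm, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
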