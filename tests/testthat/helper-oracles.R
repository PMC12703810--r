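# Independent oracles and shared small fixtures.
#
# The isochromat simulator and the brute-force matcher are deliberately
# written in plain R against the same physical event sequence as the
# package's compiled EPG path, but via a different formalism (explicit
# Bloch rotation of N uniformly dephased spins; naive exhaustive argmax),
# so agreement is a genuine cross-check, not a tautology.

# Isochromat Bloch-summation oracle: N spins spread uniformly over 2 pi of
# gradient dephasing per TR. RF phase 0 (rotation about x with
# My' = cos(a) My - sin(a) Mz, matching the F = Mx + i My convention).
oracle_iso_sim <- function(params, t1, t2, b1 = 1, m0 = 1,
                           n_spins = 1000, inv_eff = 1) {
  n <- params$n_timepoints
  psi <- 2 * pi * (seq_len(n_spins) - 1) / n_spins
  cp <- cos(psi)
  sp <- sin(psi)
  Mx <- rep(0, n_spins)
  My <- rep(0, n_spins)
  Mz <- rep(-inv_eff, n_spins)
  e1 <- exp(-params$ti_ms / t1)
  Mz <- Mz * e1 + (1 - e1)
  sig <- complex(length.out = n)
  e1te <- exp(-params$te_ms / t1)
  e2te <- exp(-params$te_ms / t2)
  for (i in seq_len(n)) {
    a <- b1 * params$fa_deg[i] * pi / 180
    My2 <- cos(a) * My - sin(a) * Mz
    Mz <- sin(a) * My + cos(a) * Mz
    My <- My2
    Mx <- Mx * e2te
    My <- My * e2te
    Mz <- Mz * e1te + (1 - e1te)
    sig[i] <- mean(complex(real = Mx, imaginary = My))
    rem <- params$tr_ms[i] - params$te_ms
    e1r <- exp(-rem / t1)
    e2r <- exp(-rem / t2)
    Mx <- Mx * e2r
    My <- My * e2r
    Mz <- Mz * e1r + (1 - e1r)
    Mx2 <- cp * Mx - sp * My
    My <- sp * Mx + cp * My
    Mx <- Mx2
  }
  m0 * sig
}

rel_rms <- function(a, b) {
  sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))
}

# Exhaustive brute-force matcher over the B1 plane nearest b1_measured
# (lower plane on exact midpoints). Returns the winning entry row index.
oracle_brute_match <- function(dict, signal, b1_measured) {
  b1g <- dict$b1_values
  bm <- min(max(b1_measured, 0.6), 1.4)
  b1v <- b1g[which.min(abs(b1g - bm))]  # first minimum = lower on ties
  rows <- which(abs(dict$entries$b1_rel - b1v) < 1e-12)
  sc <- vapply(rows, function(r) {
    Mod(sum(Conj(dict$atoms[r, ]) * signal))
  }, numeric(1))
  rows[which.max(sc)]
}

# Per-segment enumeration + set union (the axis-construction oracle).
oracle_axis <- function(segments) {
  vals <- c()
  for (s in segments) {
    k <- 0:floor((s[2] - s[1]) / s[3] + 1e-9)
    vals <- union(vals, s[1] + k * s[3])
  }
  sort(vals)
}

small_sched <- function(n = 300) default_schedule(n)

small_grid <- function() {
  grid_spec(t1_segments = list(c(200, 1000, 200), c(1000, 2000, 500)),
            t2_segments = list(c(20, 100, 40), c(100, 300, 100)),
            b1_values = c(0.8, 1.0, 1.2))
}

# Memoized small dictionary shared across test files in one run.
.fixtures <- new.env(parent = emptyenv())

get_small_dict <- function() {
  if (is.null(.fixtures$dict)) {
    .fixtures$dict <- build_dictionary(small_grid(), small_sched())
  }
  .fixtures$dict
}

get_small_cdict <- function(rank = 30L) {
  key <- paste0("cdict", rank)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- compress_dictionary(get_small_dict(), rank)
  }
  .fixtures[[key]]
}

# Two-vial mini phantom (one PVP40 vial, one fat mimic) used across the
# matching/pipeline tests.
mini_phantom_spec <- function(n_slices = 2) {
  phantom_spec(shape = c(40, 40), n_slices = n_slices,
               vials = data.frame(material = c("PVP40", "fat"),
                                  x_mm = c(12, 28), y_mm = c(20, 20),
                                  diameter_mm = 12))
}
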