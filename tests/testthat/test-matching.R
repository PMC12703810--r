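test_that("a dictionary atom matches itself exactly", {
  d <- get_small_dict()
  i <- which(d$entries$t1_ms == 1000 & d$entries$t2_ms == 100 &
               d$entries$b1_rel == 1.0)
  m <- match_pixel(d$atoms[i, ] * 2.5, 1.0, d)
  expect_equal(m$t1_ms, 1000)
  expect_equal(m$t2_ms, 100)
  expect_equal(m$b1_used, 1.0)
  expect_equal(m$score, 1, tolerance = 1e-9)
  expect_equal(Mod(m$m0), 2.5, tolerance = 1e-9)
})

test_that("matching equals exhaustive brute force on random noiseless atoms", {
  d <- get_small_dict()
  set.seed(21)
  idx <- sample(nrow(d$entries), 60)
  for (i in idx) {
    s <- d$atoms[i, ]
    m <- match_pixel(s, d$entries$b1_rel[i], d)
    o <- oracle_brute_match(d, s, d$entries$b1_rel[i])
    expect_equal(c(m$t1_ms, m$t2_ms, m$b1_used),
                 unlist(d$entries[o, ], use.names = FALSE))
    expect_identical(o, i)
  }
})

test_that("off-grid signals agree with the brute-force oracle", {
  d <- get_small_dict()
  p <- small_sched(300)
  set.seed(31)
  for (k in 1:20) {
    t1 <- runif(1, 250, 1900)
    t2 <- runif(1, 25, min(280, t1))
    s <- simulate_signal(p, tissue_params(t1, t2))
    m <- match_pixel(s, 1.0, d)
    o <- oracle_brute_match(d, s, 1.0)
    expect_equal(m$t1_ms, d$entries$t1_ms[o])
    expect_equal(m$t2_ms, d$entries$t2_ms[o])
  }
})

test_that("zero-norm signals raise a no-match error", {
  d <- get_small_dict()
  expect_error(match_pixel(rep(0 + 0i, 300), 1.0, d), "zero norm")
})

test_that("B1 snapping picks the nearest plane, lower on midpoints", {
  d <- get_small_dict()  # B1 planes at 0.8, 1.0, 1.2
  s <- d$atoms[1, ]
  expect_equal(match_pixel(s, 0.85, d)$b1_used, 0.8)
  expect_equal(match_pixel(s, 0.95, d)$b1_used, 1.0)
  expect_equal(match_pixel(s, 0.9, d)$b1_used, 0.8)   # exact midpoint
  expect_equal(match_pixel(s, 1.1, d)$b1_used, 1.0)   # exact midpoint
  # piecewise-constant selection (tie tolerance mirrors the documented
  # midpoint rule: within 1e-12 of equidistant counts as a tie -> lower)
  planes <- c(0.8, 1.0, 1.2)
  for (b in seq(0.8, 1.2, by = 0.01)) {
    used <- match_pixel(s, b, d)$b1_used
    d_all <- abs(planes - b)
    o <- order(d_all)
    want <- if (d_all[o[2]] - d_all[o[1]] <= 1e-12) {
      min(planes[o[1:2]])
    } else {
      planes[o[1]]
    }
    expect_equal(used, want)
  }
  expect_warning(m <- match_pixel(s, 1.7, d), "clamped")
  expect_equal(m$b1_used, 1.2)
})

test_that("matching survives 2% complex Gaussian noise on on-grid signals", {
  d <- get_small_dict()
  set.seed(41)
  n_trials <- 500
  idx <- sample(nrow(d$entries), n_trials, replace = TRUE)
  hits <- 0
  for (i in idx) {
    s <- d$atoms[i, ]
    pk <- max(Mod(s))
    s <- s + complex(real = rnorm(length(s), sd = 0.02 * pk),
                     imaginary = rnorm(length(s), sd = 0.02 * pk))
    m <- match_pixel(s, d$entries$b1_rel[i], d)
    hits <- hits + (m$t1_ms == d$entries$t1_ms[i] &&
                      m$t2_ms == d$entries$t2_ms[i])
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("match_image assembles per-voxel matches and masks zero voxels", {
  d <- get_small_dict()
  idx <- c(5, 40, 72, 103)  # spread across the three B1 planes
  n_t <- ncol(d$atoms)
  series <- array(0 + 0i, dim = c(2, 2, 1, n_t))
  for (k in 1:4) {
    series[(k - 1) %% 2 + 1, (k - 1) %/% 2 + 1, 1, ] <- d$atoms[idx[k], ]
  }
  b1 <- array(d$entries$b1_rel[idx], dim = c(2, 2, 1))
  pm <- match_image(series, b1, d)
  expect_s3_class(pm, "parameter_map")
  expect_equal(as.vector(pm$t1_ms), d$entries$t1_ms[idx])
  expect_equal(as.vector(pm$t2_ms), d$entries$t2_ms[idx])
  expect_true(all(pm$mask))
  expect_equal(as.vector(pm$score), rep(1, 4), tolerance = 1e-9)

  # an all-zero voxel is masked, others unaffected
  series[2, 2, 1, ] <- 0 + 0i
  pm2 <- match_image(series, b1, d)
  expect_false(pm2$mask[2, 2, 1])
  expect_true(all(pm2$mask[cbind(c(1, 2, 1), c(1, 1, 2), 1)]))
  expect_equal(pm2$t1_ms[1, 1, 1], d$entries$t1_ms[idx[1]])

  expect_error(match_image(series, array(1, c(3, 3, 1)), d), "shape")
})

test_that("compressed and full matching give identical maps on clean data", {
  d <- get_small_dict()
  cd <- get_small_cdict(30)
  p <- small_sched(300)
  set.seed(51)
  shape <- c(3, 3, 1)
  t1 <- array(runif(9, 300, 1800), shape)
  t2 <- array(runif(9, 30, 250), shape)
  series <- array(0 + 0i, dim = c(shape, 300))
  for (i in 1:3) for (j in 1:3) {
    series[i, j, 1, ] <- simulate_signal(p, tissue_params(t1[i, j, 1],
                                                          t2[i, j, 1]))
  }
  b1 <- array(1.0, shape)
  pm_full <- match_image(series, b1, d)
  pm_comp <- match_image(series, b1, cd)
  expect_equal(pm_comp$t1_ms, pm_full$t1_ms)
  expect_equal(pm_comp$t2_ms, pm_full$t2_ms)
})

test_that("low-T1 masking is correct, monotone, and non-mutating", {
  shape <- c(4, 4, 2)
  t1 <- array(rep(c(300, 656, 1046, 2872), 8), shape)
  base <- parameter_map(t1_ms = t1, t2_ms = t1 * 0 + 50,
                        m0_magnitude = t1 * 0 + 1, score = t1 * 0 + 1,
                        mask = array(TRUE, shape))
  m400 <- apply_t1_mask(base, 400)
  expect_equal(!m400$mask, t1 < 400)
  expect_true(all(base$mask))  # input untouched
  # threshold 0 changes nothing (T1 > 0 invariant)
  expect_equal(apply_t1_mask(base, 0)$mask, base$mask)
  # map with min T1 = 656: mask unchanged at 400
  t1b <- array(rep(c(656, 1304, 2151, 2872), 8), shape)
  base_b <- parameter_map(t1_ms = t1b, t2_ms = t1b * 0 + 50,
                          m0_magnitude = t1b * 0 + 1, score = t1b * 0 + 1,
                          mask = array(TRUE, shape))
  expect_equal(apply_t1_mask(base_b, 400)$mask, base_b$mask)
  # monotone: reported set shrinks as the threshold grows
  thresholds <- c(0, 400, 700, 1100, 3000)
  reported <- lapply(thresholds, function(th) {
    which(apply_t1_mask(base, th)$mask)
  })
  for (k in seq_len(length(thresholds) - 1)) {
    expect_true(all(reported[[k + 1]] %in% reported[[k]]))
  }
  expect_error(apply_t1_mask(base, -1), "non-negative")
})

test_that("parameter map construction validates shapes", {
  expect_error(parameter_map(t1_ms = matrix(1, 2, 2),
                             t2_ms = matrix(1, 2, 2),
                             m0_magnitude = matrix(1, 2, 2),
                             score = matrix(1, 2, 2),
                             mask = matrix(TRUE, 2, 2)), "3D")
  a <- array(1, c(2, 2, 1))
  expect_error(parameter_map(a, a, a, array(1, c(2, 2, 2)),
                             array(TRUE, c(2, 2, 1))), "share")
})
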