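test_that("phantom truth assigns Table-style material values by vial", {
  tr <- generate_phantom_truth(phantom_spec())
  mats <- material_table()
  vials <- default_vials()
  expect_equal(dim(tr$t1_ms), c(128, 128, 7))
  for (v in seq_len(nrow(vials))) {
    sel <- tr$label == v
    expect_gt(sum(sel), 0)
    mat <- mats[mats$material == vials$material[v], ]
    expect_true(all(tr$t1_ms[sel] == mat$t1_ms))
    expect_true(all(tr$t2_ms[sel] == mat$t2_ms))
  }
  # 40% PVP vials carry exactly (656, 472)
  pvp40 <- which(vials$material == "PVP40")
  sel <- tr$label %in% pvp40
  expect_true(all(tr$t1_ms[sel] == 656 & tr$t2_ms[sel] == 472))
  # background is FBG
  bg <- tr$label == 0
  expect_true(all(tr$t1_ms[bg] == 1321 & tr$t2_ms[bg] == 41))
  # exactly four vials with T1 < 400 (the fat mimics)
  short <- vapply(seq_len(nrow(vials)), function(v) {
    any(tr$t1_ms[tr$label == v] < 400)
  }, logical(1))
  expect_equal(sum(short), 4L)
})

test_that("zero vials gives a uniform background volume", {
  spec <- phantom_spec(shape = c(10, 10), n_slices = 2,
                       vials = default_vials()[0, ])
  tr <- generate_phantom_truth(spec)
  expect_true(all(tr$label == 0))
  expect_true(all(tr$t1_ms == 1321))
})

test_that("overlapping or out-of-bounds vials are rejected", {
  expect_error(phantom_spec(shape = c(40, 40), vials = data.frame(
    material = c("PVP0", "PVP10"), x_mm = c(20, 28), y_mm = c(20, 20),
    diameter_mm = 16)), "overlap")
  expect_error(phantom_spec(shape = c(40, 40), vials = data.frame(
    material = "PVP0", x_mm = 5, y_mm = 20, diameter_mm = 16)),
    "field of view")
  expect_error(phantom_spec(vials = data.frame(
    material = "butter", x_mm = 64, y_mm = 64, diameter_mm = 16)),
    "unknown material")
})

test_that("vial geometry is invariant to noise settings", {
  spec <- mini_phantom_spec()
  tr <- generate_phantom_truth(spec)
  counts <- table(tr$label)
  tr2 <- generate_phantom_truth(spec)  # regenerate: label geometry fixed
  expect_identical(table(tr2$label), counts)
})

test_that("brain truth hits target volumes at 5 mm^3 voxel granularity", {
  spec <- brain_spec(regions = data.frame(
    label = 1:3, name = c("CSF", "GM", "WM"),
    volume_cm3 = c(0.5, 1, 2), t1_ms = c(3383, 1516, 1046),
    t2_ms = c(453, 68, 46)), shape = c(30, 30, 5))
  tr <- generate_brain_truth(spec, seed = 7)
  # 1 cm^3 = 200 voxels of 5 mm^3
  expect_equal(sum(tr$label == 2), 200L)
  expect_equal(sum(tr$label == 1), 100L)
  expect_equal(sum(tr$label == 3), 400L)
  # WM voxels carry the WM means
  expect_true(all(tr$t1_ms[tr$label == 3] == 1046))
  expect_true(all(tr$t2_ms[tr$label == 3] == 46))
  # background has zero proton density
  expect_true(all(tr$m0[tr$label == 0] == 0))
  # determinism
  tr2 <- generate_brain_truth(spec, seed = 7)
  expect_identical(tr2$label, tr$label)
  expect_false(identical(generate_brain_truth(spec, seed = 8)$label,
                         tr$label))
})

test_that("infeasible packing errors out", {
  # a needle-shaped volume: 750 of 800 voxels can never form a compact
  # blob, so every placement fails the compactness check
  spec <- brain_spec(regions = data.frame(
    label = 1, name = "WM", volume_cm3 = 3.75, t1_ms = 1046, t2_ms = 46),
    shape = c(4, 4, 50))
  expect_error(generate_brain_truth(spec, seed = 1, max_tries = 25),
               "packing|fit")
})

test_that("B1 fields are smooth, bounded, and seeded", {
  shape <- c(24, 24, 3)
  expect_equal(generate_b1_field(shape, 0), array(1, shape))
  f <- generate_b1_field(shape, 0.3, seed = 3)
  expect_true(all(f >= 0.6 & f <= 1.4))
  expect_equal(max(abs(f - 1)), 0.3, tolerance = 1e-12)
  expect_identical(generate_b1_field(shape, 0.3, seed = 3), f)
  expect_false(identical(generate_b1_field(shape, 0.3, seed = 4), f))
  expect_error(generate_b1_field(shape, 0.5), "amplitude")
})

test_that("noiseless acquisition equals the per-voxel signal model", {
  spec <- mini_phantom_spec(n_slices = 1)
  tr <- generate_phantom_truth(spec)
  p <- small_sched(60)
  b1 <- generate_b1_field(dim(tr$t1_ms), 0.1, seed = 2)
  ser <- simulate_acquisition(tr, b1, p)
  i <- which(tr$label == 1)[1]
  ij <- arrayInd(i, dim(tr$t1_ms))
  s <- simulate_signal(p, tissue_params(656, 472, b1_rel = b1[i]))
  expect_equal(as.vector(ser[ij[1], ij[2], ij[3], ]), s, tolerance = 1e-12)
})

test_that("empirical noise SD matches the model on pure-noise voxels", {
  # 10^4 background voxels with m0 = 0: the series is pure noise
  shape <- c(100, 100, 1)
  truth <- list(t1_ms = array(1000, shape), t2_ms = array(100, shape),
                m0 = array(0, shape))
  truth$m0[1, 1, 1] <- 1  # one live voxel defines the m0 scale
  p <- small_sched(10)
  ser <- simulate_acquisition(truth, array(1, shape), p,
                              acquisition_noise(0.05, seed = 9))
  noise_vox <- as.vector(ser[, , , 2])[-1]
  expect_lt(abs(sd(Re(noise_vox)) - 0.05) / 0.05, 0.03)
  expect_lt(abs(sd(Im(noise_vox)) - 0.05) / 0.05, 0.03)
  # determinism
  ser2 <- simulate_acquisition(truth, array(1, shape), p,
                               acquisition_noise(0.05, seed = 9))
  expect_identical(ser2, ser)
})

test_that("test-retest pairs share truth but not noise", {
  spec <- phantom_spec(shape = c(24, 24), n_slices = 1,
                       vials = default_vials()[0, ])
  tr <- generate_phantom_truth(spec)
  p <- small_sched(20)
  b1 <- array(1, dim(tr$t1_ms))
  # noiseless: the two series are identical
  pair0 <- generate_test_retest_pair(tr, b1, p, acquisition_noise(0),
                                     seeds = c(1, 2))
  expect_identical(pair0$test, pair0$retest)
  # noisy: differ, and the noise components are uncorrelated
  pair <- generate_test_retest_pair(tr, b1, p, acquisition_noise(0.05),
                                    seeds = c(1, 2))
  expect_false(identical(pair$test, pair$retest))
  n1 <- Re(pair$test - pair0$test)
  n2 <- Re(pair$retest - pair0$retest)
  expect_lt(abs(cor(as.vector(n1), as.vector(n2))), 0.02)
  expect_warning(generate_test_retest_pair(tr, b1, p,
                                           acquisition_noise(0.05),
                                           seeds = c(3, 3)), "correlated")
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(123)
  expected <- rnorm(3)
  set.seed(123)
  invisible(generate_b1_field(c(4, 4, 1), 0.2, seed = 77))
  invisible(generate_brain_truth(brain_spec(regions = data.frame(
    label = 1, name = "GM", volume_cm3 = 0.1, t1_ms = 1516, t2_ms = 68),
    shape = c(10, 10, 2)), seed = 5))
  expect_identical(rnorm(3), expected)
})
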