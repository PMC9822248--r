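test_that("noise-free generation is exact and honors the requested tree", {
  d <- simulate_ephys_dataset(n_batches = 2, n_cells = 3, n_sweeps = 4,
                              baseline_mean = 100,
                              group_effects = c(control_A = 1, ko_A = 1,
                                                control_B = 1, ko_B = 1),
                              batch_sd = 0, cell_sd = 0, sweep_cv = 0, seed = 1)
  expect_true(all(d$value == 100))
  expect_equal(nrow(d), 4 * 2 * 3 * 4)
  for (g in GROUP_LABELS) {
    xg <- d[d$group == g, ]
    expect_equal(length(unique(xg$batch)), 2)
    expect_equal(length(unique(paste(xg$batch, xg$cell))), 6)
  }
})

test_that("noise-free group effects reproduce the true ratio statistic", {
  d <- simulate_ephys_dataset(group_effects = c(control_A = 1, ko_A = 0.15,
                                                control_B = 1, ko_B = 0.075),
                              batch_sd = 0, cell_sd = 0, sweep_cv = 0, seed = 2)
  expect_equal(statistic_T(d), 2, tolerance = 1e-12)
  expect_equal(attr(d, "ground_truth")$T_true, 2)
})

test_that("generators are pure functions of their seed", {
  expect_identical(simulate_ephys_dataset(seed = 8),
                   simulate_ephys_dataset(seed = 8))
  expect_false(identical(simulate_ephys_dataset(seed = 8)$value,
                         simulate_ephys_dataset(seed = 9)$value))
  for (k in c("evoked_pair", "sucrose_step", "minis", "train")) {
    t1 <- simulate_trace(k, noise_sd = 2, seed = 5)
    t2 <- simulate_trace(k, noise_sd = 2, seed = 5)
    expect_identical(t1$samples, t2$samples)
  }
  expect_identical(simulate_sideview_image(seed = 3)$channels,
                   simulate_sideview_image(seed = 3)$channels)
  expect_identical(simulate_puncta_field(seed = 3)$image,
                   simulate_puncta_field(seed = 3)$image)
})

test_that("with zero batch/cell variance the group mean converges to its target", {
  d <- simulate_ephys_dataset(n_batches = 1, n_cells = 1, n_sweeps = 10000,
                              baseline_mean = 200,
                              group_effects = c(control_A = 1, ko_A = 0.15,
                                                control_B = 1, ko_B = 0.075),
                              batch_sd = 0, cell_sd = 0, sweep_cv = 0.3, seed = 12)
  for (g in GROUP_LABELS) {
    v <- d$value[d$group == g]
    target <- 200 * attr(d, "ground_truth")$group_effects[[g]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 3 * se)
  }
})

test_that("the generator's ratio statistic is centred on T_true (log scale)", {
  # the plug-in ratio of means is slightly biased upward at 3 batches; on the
  # log scale the equal control/ko coefficients of variation cancel, so the
  # Monte-Carlo mean of log T-hat estimates log T_true
  n_rep <- 400
  set.seed(101)
  logt <- replicate(n_rep, log(statistic_T(simulate_ephys_dataset())))
  se <- sd(logt) / sqrt(n_rep)
  expect_lt(abs(mean(logt) - log(2)), 3 * se)
})

test_that("per-batch and per-cell count ranges are honored", {
  d <- simulate_ephys_dataset(n_batches = 2, n_cells = c(2, 5),
                              n_sweeps = c(3, 4), seed = 6)
  per_cell <- tapply(d$value, paste(d$group, d$batch, d$cell), length)
  expect_true(all(per_cell %in% 3:4))
  per_batch_cells <- tapply(d$cell, paste(d$group, d$batch),
                            function(x) length(unique(x)))
  expect_true(all(per_batch_cells %in% 2:5))
})

test_that("single-sweep ephys datasets carry the flag and one value per cell", {
  d <- simulate_ephys_dataset(single_sweep = TRUE, seed = 4)
  expect_true(attr(d, "single_sweep"))
  expect_true(all(tapply(d$value, paste(d$group, d$batch, d$cell), length) == 1))
})

test_that("trace ground truth matches the rendered waveforms", {
  # paired pulse: stated amplitudes give the stated ratio
  tp <- simulate_trace("evoked_pair", amplitudes = c(100, 150), noise_sd = 0)
  expect_equal(attr(tp, "ground_truth")$ppr, 1.5)
  # sucrose: injected charge equals the integral of the noise-free trace
  ts <- simulate_trace("sucrose_step", amplitude = 100, plateau_duration = 10,
                       noise_sd = 0)
  gt <- attr(ts, "ground_truth")
  expect_equal(gt$charge_pC, 1000)
  tt <- (seq_along(ts$samples) - 1) / ts$sampling_rate
  num <- pracma::trapz(tt, abs(ts$samples))
  expect_lt(abs(num - gt$charge_pC) / gt$charge_pC, 0.001)
  # minis at rate 0: baseline-only trace, empty ground truth
  tm <- simulate_trace("minis", rate = 0, noise_sd = 1.5, duration = 20, seed = 2)
  expect_length(attr(tm, "ground_truth")$event_times, 0)
  expect_lt(max(abs(tm$samples)), 10)  # noise only
  tm0 <- simulate_trace("minis", rate = 0, noise_sd = 0, duration = 5)
  expect_true(all(tm0$samples == 0))
})

test_that("side-view rendering is geometrically faithful", {
  # zero test amplitude: test channel is exactly background
  s0 <- simulate_sideview_image(noise_sd = 0, background_level = 0,
                                channel_amplitudes = c(150, 200, 0))
  expect_true(all(s0$channels$test == 0))
  # orientation propagates to the rendered band within a degree
  for (ang in c(0, 30, 117)) {
    s <- simulate_sideview_image(psd_orientation = ang, noise_sd = 0)
    roi <- fit_psd_ellipse(s$ground_truth$psd_mask, pixel_size = s$pixel_size)
    delta <- abs(roi$orientation - ang) %% 180
    expect_lt(min(delta, 180 - delta), 1)
  }
  expect_error(simulate_sideview_image(psd_center = c(2, 2)), "fit inside")
})

test_that("puncta fields respect separation and are reproducible", {
  pf <- simulate_puncta_field(n_puncta = 30, seed = 9)
  gt <- pf$ground_truth
  dmat <- as.matrix(dist(cbind(gt$x, gt$y))) * pf$pixel_size
  diag(dmat) <- Inf
  expect_gte(min(dmat), 350)
  expect_identical(pf$image, simulate_puncta_field(n_puncta = 30, seed = 9)$image)
  # empty field: background plus noise only, empty ground truth
  p0 <- simulate_puncta_field(n_puncta = 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(p0$ground_truth), 0)
  expect_true(all(p0$image == 10))
  # impossible packing fails with a placement error
  expect_error(simulate_puncta_field(n_puncta = 500, image_size = 64,
                                     min_separation = 500, max_tries = 2000,
                                     seed = 1),
               "could not place")
})

test_that("nested datasets round-trip through delimited text", {
  d <- simulate_ephys_dataset(n_batches = 2, n_cells = 2, n_sweeps = 2, seed = 13)
  tmp <- tempfile(fileext = ".tsv")
  write_nested_dataset(d, tmp)
  d2 <- read_nested_dataset(tmp)
  expect_equal(d2$value, d$value)
  expect_equal(statistic_T(d2), statistic_T(d))
})

test_that("traces round-trip through delimited text with JSON metadata", {
  tr <- simulate_trace("evoked_pair", noise_sd = 1, seed = 2)
  tmp <- tempfile(fileext = ".tsv")
  write_trace(tr, tmp)
  tr2 <- read_trace(tmp)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-9)
  expect_equal(tr2$stimulus_times, tr$stimulus_times)
  expect_equal(tr2$sampling_rate, tr$sampling_rate, tolerance = 1e-6)
})
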