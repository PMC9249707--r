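# Synthetic CLE generator: calibration mechanics, study structure,
# determinism, artifacts, kinetics ramp, simulated raters.

test_that("degenerate intensity targets give constant frames", {
  cfg <- small_cfg(benign_mean = 0, benign_spread = 0)
  set.seed(1)
  f <- generate_benign_frame(cfg)
  expect_true(all(f == 0L))
  rois <- corner_rois(100, 1)
  expect_equal(roi_means(f, rois), c(top_left = 0, top_right = 0,
                                     bottom_left = 0, bottom_right = 0))
  cfg2 <- small_cfg(scc_mean = 500, scc_spread = 0)
  set.seed(1)
  expect_true(all(generate_scc_frame(cfg2) == 500L))
})

test_that("calibrated frames hit the preset first and second moments", {
  cfg <- small_cfg(calibration_frames = 300L)
  rois <- corner_rois(cfg$frame_px, cfg$pixel_size_um)
  for (class in c("benign", "scc")) {
    cal <- frame_calibration(cfg, class)
    gen <- if (class == "benign") generate_benign_frame else generate_scc_frame
    target_mean <- if (class == "benign") cfg$benign_mean else cfg$scc_mean
    target_spread <- if (class == "benign") cfg$benign_spread else cfg$scc_spread
    set.seed(500)
    stats <- replicate(150, {
      f <- gen(cfg, cal)
      c(mean(roi_means(f, rois)), frame_spread(f, rois))
    })
    se_mean <- sqrt(cal$mean_se^2 + var(stats[1, ]) / ncol(stats))
    se_spread <- sqrt(cal$spread_se^2 + var(stats[2, ]) / ncol(stats))
    expect_lt(abs(mean(stats[1, ]) - target_mean), 3 * se_mean)
    expect_lt(abs(mean(stats[2, ]) - target_spread), 3 * se_spread)
  }
})

test_that("switching off leakage and the regional field collapses the SCC spread", {
  cfg <- small_cfg()
  cal <- frame_calibration(cfg, "scc")
  flat <- small_cfg(leakage_patch_density = 0, regional_amp = 0)
  rois <- corner_rois(cfg$frame_px, cfg$pixel_size_um)
  set.seed(9)
  # same fixed intensity mapping (cal) for both, so only the mechanics differ
  s_full <- replicate(40, frame_spread(generate_scc_frame(cfg, cal), rois))
  s_flat <- replicate(40, frame_spread(generate_scc_frame(flat, cal), rois))
  expect_lt(median(s_flat), 0.6 * median(s_full))
})

test_that("a study has the configured design and labels", {
  cfg <- small_cfg()
  study <- generate_study(cfg)
  expect_length(study, 4)
  labels <- vapply(study, function(s) s$label, character(1))
  expect_equal(labels, c("benign", "benign", "scc", "scc"))
  expect_true(all(vapply(study, n_frames, integer(1)) == 3L))
  rng <- range(vapply(study, function(s) range(unlist(s$frames)), numeric(2)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 65535)
  # no frame is entirely saturated
  expect_true(all(vapply(study, function(s)
    all(vapply(s$frames, function(f) any(f < 65535L), logical(1))),
    logical(1))))

  minimal <- generator_config(frame_px = 100L, n_benign = 1L, n_scc = 0L,
                              frames_per_sequence = 1L,
                              calibration_frames = 30L, seed = 3L)
  one <- generate_study(minimal)
  expect_length(one, 1)
  expect_equal(one[[1]]$label, "benign")
  expect_equal(n_frames(one[[1]]), 1L)
})

test_that("studies are deterministic and substreams are stable per sequence", {
  cfg <- small_cfg()
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)
  # adding SCC sequences must not perturb earlier benign sequences
  more <- small_cfg(n_scc = 4L)
  c <- generate_study(more)
  expect_identical(a[[1]]$frames, c[[1]]$frames)
  expect_identical(a[[2]]$frames, c[[2]]$frames)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(frame_px = 60L), "twice the ROI side")
  expect_error(generator_config(frames_per_sequence = 0L), ">= 1")
  expect_error(generator_config(benign_mean = -1), "intensity targets")
  expect_error(generator_config(artifact_probs = c(blood = 1.5)), "\\[0, 1\\]")
  expect_error(kinetics_params(onset_s = 224, adequate_s = 208), "onset_s")
  expect_error(kinetics_params(baseline = 300, plateau = 200), "baseline")
})

test_that("the wash-in ramp is 0 before onset and exactly 0.9 at adequate_s", {
  k <- kinetics_params()
  expect_equal(kinetics_ramp(c(0, 100, 207.9), k), c(0, 0, 0))
  expect_equal(kinetics_ramp(224, k), 0.9)
  expect_equal(kinetics_ramp(1e6, k), 1)
  k2 <- kinetics_params(rise_shape = 2)
  expect_equal(kinetics_ramp(224, k2), 0.9)
  expect_true(all(diff(kinetics_ramp(seq(0, 400, by = 0.5), k)) >= 0))
})

test_that("apply_kinetics renders baseline before onset and the template after", {
  cfg <- small_cfg()
  set.seed(21)
  tpl <- replicate(3, generate_benign_frame(cfg), simplify = FALSE)
  k <- kinetics_params(baseline = 25, plateau = 232.1)

  pre <- apply_kinetics(tpl, k, t0_s = 0, n_frames = 24, fps = 1, noise_sd = 2)
  pre_means <- vapply(pre$frames, mean, numeric(1))
  expect_true(all(abs(pre_means - 25) < 1))

  post <- apply_kinetics(tpl, k, t0_s = 1000, n_frames = 6, fps = 1,
                         noise_sd = 2)
  rois <- corner_rois(cfg$frame_px, 1)
  pooled <- mean(vapply(post$frames, function(f) mean(roi_means(f, rois)),
                        numeric(1)))
  # fully flooded: pooled ROI mean ~ baseline + plateau
  expect_lt(abs(pooled - (25 + 232.1)), 10)
})

test_that("artifacts modify frames as specified", {
  cfg <- small_cfg()
  set.seed(31)
  f <- generate_benign_frame(cfg)
  rois <- corner_rois(cfg$frame_px, 1)

  expect_error(apply_artifact(f, "sneeze"), "unknown artifact kind")

  g <- apply_artifact(f, "contact_loss", baseline = 25)
  expect_true(all(abs(roi_means(g, rois) - 25) < 2))
  expect_lt(frame_spread(g, rois), 1)

  # tangent on a constant frame: closed-form spread from the ROI centres
  const <- matrix(1000L, 100, 100)
  grad <- 80
  ang <- pi / 7
  g <- apply_artifact(const, "tangent", gradient = grad, angle = ang)
  ctr <- (100 - 1) / 2
  centre_of <- function(r) c(r[["row0"]] + 22, r[["col0"]] + 22)
  proj <- vapply(rois, function(r) {
    ctr_rc <- centre_of(r)
    (cos(ang) * (ctr_rc[2] - ctr) + sin(ang) * (ctr_rc[1] - ctr)) / ctr
  }, numeric(1))
  expect_equal(frame_spread(g, rois), sd(1000 + grad * proj),
               tolerance = 2e-3)

  # all artifact kinds stay within the intensity bounds
  for (kind in c("blood", "saliva", "bubble", "motion", "dirt")) {
    set.seed(100)
    h <- apply_artifact(f, kind)
    expect_gte(min(h), 0)
    expect_lte(max(h), 65535)
    expect_equal(dim(h), dim(f))
  }
})

test_that("motion artifacts inflate the across-ROI spread", {
  cfg <- small_cfg()
  rois <- corner_rois(cfg$frame_px, 1)
  cal <- frame_calibration(cfg, "benign")
  set.seed(87)
  hits <- replicate(100, {
    f <- generate_benign_frame(cfg, cal)
    frame_spread(apply_artifact(f, "motion"), rois) > frame_spread(f, rois)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("simulated raters follow their operating profiles", {
  truth <- c("benign", "scc")
  perfect <- list(rater_profile(1, 1), rater_profile(1, 1))
  rm <- simulate_raters(truth, perfect)
  expect_equal(unname(rm$calls), cbind(c(0L, 1L), c(0L, 1L)))

  always <- simulate_raters(truth, list(rater_profile(1, 0)))
  expect_true(all(always$calls == 1L))

  expect_error(simulate_raters(character(0), perfect), "at least one item")

  # Bernoulli expectation over a large item set
  set.seed(12)
  labels <- rep(c("benign", "scc"), times = c(4500, 5500))
  profiles <- observer_rater_profiles()
  rm <- simulate_raters(labels, profiles)
  for (j in seq_along(profiles)) {
    sens_hat <- mean(rm$calls[labels == "scc", j])
    spec_hat <- mean(1 - rm$calls[labels == "benign", j])
    p <- profiles[[j]]$sensitivity
    expect_lt(abs(sens_hat - p), 3 * sqrt(max(p * (1 - p), 1e-4) / 5500))
    q <- profiles[[j]]$specificity
    expect_lt(abs(spec_hat - q), 3 * sqrt(max(q * (1 - q), 1e-4) / 4500))
  }
})
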