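test_that("clip generation is deterministic and seed-sensitive", {
  cfg <- tiny_config()
  a <- generate_normal_clip(cfg, seed = 7)
  b <- generate_normal_clip(cfg, seed = 7)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "trajectory"), attr(b, "trajectory"))
  expect_false(identical(a$data, generate_normal_clip(cfg, seed = 8)$data))

  # generation restores the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_normal_clip(cfg, seed = 7))
  expect_identical(rnorm(3), before)
})

test_that("a zero-motion, zero-noise configuration is a static scene", {
  cfg <- synth_config(frame_size = c(32, 40), n_frames = 10, speed = 0,
                      heading_sd = 0, noise_sd = 0, illum_amp = 0)
  v <- generate_normal_clip(cfg, seed = 3)
  for (t in 2:10) expect_identical(v$data[, , t], v$data[, , 1])
})

test_that("smooth motion respects the small-angle heading cap", {
  # slow blob far from borders: no reflections can occur in 40 frames
  cfg <- synth_config(frame_size = c(64, 64), n_frames = 40, speed = 0.3,
                      heading_sd = 0.05, heading_cap = 0.1, start_jitter = 1,
                      noise_sd = 0)
  tr <- attr(generate_normal_clip(cfg, seed = 5), "trajectory")
  expect_lte(max(abs(diff(tr$heading))), 0.1 + 1e-12)
  expect_false(any(tr$frozen))
  expect_false(any(tr$jerk))
})

test_that("abnormal clips log reversals of at least 90 degrees and freezes", {
  cfg <- synth_config(frame_size = c(48, 48), n_frames = 120, speed = 1.5,
                      jerk_rate = 40, freeze_prob = 0.05, freeze_len = 10,
                      noise_sd = 0)
  tr <- attr(generate_abnormal_clip(cfg, seed = 9), "trajectory")

  expect_gt(sum(tr$jerk), 0)
  # reversal angles, excluding frames where a border reflection also
  # altered the heading
  sel <- tr$jerk[-1] & !tr$reflect[-1]
  dh <- abs(diff(tr$heading))[sel]
  expect_true(all(dh >= pi / 2 - 1e-12 & dh <= pi + 1e-12))

  expect_gt(sum(tr$frozen), 0)
  # positions are constant across every frozen stretch
  runs <- rle(tr$frozen)
  idx <- cumsum(runs$lengths)
  start <- c(1, head(idx, -1) + 1)
  for (r in which(runs$values)) {
    seg <- tr[max(1, start[r] - 1):idx[r], ]
    expect_equal(diff(range(seg$x)), 0)
    expect_equal(diff(range(seg$y)), 0)
  }
})

test_that("reversal frequency tracks the configured rate", {
  cfg <- synth_config(frame_size = c(64, 64), n_frames = 400, speed = 1,
                      jerk_rate = 25, freeze_prob = 0, noise_sd = 0)
  rates <- vapply(1:6, function(s) {
    tr <- attr(generate_abnormal_clip(cfg, seed = 400 + s), "trajectory")
    100 * mean(tr$jerk)
  }, numeric(1))
  # Monte-Carlo tolerance: binomial sd of the per-clip rate is ~2.2
  expect_lt(abs(mean(rates) - 25), 3 * 2.2 / sqrt(6))
})

test_that("the abnormal model degenerates exactly to the normal model", {
  cfg <- synth_config(frame_size = c(32, 40), n_frames = 30,
                      jerk_rate = 0, freeze_prob = 0, noise_sd = 0.003)
  a <- generate_abnormal_clip(cfg, seed = 14)
  n <- generate_normal_clip(cfg, seed = 14)
  expect_identical(a$data, n$data)
  expect_identical(attr(a, "trajectory"), attr(n, "trajectory"))
})

test_that("cohorts have the requested shape, labels and determinism", {
  cfg <- tiny_config()
  coh <- generate_cohort(n_patients = 9, clips_per_patient = 5,
                         abnormal_fraction = 0.5, config = cfg, seed = 6)
  expect_length(coh$clips, 45)
  expect_length(unique(coh$annotations$patient_id), 9)
  expect_identical(sum(coh$annotations$label == "abnormal"),
                   as.integer(round(0.5 * 45)))

  coh4 <- generate_cohort(n_patients = 3, clips_per_patient = 5,
                          abnormal_fraction = 0.4, config = cfg, seed = 6)
  expect_identical(sum(coh4$annotations$label == "abnormal"),
                   as.integer(round(0.4 * 15)))

  coh2 <- generate_cohort(n_patients = 9, clips_per_patient = 5,
                          abnormal_fraction = 0.5, config = cfg, seed = 6)
  expect_identical(coh$annotations, coh2$annotations)
  expect_identical(coh$clips[[17]]$data, coh2$clips[[17]]$data)

  expect_error(generate_cohort(0, 5, 0.5, cfg, 1), "n_patients")
  expect_error(generate_cohort(2, 5, 1.4, cfg, 1), "abnormal_fraction")
})

test_that("the streaming feature path reproduces the materialized cohort", {
  cfg <- tiny_config()
  bank <- tiny_bank(2)
  coh <- generate_cohort(3, 3, 0.5, cfg, seed = 10)
  ref <- compute_features(coh$clips, labels = coh$annotations$label,
                          bank = bank)
  got <- generate_cohort_features(3, 3, 0.5, cfg, seed = 10, bank = bank)
  expect_identical(got$clip_id, ref$clip_id)
  expect_identical(got$label, ref$label)
  expect_equal(as.matrix(got[, -(1:3)]), as.matrix(ref[, -(1:3)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("write_cohort lays out frames, logs and annotations", {
  cfg <- synth_config(frame_size = c(16, 20), n_frames = 4, blob_radius = 1.5)
  coh <- generate_cohort(2, 2, 0.5, cfg, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_identical(nrow(ann), 4L)
  first <- file.path(dir, coh$annotations$clip[1])
  expect_length(list.files(first, pattern = "frame.*png"), 4)
  expect_true(file.exists(file.path(first, "trajectory.csv")))

  v <- load_video(first, target_size = c(16, 20))
  expect_identical(dim(v), c(16L, 20L, 4L))
})

test_that("distractor blobs and illumination drift stay in bounds", {
  cfg <- synth_config(frame_size = c(32, 40), n_frames = 20, blob_radius = 2,
                      n_distractors = 2, illum_amp = 0.1, illum_period = 10,
                      noise_sd = 0.01)
  v <- generate_normal_clip(cfg, seed = 77)
  expect_gte(min(v$data), 0)
  expect_lte(max(v$data), 1)
  # drift modulates the background over time
  bg <- apply(v$data, 3, median)
  expect_gt(diff(range(bg)), 0.05)
})
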