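#' Configuration of the synthetic surrogate video generator
#'
#' The generator renders a bright Gaussian-profile blob (the moving patient)
#' over a darker uniform background, optionally with illumination drift,
#' pixel noise, and independently moving distractor blobs (other persons in
#' the ward). Normal clips move smoothly: constant speed with small
#' Ornstein-Uhlenbeck-style heading jitter, reflecting at the frame borders.
#' Abnormal clips follow the motion signature of seizure-related movement —
#' abrupt heading reversals (instantaneous turns of at least 90 degrees) at
#' a configured rate, interleaved with frozen no-movement periods.
#'
#' @param frame_size `c(height, width)` in pixels; default `c(128, 160)`,
#'   the working resolution of the pipeline.
#' @param n_frames frames per clip; default 250 (10 s at 25 fps).
#' @param frame_rate frames per second; default 25.
#' @param blob_radius Gaussian sigma of the blob profile, pixels.
#' @param blob_intensity peak intensity of the blob above the background.
#' @param background uniform background intensity.
#' @param speed blob speed, pixels/frame.
#' @param heading_sd per-frame heading jitter standard deviation, radians.
#' @param heading_cap small-angle cap on the per-frame heading change of
#'   smooth motion, radians.
#' @param jerk_rate expected abrupt direction reversals per 100 frames
#'   (abnormal clips only).
#' @param freeze_prob per-frame probability of entering a no-movement
#'   period (abnormal clips only).
#' @param freeze_len length of each frozen period, frames.
#' @param start_jitter half-width (pixels) of the uniform jitter of the
#'   starting position around the frame center; the overhead camera is
#'   centered on the patient, so trajectories begin near the center.
#' @param illum_amp amplitude of a slow sinusoidal additive illumination
#'   drift (0 disables).
#' @param illum_period period of the illumination drift, frames.
#' @param noise_sd standard deviation of additive per-pixel Gaussian noise.
#' @param n_distractors number of extra smoothly moving dimmer blobs.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(frame_size = c(128L, 160L), n_frames = 250L,
                         frame_rate = 25, blob_radius = 5,
                         blob_intensity = 0.6, background = 0.25,
                         speed = 16, heading_sd = 0.06, heading_cap = 0.15,
                         jerk_rate = 100, freeze_prob = 0.3, freeze_len = 80L,
                         start_jitter = 6,
                         illum_amp = 0, illum_period = 200,
                         noise_sd = 0.005, n_distractors = 0L) {
  frame_size <- as.integer(frame_size)
  if (length(frame_size) != 2L || any(frame_size < 8L))
    stop("`frame_size` must be c(height, width), both >= 8", call. = FALSE)
  if (n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  if (frame_rate <= 0) stop("`frame_rate` must be > 0", call. = FALSE)
  if (blob_radius <= 0) stop("`blob_radius` must be > 0", call. = FALSE)
  if (2 * blob_radius >= min(frame_size) / 2)
    stop("blob does not fit inside the frame", call. = FALSE)
  if (freeze_prob < 0 || freeze_prob > 1)
    stop("`freeze_prob` must be in [0, 1]", call. = FALSE)
  if (jerk_rate < 0) stop("`jerk_rate` must be >= 0", call. = FALSE)
  if (noise_sd < 0 || illum_amp < 0 || speed < 0)
    stop("`noise_sd`, `illum_amp`, `speed` must be >= 0", call. = FALSE)
  structure(
    list(frame_size = frame_size, n_frames = as.integer(n_frames),
         frame_rate = frame_rate, blob_radius = blob_radius,
         blob_intensity = blob_intensity, background = background,
         speed = speed, heading_sd = heading_sd, heading_cap = heading_cap,
         jerk_rate = jerk_rate, freeze_prob = freeze_prob,
         freeze_len = as.integer(freeze_len), start_jitter = start_jitter,
         illum_amp = illum_amp,
         illum_period = illum_period, noise_sd = noise_sd,
         n_distractors = as.integer(n_distractors)),
    class = "synth_config"
  )
}

# Simulate a blob trajectory. Returns a data.frame log with one row per
# frame: position, heading, and whether a jerk or freeze was active. All
# randomness must already be seeded by the caller.
simulate_trajectory <- function(config, abnormal) {
  n <- config$n_frames
  margin <- 2 * config$blob_radius
  lo <- c(margin, margin)
  hi <- c(config$frame_size[1] - 1 - margin, config$frame_size[2] - 1 - margin)
  # the camera is centered on the patient, so trajectories start near the
  # frame center (with jitter); reversal-heavy abnormal motion then stays
  # localized there while smooth motion wanders across the frame
  ctr <- (config$frame_size - 1) / 2
  pos <- pmin(pmax(ctr + stats::runif(2, -config$start_jitter,
                                      config$start_jitter), lo), hi)
  heading <- stats::runif(1, 0, 2 * pi)
  p_jerk <- if (abnormal) config$jerk_rate / 100 else 0
  p_freeze <- if (abnormal) config$freeze_prob else 0
  freeze_left <- 0L
  x <- y <- h <- numeric(n)
  jerk <- frozen <- reflect <- logical(n)
  for (t in seq_len(n)) {
    if (freeze_left > 0L) {
      freeze_left <- freeze_left - 1L
      frozen[t] <- TRUE
    } else {
      if (p_freeze > 0 && stats::runif(1) < p_freeze) {
        freeze_left <- config$freeze_len - 1L
        frozen[t] <- TRUE
      } else {
        if (p_jerk > 0 && stats::runif(1) < p_jerk) {
          # abrupt reversal: instantaneous turn of at least 90 degrees
          heading <- heading +
            sample(c(-1, 1), 1) * stats::runif(1, pi / 2, pi)
          jerk[t] <- TRUE
        } else {
          dh <- stats::rnorm(1, 0, config$heading_sd)
          heading <- heading +
            max(-config$heading_cap, min(config$heading_cap, dh))
        }
        step <- config$speed * c(cos(heading), sin(heading))
        nxt <- pos + step
        # reflect at the safe box so the blob stays fully inside the frame
        if (nxt[1] < lo[1] || nxt[1] > hi[1]) {
          heading <- pi - heading
          nxt[1] <- pmin(pmax(nxt[1], lo[1]), hi[1])
          reflect[t] <- TRUE
        }
        if (nxt[2] < lo[2] || nxt[2] > hi[2]) {
          heading <- -heading
          nxt[2] <- pmin(pmax(nxt[2], lo[2]), hi[2])
          reflect[t] <- TRUE
        }
        pos <- nxt
      }
    }
    x[t] <- pos[1]; y[t] <- pos[2]; h[t] <- heading
  }
  data.frame(frame = seq_len(n), x = x, y = y, heading = h,
             jerk = jerk, frozen = frozen, reflect = reflect)
}

# Render a trajectory (plus optional distractors) into an intensity volume.
render_clip <- function(config, traj, distractor_trajs = list()) {
  d <- c(config$frame_size, config$n_frames)
  rows <- seq_len(d[1]) - 1
  cols <- seq_len(d[2]) - 1
  s2 <- 2 * config$blob_radius^2
  vol <- array(0, d)
  for (t in seq_len(d[3])) {
    frame <- matrix(config$background, d[1], d[2])
    if (config$illum_amp > 0)
      frame <- frame +
        config$illum_amp * sin(2 * pi * t / config$illum_period)
    # separable Gaussian blob render
    frame <- frame + config$blob_intensity *
      (exp(-(rows - traj$x[t])^2 / s2) %o% exp(-(cols - traj$y[t])^2 / s2))
    for (dt in distractor_trajs) {
      frame <- frame + 0.5 * config$blob_intensity *
        (exp(-(rows - dt$x[t])^2 / s2) %o% exp(-(cols - dt$y[t])^2 / s2))
    }
    vol[, , t] <- frame
  }
  if (config$noise_sd > 0)
    vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd)
  pmin(pmax(vol, 0), 1)
}

generate_clip <- function(config, seed, abnormal, patient_id = "",
                          clip_id = "") {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    traj <- simulate_trajectory(config, abnormal = abnormal)
    distractors <- lapply(seq_len(config$n_distractors), function(i)
      simulate_trajectory(config, abnormal = FALSE))
    vol <- render_clip(config, traj, distractors)
    out <- video_volume(vol, frame_rate = config$frame_rate,
                        patient_id = patient_id, clip_id = clip_id)
    attr(out, "trajectory") <- traj
    out
  })
}

#' Generate a synthetic clip with smooth ("normal") motion
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical seeds give identical volumes.
#' @param patient_id,clip_id provenance identifiers for the volume.
#' @return a [video_volume()] with the simulated trajectory attached as
#'   attribute `"trajectory"` (data.frame: frame, x, y, heading, jerk,
#'   frozen) for use as a test oracle.
#' @export
generate_normal_clip <- function(config = synth_config(), seed,
                                 patient_id = "", clip_id = "") {
  generate_clip(config, seed, abnormal = FALSE, patient_id = patient_id,
                clip_id = clip_id)
}

#' Generate a synthetic clip with abnormal (seizure-like) motion
#'
#' As [generate_normal_clip()], but the heading process additionally makes
#' abrupt reversals (instantaneous turns of 90 degrees or more) at rate
#' `jerk_rate` per 100 frames, and motion freezes for `freeze_len`-frame
#' runs entered with per-frame probability `freeze_prob`. With
#' `jerk_rate = 0` and `freeze_prob = 0` the model degenerates exactly to
#' the smooth normal model (identical output for the same seed).
#'
#' @inheritParams generate_normal_clip
#' @return a [video_volume()] with attribute `"trajectory"`.
#' @export
generate_abnormal_clip <- function(config = synth_config(), seed,
                                   patient_id = "", clip_id = "") {
  generate_clip(config, seed, abnormal = TRUE, patient_id = patient_id,
                clip_id = clip_id)
}

# Deterministic cohort plan: per-patient nuisance configs, labels, and one
# derived seed per clip. Both the volume-materializing and the streaming
# feature path consume the same plan, so they describe the same cohort.
cohort_plan <- function(n_patients, clips_per_patient, abnormal_fraction,
                        config, seed) {
  if (n_patients < 1L || clips_per_patient < 2L)
    stop("need `n_patients` >= 1 and `clips_per_patient` >= 2", call. = FALSE)
  if (abnormal_fraction < 0 || abnormal_fraction > 1)
    stop("`abnormal_fraction` must be in [0, 1]", call. = FALSE)
  total <- n_patients * clips_per_patient
  n_abn <- round(abnormal_fraction * total)
  # spread the abnormal quota as evenly as possible across patients
  quota <- rep(n_abn %/% n_patients, n_patients)
  extra <- n_abn %% n_patients
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  quota <- pmin(quota, clips_per_patient)
  deficit <- n_abn - sum(quota)
  p <- 1L
  while (deficit > 0L) {           # spill-over when a patient's quota capped
    if (quota[p] < clips_per_patient) {
      quota[p] <- quota[p] + 1L; deficit <- deficit - 1L
    }
    p <- p %% n_patients + 1L
  }

  configs <- vector("list", n_patients)
  rows <- vector("list", total)
  idx <- 1L
  with_seed(seed, {
    for (p in seq_len(n_patients)) {
      pid <- sprintf("patient%02d", p)
      pconf <- config
      pconf$background <- stats::runif(1, 0.2, 0.3)
      pconf$blob_intensity <- stats::runif(1, 0.5, 0.65)
      pconf$blob_radius <- stats::runif(1, 0.9, 1.1) * config$blob_radius
      configs[[p]] <- pconf
      abn_clips <- sample.int(clips_per_patient, quota[p])
      for (cl in seq_len(clips_per_patient)) {
        rows[[idx]] <- data.frame(
          clip = sprintf("%s_clip%02d", pid, cl), patient_id = pid,
          patient = p,
          label = if (cl %in% abn_clips) "abnormal" else "normal",
          seed = (as.integer(seed) + p * 131071L + cl * 127L) %% 2147483647L,
          stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
  })
  list(table = do.call(rbind, rows), configs = configs)
}

#' Generate a labeled synthetic cohort
#'
#' Emulates the shape of a ward study: `n_patients` patients with
#' `clips_per_patient` clips each. Per-patient appearance nuisances
#' (background level, blob intensity and size — different clothes and
#' lighting across patients) are drawn once per patient; clip labels are
#' assigned so that `round(abnormal_fraction * total)` clips are abnormal,
#' spread as evenly as possible across patients. Everything is
#' deterministic given `seed`.
#'
#' @param n_patients number of patients (default 9).
#' @param clips_per_patient clips per patient, >= 2 (default 6).
#' @param abnormal_fraction fraction of abnormal clips in the cohort.
#' @param config base [synth_config()]; per-patient nuisances perturb it.
#' @param seed integer cohort seed.
#' @return a list of class `synth_cohort` with `clips` (list of
#'   [video_volume()] with trajectory attributes) and `annotations`
#'   (data.frame `clip,patient_id,label,top,left,height,width`).
#' @examples
#' \donttest{
#' coh <- generate_cohort(n_patients = 2, clips_per_patient = 2,
#'                        config = synth_config(frame_size = c(32, 40),
#'                                              n_frames = 24), seed = 1)
#' table(coh$annotations$label)
#' }
#' @export
generate_cohort <- function(n_patients = 9L, clips_per_patient = 6L,
                            abnormal_fraction = 0.5,
                            config = synth_config(), seed = 1L) {
  plan <- cohort_plan(n_patients, clips_per_patient, abnormal_fraction,
                      config, seed)
  tab <- plan$table
  clips <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    clips[[i]] <- generate_clip(plan$configs[[tab$patient[i]]], tab$seed[i],
                                abnormal = tab$label[i] == "abnormal",
                                patient_id = tab$patient_id[i],
                                clip_id = tab$clip[i])
  }
  ann <- data.frame(clip = tab$clip, patient_id = tab$patient_id,
                    label = tab$label, top = NA_integer_, left = NA_integer_,
                    height = NA_integer_, width = NA_integer_,
                    stringsAsFactors = FALSE)
  structure(list(clips = clips, annotations = ann,
                 config = config, seed = as.integer(seed)),
            class = "synth_cohort")
}

#' Generate a synthetic cohort and stream it into gist features
#'
#' Describes exactly the same cohort as [generate_cohort()] (same seeds,
#' trajectories and labels) but extracts each clip's gist descriptor as soon
#' as the clip is rendered and then discards the volume, so full-resolution
#' cohorts of arbitrary size run in the memory footprint of a single clip.
#'
#' @inheritParams generate_cohort
#' @param bank,grid passed to [extract_gist()].
#' @return a [compute_features()]-layout data.frame (`clip_id`,
#'   `patient_id`, `label`, `fNNN...`).
#' @export
generate_cohort_features <- function(n_patients = 9L, clips_per_patient = 6L,
                                     abnormal_fraction = 0.5,
                                     config = synth_config(), seed = 1L,
                                     bank = build_default_bank(),
                                     grid = c(4L, 4L, 4L)) {
  plan <- cohort_plan(n_patients, clips_per_patient, abnormal_fraction,
                      config, seed)
  tab <- plan$table
  feats <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    clip <- generate_clip(plan$configs[[tab$patient[i]]], tab$seed[i],
                          abnormal = tab$label[i] == "abnormal",
                          patient_id = tab$patient_id[i],
                          clip_id = tab$clip[i])
    feats[[i]] <- extract_gist(clip, bank = bank, grid = grid)
    rm(clip)
  }
  out <- data.frame(clip_id = tab$clip, patient_id = tab$patient_id,
                    label = tab$label, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(do.call(rbind, feats)))
}

#' @export
print.synth_cohort <- function(x, ...) {
  tab <- table(x$annotations$label)
  cat(sprintf("<synth_cohort> %d clips, %d patients (%s)\n",
              nrow(x$annotations), length(unique(x$annotations$patient_id)),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One PNG frame directory per clip, an `annotations.csv` in the schema
#' read by [read_annotations()], and a `trajectory.csv` ground-truth log
#' next to each clip's frames.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (clip in cohort$clips) {
    cdir <- file.path(dir, clip$clip_id)
    dir.create(cdir, showWarnings = FALSE)
    for (t in seq_len(dim(clip$data)[3]))
      EBImage::writeImage(EBImage::Image(clip$data[, , t]),
                          file.path(cdir, sprintf("frame%04d.png", t)))
    utils::write.csv(attr(clip, "trajectory"),
                     file.path(cdir, "trajectory.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
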