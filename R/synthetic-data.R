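#' Configure a synthetic cohort
#'
#' Builds the configuration for [generate_cohort()]. Two regimes are
#' supported. `"real_world"` emulates unconstrained daily-life collection:
#' 32 Hz sampling, heterogeneous bout lengths, activity interruptions,
#' self-report boundary jitter, overlapping labels, occasional mislabels and
#' sensor dropouts. `"controlled"` emulates a supervised lab protocol:
#' 50 Hz sampling, uninterrupted exact-duration bouts, a fixed wristband
#' orientation and zero label noise, over the four-activity vocabulary
#' shared between the two regimes.
#'
#' @param mode `"real_world"` or `"controlled"`.
#' @param n_subjects Number of participants.
#' @param activity_minutes Named numeric vector of target labeled minutes per
#'   activity. Defaults: real-world `computer_table = 190`, `standing_still =
#'   10`, `walking = 20`, `running = 20`, `cycling = 20` (enough labeled time
#'   per activity to fill the default personalization budget, leakage gap and
#'   minimum test amount); controlled 1 min per activity.
#' @param sampling_rate Sampling rate in Hz (32 real-world, 50 controlled).
#' @param overlap_prob Probability that a self-report interval is extended
#'   past the start of the next one, creating an overlapping-label pair.
#' @param boundary_jitter_sd_s Standard deviation (s) of self-report boundary
#'   jitter.
#' @param mislabel_prob Probability a self-report interval carries the wrong
#'   activity name.
#' @param gap_rate Sensor-dropout events per hour.
#' @param start_time Epoch-seconds origin of the collection span.
#' @param start_spread_s Subjects begin recording uniformly within this many
#'   seconds of `start_time` (real-world only).
#' @param bout_range_s Min/max real-world bout length in seconds.
#' @param controlled_bout_s Exact bout length for the controlled protocol.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `har_config`.
#' @export
cohort_config <- function(mode = c("real_world", "controlled"),
                          n_subjects = 6,
                          activity_minutes = NULL,
                          sampling_rate = NULL,
                          overlap_prob = 0.05,
                          boundary_jitter_sd_s = 2,
                          mislabel_prob = 0.01,
                          gap_rate = 0.5,
                          start_time = 0,
                          start_spread_s = 900,
                          bout_range_s = c(60, 300),
                          controlled_bout_s = 60,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(activity_minutes)) {
    activity_minutes <- if (mode == "real_world") {
      c(computer_table = 190, standing_still = 10, walking = 20,
        running = 20, cycling = 20)
    } else {
      setNames(rep(1, 4), har_activities_controlled())
    }
  }
  if (is.null(sampling_rate)) sampling_rate <- if (mode == "real_world") 32 else 50
  assert_positive(n_subjects, "n_subjects")
  assert_positive(sampling_rate, "sampling_rate")
  assert_positive(activity_minutes, "activity_minutes")
  assert_prob(overlap_prob, "overlap_prob")
  assert_prob(mislabel_prob, "mislabel_prob")
  assert_positive(gap_rate, "gap_rate", strict = FALSE)
  if (mode == "controlled") {
    overlap_prob <- 0; boundary_jitter_sd_s <- 0; mislabel_prob <- 0; gap_rate <- 0
  }
  structure(list(
    mode = mode, n_subjects = as.integer(n_subjects),
    activity_minutes = activity_minutes, sampling_rate = sampling_rate,
    overlap_prob = overlap_prob, boundary_jitter_sd_s = boundary_jitter_sd_s,
    mislabel_prob = mislabel_prob, gap_rate = gap_rate,
    start_time = start_time, start_spread_s = start_spread_s,
    bout_range_s = bout_range_s, controlled_bout_s = controlled_bout_s,
    seed = as.integer(seed)
  ), class = "har_config")
}

# Fixed per-activity signal conventions: approximate gravity direction of the
# wrist in the body frame, harmonic axis mix, and (for static activities) a
# slow incidental oscillation frequency.
activity_signal_spec <- function(activity) {
  switch(activity,
    computer_table = list(gravity = c(0.20, -0.92, 0.33), mix = c(0.5, 0.3, 1.0), freq = 4.0),
    standing_still = list(gravity = c(0.05, -0.99, 0.10), mix = c(1.0, 0.2, 0.6), freq = 0.4),
    walking        = list(gravity = c(0.30, -0.90, 0.10), mix = c(0.6, 1.0, 0.4), freq = NA),
    running        = list(gravity = c(0.50, -0.80, 0.20), mix = c(0.8, 1.0, 0.5), freq = NA),
    cycling        = list(gravity = c(0.85, -0.30, 0.43), mix = c(0.5, 0.3, 1.0), freq = NA),
    abort(sprintf("unknown activity '%s'", activity))
  )
}

is_locomotion <- function(activity) activity %in% c("walking", "running", "cycling")

normalize3 <- function(v) v / sqrt(sum(v^2))

#' A rotation matrix about a coordinate axis
#'
#' Convenience constructor used to place a synthetic subject's wristband in a
#' specific orientation, e.g. to create a deliberately distribution-shifted
#' participant.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Draw subject profiles for a synthetic cohort
#'
#' Each participant gets their own locomotion cadences, movement amplitudes,
#' wrist orientation (a proper rotation applied to their whole signal,
#' modelling dominant/non-dominant arm and placement), per-activity posture
#' gravity directions, self-report labeling bias, interruption rate and
#' sensor noise level. Controlled mode fixes the wrist orientation to the
#' identity (a strapped-down protocol device).
#'
#' @param n Number of subjects.
#' @param mode `"real_world"` or `"controlled"`.
#' @param seed Integer seed.
#' @param rotation_strength Strength in `[0, 1]` of the random wrist rotation
#'   (0 = identity); ignored in controlled mode.
#' @return A tibble with one row per subject; matrix/vector fields are list
#'   columns.
#' @export
subject_profiles <- function(n, mode = c("real_world", "controlled"),
                             seed = 1L, rotation_strength = 0.3) {
  mode <- match.arg(mode)
  # The controlled protocol (supervised, device strapped in a fixed
  # orientation, subjects executing each activity "properly") compresses the
  # inter-subject variability that free-living collection exhibits, so its
  # cadence/amplitude draws cover only the central part of the real-world
  # ranges.
  rng <- function(lo, hi) {
    if (mode == "controlled") {
      m <- (lo + hi) / 2; h <- (hi - lo) / 5
      c(m - h, m + h)
    } else c(lo, hi)
  }
  with_seed(seed, {
    tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      cadence_walking = runif(n, rng(1.6, 2.2)[1], rng(1.6, 2.2)[2]),
      cadence_running = runif(n, rng(2.4, 3.2)[1], rng(2.4, 3.2)[2]),
      cadence_cycling = runif(n, rng(0.8, 1.5)[1], rng(0.8, 1.5)[2]),
      amp_walking = runif(n, rng(0.25, 0.50)[1], rng(0.25, 0.50)[2]),
      amp_running = runif(n, rng(0.60, 1.20)[1], rng(0.60, 1.20)[2]),
      amp_cycling = runif(n, rng(0.10, 0.20)[1], rng(0.10, 0.20)[2]),
      amp_computer_table = runif(n, rng(0.010, 0.030)[1], rng(0.010, 0.030)[2]),
      amp_standing_still = runif(n, rng(0.020, 0.050)[1], rng(0.020, 0.050)[2]),
      wrist_rotation = purrr::map(seq_len(n), function(i) {
        if (mode == "controlled") diag(3) else sample_rotation(rotation_strength)
      }),
      gravity_computer_table = purrr::map(seq_len(n), function(i) {
        normalize3(activity_signal_spec("computer_table")$gravity + rnorm(3, 0, 0.05))
      }),
      gravity_standing_still = purrr::map(seq_len(n), function(i) {
        normalize3(activity_signal_spec("standing_still")$gravity + rnorm(3, 0, 0.05))
      }),
      labeling_bias = runif(n, 0.5, 0.9),
      interruption_rate = if (mode == "real_world") runif(n, 0.05, 0.20) else rep(0, n),
      noise_sd_g = runif(n, 0.02, 0.05)
    )
  })
}

#' Replace one subject's wrist rotation
#'
#' @param profiles A profile tibble from [subject_profiles()].
#' @param subject_id Subject to modify.
#' @param rotation A 3x3 proper rotation matrix.
#' @return The modified profile tibble.
#' @export
set_wrist_rotation <- function(profiles, subject_id, rotation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (abs(det(rotation) - 1) > 1e-6) abort("rotation must have determinant +1")
  i <- match(subject_id, profiles$subject_id)
  if (is.na(i)) abort(sprintf("unknown subject '%s'", subject_id))
  profiles$wrist_rotation[[i]] <- rotation
  profiles
}

validate_profile <- function(p) {
  R <- p$wrist_rotation[[1]]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    abort("wrist_rotation must be orthonormal with determinant +1")
  }
  for (f in c("gravity_computer_table", "gravity_standing_still")) {
    if (abs(sqrt(sum(p[[f]][[1]]^2)) - 1) > 1e-6) abort(sprintf("%s must be unit norm", f))
  }
  assert_prob(p$labeling_bias, "labeling_bias")
  assert_positive(p$noise_sd_g, "noise_sd_g")
  invisible(p)
}

# Split one activity's target duration into bout lengths.
draw_bouts <- function(total_s, mode, bout_range_s, controlled_bout_s) {
  if (mode == "controlled") {
    n_full <- floor(total_s / controlled_bout_s)
    rest <- total_s - n_full * controlled_bout_s
    out <- rep(controlled_bout_s, n_full)
    if (rest > 1e-9) out <- c(out, rest)
    return(out)
  }
  out <- numeric(0)
  remaining <- total_s
  while (remaining > 0) {
    len <- min(remaining, runif(1, bout_range_s[1], bout_range_s[2]))
    if (remaining - len < 20) len <- remaining  # avoid trailing slivers
    out <- c(out, len)
    remaining <- remaining - len
  }
  out
}

# Synthesize the un-rotated 3xN signal template for one bout.
bout_template <- function(activity, t_rel, profile, rng_phases) {
  spec <- activity_signal_spec(activity)
  gvec <- switch(activity,
    computer_table = profile$gravity_computer_table[[1]],
    standing_still = profile$gravity_standing_still[[1]],
    normalize3(spec$gravity)
  )
  n <- length(t_rel)
  sig <- matrix(gvec, nrow = 3, ncol = n)
  amp <- profile[[paste0("amp_", activity)]]
  if (is_locomotion(activity)) {
    f <- profile[[paste0("cadence_", activity)]]
    weights <- c(1, 0.4, 0.15)
    for (h in 1:3) {
      osc <- sin(2 * pi * h * f * t_rel + rng_phases[h])
      sig <- sig + (amp * weights[h]) * (spec$mix %o% osc)
    }
    if (activity == "cycling") {
      # hands on the handlebar: little arm swing, but broadband road/frame
      # vibration whose frequency scales with pedalling speed
      vib <- sin(2 * pi * 8 * f * t_rel + rng_phases[2])
      sig <- sig + (0.5 * amp) * (c(0.8, 0.8, 0.8) %o% vib)
    }
  } else {
    osc <- sin(2 * pi * spec$freq * t_rel + rng_phases[1])
    sig <- sig + amp * (spec$mix %o% osc)
  }
  sig
}

#' Generate a synthetic multi-participant cohort
#'
#' Produces, per subject, a triaxial accelerometer stream (in g) and two
#' label timelines: the noisy self-report and the exact ground truth. Each
#' activity bout is the sum of a gravity component (the activity's posture
#' gravity, ~1 g), a periodic component at the subject's cadence (three
#' harmonics with relative amplitudes 1 / 0.4 / 0.15 for locomotion; one
#' small slow oscillation for static activities) and white noise; the whole
#' signal is then rotated by the subject's wrist orientation. Real-world
#' mode additionally inserts activity interruptions (5-30 s of another
#' activity inside a bout, absorbed into the surrounding self-report label
#' with the subject's labeling bias), boundary jitter, overlapping labels and
#' sensor gaps. Controlled mode emits exact-duration uninterrupted bouts with
#' zero label noise and no gaps.
#'
#' @param config A [cohort_config()].
#' @param profiles Optional [subject_profiles()] tibble; drawn from the
#'   config seed when omitted.
#' @return A list of class `har_cohort` with elements `streams` (named list
#'   of tibbles `timestamp_s, x_g, y_g, z_g`), `self_report` and
#'   `ground_truth` (tibbles `subject, start_s, end_s, activity`), `profiles`
#'   and `config`.
#' @export
generate_cohort <- function(config, profiles = NULL) {
  if (!inherits(config, "har_config")) abort("`config` must come from cohort_config()")
  n <- config$n_subjects
  seeds <- derive_seeds(config$seed, n + 1L)
  if (is.null(profiles)) {
    profiles <- subject_profiles(n, mode = config$mode, seed = seeds[1])
  }
  if (nrow(profiles) != n) abort("profiles must have one row per subject")
  streams <- list(); self_rep <- list(); truth <- list()
  for (i in seq_len(n)) {
    prof <- profiles[i, ]
    validate_profile(prof)
    sub <- with_seed(seeds[i + 1L], generate_subject(prof, config))
    streams[[prof$subject_id]] <- sub$stream
    self_rep[[i]] <- sub$self_report
    truth[[i]] <- sub$ground_truth
  }
  structure(list(
    streams = streams,
    self_report = dplyr::bind_rows(self_rep),
    ground_truth = dplyr::bind_rows(truth),
    profiles = profiles, config = config
  ), class = "har_cohort")
}

#' @export
print.har_cohort <- function(x, ...) {
  cat(sprintf("<har_cohort> %s mode, %d subjects, %.0f Hz\n",
              x$config$mode, x$config$n_subjects, x$config$sampling_rate))
  d <- x$ground_truth
  cat(sprintf("  labeled time: %.1f h ground truth, %.1f h self-report\n",
              sum(d$end_s - d$start_s) / 3600,
              sum(x$self_report$end_s - x$self_report$start_s) / 3600))
  invisible(x)
}

generate_subject <- function(prof, config) {
  rate <- config$sampling_rate
  acts <- names(config$activity_minutes)
  t0 <- config$start_time +
    if (config$mode == "real_world") runif(1, 0, config$start_spread_s) else 0
  # snap start to the sample grid so timestamps are exact multiples of 1/rate
  t0 <- round(t0 * rate) / rate

  # --- bout schedule -------------------------------------------------------
  bouts <- purrr::map(acts, function(a) {
    tibble(activity = a,
           dur = draw_bouts(config$activity_minutes[[a]] * 60, config$mode,
                            config$bout_range_s, config$controlled_bout_s))
  })
  bouts <- dplyr::bind_rows(bouts)
  if (config$mode == "real_world") bouts <- bouts[sample.int(nrow(bouts)), ]
  pause <- if (config$mode == "real_world") {
    runif(nrow(bouts), 10, 60)
  } else rep(5, nrow(bouts))
  # snap bout durations and pauses to whole samples
  bouts$dur <- round(bouts$dur * rate) / rate
  pause <- round(pause * rate) / rate
  start <- t0 + c(0, cumsum(bouts$dur + pause))[seq_len(nrow(bouts))]
  bouts$start <- start
  bouts$end <- start + bouts$dur

  # --- interruptions (ground truth granularity) ---------------------------
  segments <- list()   # true activity segments, contiguous inside each bout
  reported <- list()   # self-report intervals before jitter/overlap noise
  for (b in seq_len(nrow(bouts))) {
    act <- bouts$activity[b]; bs <- bouts$start[b]; be <- bouts$end[b]
    ints <- tibble(start = numeric(0), end = numeric(0), activity = character(0))
    if (config$mode == "real_world" && prof$interruption_rate > 0) {
      n_int <- stats::rpois(1, prof$interruption_rate * (be - bs) / 60)
      if (n_int > 0) {
        s <- sort(runif(n_int, bs + 10, max(bs + 10, be - 40)))
        d <- runif(n_int, 5, 30)
        keep <- rep(TRUE, n_int)
        last_end <- -Inf
        for (j in seq_len(n_int)) {
          e <- min(s[j] + d[j], be - 5)
          if (s[j] <= last_end || e <= s[j]) { keep[j] <- FALSE; next }
          d[j] <- e - s[j]; last_end <- e
        }
        s <- s[keep]; d <- d[keep]
        if (length(s)) {
          ints <- tibble(start = round(s * rate) / rate,
                         end = round((s + d) * rate) / rate,
                         activity = sample(setdiff(har_activities(), act),
                                           length(s), replace = TRUE))
        }
      }
    }
    # true segments: bout carved around interruptions
    cuts <- rbind(tibble(start = bs, end = be, activity = act))
    if (nrow(ints)) {
      segs <- list(); cur <- bs
      for (j in seq_len(nrow(ints))) {
        if (ints$start[j] > cur) segs[[length(segs) + 1]] <- c(cur, ints$start[j])
        cur <- ints$end[j]
      }
      if (cur < be) segs[[length(segs) + 1]] <- c(cur, be)
      cuts <- dplyr::bind_rows(
        purrr::map(segs, ~tibble(start = .x[1], end = .x[2], activity = act)),
        ints
      )
      cuts <- cuts[order(cuts$start), ]
    }
    segments[[b]] <- cuts
    # self-report: each interruption absorbed with prob labeling_bias
    if (nrow(ints) == 0) {
      reported[[b]] <- tibble(start = bs, end = be, activity = act)
    } else {
      absorbed <- runif(nrow(ints)) < prof$labeling_bias
      vis <- ints[!absorbed, , drop = FALSE]
      if (nrow(vis) == 0) {
        reported[[b]] <- tibble(start = bs, end = be, activity = act)
      } else {
        segs <- list(); cur <- bs
        for (j in seq_len(nrow(vis))) {
          if (vis$start[j] > cur) segs[[length(segs) + 1]] <- tibble(
            start = cur, end = vis$start[j], activity = act)
          segs[[length(segs) + 1]] <- vis[j, ]
          cur <- vis$end[j]
        }
        if (cur < be) segs[[length(segs) + 1]] <- tibble(start = cur, end = be, activity = act)
        reported[[b]] <- dplyr::bind_rows(segs)
      }
    }
  }
  truth <- dplyr::bind_rows(segments)
  report <- dplyr::bind_rows(reported)

  # --- self-report noise ---------------------------------------------------
  if (config$mode == "real_world") {
    report <- jitter_boundaries(report, config$boundary_jitter_sd_s)
    if (config$mislabel_prob > 0) {
      flip <- runif(nrow(report)) < config$mislabel_prob
      if (any(flip)) {
        report$activity[flip] <- vapply(report$activity[flip], function(a) {
          sample(setdiff(har_activities(), a), 1)
        }, character(1))
      }
    }
    if (config$overlap_prob > 0 && nrow(report) > 1) {
      for (j in seq_len(nrow(report) - 1)) {
        if (runif(1) < config$overlap_prob) {
          ext <- runif(1, 2, 15)
          report$end[j] <- min(report$start[j + 1] + ext,
                               report$end[j + 1] - 0.5)
          report$end[j] <- max(report$end[j], report$start[j] + 0.5)
        }
      }
    }
  }

  # --- signal synthesis ----------------------------------------------------
  span_end <- max(bouts$end) + 10
  n_samp <- floor((span_end - t0) * rate) + 1
  ts <- t0 + (seq_len(n_samp) - 1) / rate
  sig <- matrix(0, nrow = 3, ncol = n_samp)
  sig[] <- prof$gravity_standing_still[[1]]      # idle filler between bouts
  sig <- sig + matrix(rnorm(3 * n_samp, 0, prof$noise_sd_g), 3, n_samp)
  for (j in seq_len(nrow(truth))) {
    idx <- which(ts >= truth$start[j] - 1e-9 & ts < truth$end[j] - 1e-9)
    if (!length(idx)) next
    phases <- runif(3, 0, 2 * pi)
    tmpl <- bout_template(truth$activity[j], ts[idx] - truth$start[j], prof, phases)
    sig[, idx] <- tmpl + matrix(rnorm(3 * length(idx), 0, prof$noise_sd_g),
                                3, length(idx))
  }
  sig <- prof$wrist_rotation[[1]] %*% sig

  # --- sensor gaps ---------------------------------------------------------
  keep <- rep(TRUE, n_samp)
  if (config$gap_rate > 0) {
    n_gap <- stats::rpois(1, config$gap_rate * (span_end - t0) / 3600)
    if (n_gap > 0) {
      gs <- runif(n_gap, t0, span_end)
      gd <- runif(n_gap, 30, 180)
      for (j in seq_len(n_gap)) keep[ts >= gs[j] & ts < gs[j] + gd[j]] <- FALSE
    }
  }
  stream <- tibble(timestamp_s = ts[keep],
                   x_g = sig[1, keep], y_g = sig[2, keep], z_g = sig[3, keep])
  attr(stream, "subject_id") <- prof$subject_id
  attr(stream, "rate") <- rate

  list(
    stream = stream,
    self_report = tibble(subject = prof$subject_id, start_s = report$start,
                         end_s = report$end, activity = report$activity),
    ground_truth = tibble(subject = prof$subject_id, start_s = truth$start,
                          end_s = truth$end, activity = truth$activity)
  )
}

# Jitter interval boundaries without creating overlaps: boundaries shared by
# contiguous intervals move jointly; free boundaries are clamped to their
# neighbours.
jitter_boundaries <- function(report, sd_s) {
  if (sd_s <= 0 || nrow(report) == 0) return(report)
  n <- nrow(report)
  start <- report$start; end <- report$end
  for (j in seq_len(n)) {
    if (j == 1 || end[j - 1] < start[j] - 1e-9) {
      lo <- if (j == 1) -Inf else end[j - 1]
      start[j] <- max(lo, min(start[j] + rnorm(1, 0, sd_s), end[j] - 1))
    }
    shared <- j < n && abs(end[j] - start[j + 1]) < 1e-9
    hi <- if (j == n) Inf else report$start[j + 1] + if (shared) Inf else 0
    newe <- end[j] + rnorm(1, 0, sd_s)
    newe <- max(newe, start[j] + 1)
    if (shared) {
      newe <- min(newe, report$end[j + 1] - 1)
      end[j] <- newe; start[j + 1] <- newe
    } else {
      end[j] <- min(newe, hi)
    }
  }
  report$start <- start; report$end <- end
  report
}

#' Write a cohort to CSV files
#'
#' One stream CSV (`timestamp_s,x_g,y_g,z_g`) and one label CSV
#' (`start_s,end_s,activity`, half-open intervals) per subject, plus a JSON
#' manifest listing paths and row counts. Ground-truth timelines are written
#' alongside with a `_truth` suffix.
#'
#' @param cohort A `har_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(names(cohort$streams), function(id) {
    sp <- file.path(dir, paste0(id, "_stream.csv"))
    lp <- file.path(dir, paste0(id, "_labels.csv"))
    tp <- file.path(dir, paste0(id, "_labels_truth.csv"))
    ok <- tryCatch({
      utils::write.csv(cohort$streams[[id]], sp, row.names = FALSE)
      lab <- cohort$self_report[cohort$self_report$subject == id,
                                c("start_s", "end_s", "activity")]
      utils::write.csv(lab, lp, row.names = FALSE)
      tru <- cohort$ground_truth[cohort$ground_truth$subject == id,
                                 c("start_s", "end_s", "activity")]
      utils::write.csv(tru, tp, row.names = FALSE)
      TRUE
    }, error = function(e) abort(sprintf("failed writing files for %s under %s: %s",
                                         id, dir, conditionMessage(e))))
    tibble(subject_id = id, stream_path = sp, labels_path = lp,
           n_rows = nrow(cohort$streams[[id]]))
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the manifest.
#' @return A list with `streams`, `self_report` and `ground_truth`.
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (length(mf) == 0) {
    return(list(streams = list(), self_report = tibble(), ground_truth = tibble()))
  }
  streams <- list(); self_rep <- list(); truth <- list()
  for (i in seq_len(nrow(mf))) {
    id <- mf$subject_id[i]
    streams[[id]] <- as_tibble(utils::read.csv(mf$stream_path[i]))
    lab <- as_tibble(utils::read.csv(mf$labels_path[i]))
    self_rep[[i]] <- dplyr::mutate(lab, subject = id, .before = 1)
    tp <- sub("_labels\\.csv$", "_labels_truth.csv", mf$labels_path[i])
    if (file.exists(tp)) {
      truth[[i]] <- dplyr::mutate(as_tibble(utils::read.csv(tp)), subject = id, .before = 1)
    }
  }
  list(streams = streams,
       self_report = dplyr::bind_rows(self_rep),
       ground_truth = dplyr::bind_rows(truth))
}
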