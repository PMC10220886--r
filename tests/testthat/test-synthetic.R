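test_that("controlled mode emits exact uninterrupted bouts with no label noise", {
  cfg <- cohort_config("controlled", n_subjects = 10,
                       activity_minutes = setNames(rep(1, 4),
                                                   har_activities_controlled()),
                       seed = 3L)
  co <- generate_cohort(cfg)
  for (sub in unique(co$self_report$subject)) {
    tl <- co$self_report[co$self_report$subject == sub, ]
    expect_equal(sum(tl$end_s - tl$start_s), 240)   # 4 x 1 min exactly
    tl <- tl[order(tl$start_s), ]
    expect_true(all(tl$start_s[-1] >= tl$end_s[-nrow(tl)]))  # zero overlaps
  }
  expect_equal(co$self_report, co$ground_truth)
  expect_equal(cfg$sampling_rate, 50)
})

test_that("with noise sources disabled the self-report equals the ground truth", {
  cfg <- cohort_config("real_world", n_subjects = 2,
                       activity_minutes = c(walking = 3, cycling = 3),
                       overlap_prob = 0, boundary_jitter_sd_s = 0,
                       mislabel_prob = 0, gap_rate = 0, seed = 5L)
  profs <- subject_profiles(2, "real_world", seed = 1L)
  profs$interruption_rate <- 0
  co <- generate_cohort(cfg, profiles = profs)
  expect_equal(co$self_report, co$ground_truth)
})

test_that("generation is bitwise deterministic in the seed", {
  cfg <- cohort_config("real_world", n_subjects = 2,
                       activity_minutes = c(walking = 2, running = 2),
                       seed = 17L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$streams, b$streams)
  expect_identical(a$self_report, b$self_report)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("locomotion bouts peak at the subject's cadence", {
  cfg <- cohort_config("real_world", n_subjects = 1,
                       activity_minutes = c(walking = 4),
                       overlap_prob = 0, boundary_jitter_sd_s = 0,
                       mislabel_prob = 0, gap_rate = 0, seed = 23L)
  profs <- subject_profiles(1, "real_world", seed = 1L)
  profs$interruption_rate <- 0
  co <- generate_cohort(cfg, profiles = profs)
  st <- co$streams$S01
  gt <- co$ground_truth[order(co$ground_truth$start_s), ]
  iv <- gt[which.max(gt$end_s - gt$start_s), ]
  seg <- st[st$timestamp_s >= iv$start_s & st$timestamp_s < iv$end_s, ]
  # periodogram argmax over the dominant axis, DC excluded
  v <- seg$y_g - mean(seg$y_g)
  n <- length(v)
  pw <- Mod(stats::fft(v))^2
  freqs <- (seq_len(floor(n / 2)) ) * 32 / n
  peak <- freqs[which.max(pw[2:(floor(n / 2) + 1)])]
  expect_lt(abs(peak - profs$cadence_walking[1]), 0.1)
})

test_that("static bouts sit near 1 g and undoing the wrist rotation recovers the template", {
  cfg <- cohort_config("real_world", n_subjects = 1,
                       activity_minutes = c(standing_still = 3),
                       gap_rate = 0, seed = 29L)
  profs <- subject_profiles(1, "real_world", seed = 2L)
  co <- generate_cohort(cfg, profiles = profs)
  st <- co$streams$S01
  gt <- co$ground_truth
  iv <- gt[which.max(gt$end_s - gt$start_s), ]
  seg <- st[st$timestamp_s >= iv$start_s & st$timestamp_s < iv$end_s, ]
  norms <- sqrt(seg$x_g^2 + seg$y_g^2 + seg$z_g^2)
  expect_lt(abs(mean(norms) - 1), 0.05)
  # identical seed with the rotation replaced by the identity gives exactly
  # R^{-1} times the rotated stream
  profs_id <- set_wrist_rotation(profs, "S01", diag(3))
  co_id <- generate_cohort(cfg, profiles = profs_id)
  R <- profs$wrist_rotation[[1]]
  rotated <- as.matrix(co$streams$S01[c("x_g", "y_g", "z_g")])
  template <- as.matrix(co_id$streams$S01[c("x_g", "y_g", "z_g")])
  expect_equal(rotated %*% R, template, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("overlap frequency tracks the configured probability", {
  n_pairs <- 0; n_overlaps <- 0
  p <- 0.15
  for (seed in 1:6) {
    cfg <- cohort_config("real_world", n_subjects = 3,
                         activity_minutes = c(computer_table = 8,
                                              standing_still = 6, walking = 6,
                                              running = 6, cycling = 6),
                         overlap_prob = p, boundary_jitter_sd_s = 0,
                         mislabel_prob = 0, gap_rate = 0, seed = seed)
    co <- generate_cohort(cfg)
    for (sub in unique(co$self_report$subject)) {
      tl <- co$self_report[co$self_report$subject == sub, ]
      tl <- tl[order(tl$start_s), ]
      ov <- tl$end_s[-nrow(tl)] > tl$start_s[-1] + 1e-9
      n_pairs <- n_pairs + length(ov)
      n_overlaps <- n_overlaps + sum(ov)
    }
  }
  expect_gt(n_pairs, 200)
  ci <- stats::qbinom(c(0.005, 0.995), n_pairs, p)
  expect_gte(n_overlaps, ci[1])
  expect_lte(n_overlaps, ci[2])
})

test_that("cohorts round-trip through CSV and the manifest counts rows", {
  cfg <- cohort_config("real_world", n_subjects = 1,
                       activity_minutes = c(walking = 2), gap_rate = 0,
                       seed = 31L)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  mf <- write_cohort(co, dir)
  expect_equal(mf$n_rows, nrow(co$streams$S01))
  back <- read_cohort(dir)
  expect_equal(back$streams$S01$timestamp_s, co$streams$S01$timestamp_s,
               tolerance = 1e-9)
  expect_equal(back$streams$S01$x_g, co$streams$S01$x_g, tolerance = 1e-9)
  expect_equal(back$self_report$activity, co$self_report$activity)
  expect_equal(back$self_report$start_s, co$self_report$start_s,
               tolerance = 1e-9)
})

test_that("a 10 s stream at 32 Hz writes 320 sample rows", {
  st <- gapless_stream(10)
  co <- structure(list(streams = list(S01 = st),
                       self_report = tibble::tibble(
                         subject = "S01", start_s = 0, end_s = 10,
                         activity = "walking"),
                       ground_truth = tibble::tibble(
                         subject = "S01", start_s = 0, end_s = 10,
                         activity = "walking")),
                  class = "har_cohort")
  dir <- withr::local_tempdir()
  mf <- write_cohort(co, dir)
  expect_equal(mf$n_rows, 320)
  raw <- readLines(file.path(dir, "S01_stream.csv"))
  expect_length(raw, 321)    # header + data rows
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_subjects = 0), "positive")
  expect_error(cohort_config(activity_minutes = c(walking = -1)), "positive")
  expect_error(cohort_config(overlap_prob = 1.5), "probability")
})
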