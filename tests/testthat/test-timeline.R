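test_that("partial overlaps are excised from both intervals", {
  tl <- tibble::tibble(start_s = c(0, 80), end_s = c(100, 150),
                       activity = c("walk", "sit"))
  out <- correct_overlaps(tl)
  expect_equal(out$timeline$start_s, c(0, 100))
  expect_equal(out$timeline$end_s, c(80, 150))
  expect_equal(out$timeline$activity, c("walk", "sit"))
  # both intervals lose the 20 s contested range
  expect_equal(out$discarded_s, 40)
})

test_that("nested intervals truncate the encloser and drop the nested one", {
  tl <- tibble::tibble(start_s = c(0, 50), end_s = c(200, 70),
                       activity = c("sit", "walk"))
  out <- correct_overlaps(tl)
  expect_equal(nrow(out$timeline), 1)
  expect_equal(out$timeline$start_s, 0)
  expect_equal(out$timeline$end_s, 50)
  expect_equal(out$timeline$activity, "sit")
})

test_that("touching half-open intervals are left alone", {
  tl <- tibble::tibble(start_s = c(0, 60), end_s = c(60, 120),
                       activity = c("walk", "sit"))
  out <- correct_overlaps(tl)
  expect_equal(out$timeline$start_s, c(0, 60))
  expect_equal(out$timeline$end_s, c(60, 120))
  expect_equal(nrow(out$log), 0)
})

test_that("identical spans with different labels are both removed", {
  tl <- tibble::tibble(start_s = c(10, 10), end_s = c(50, 50),
                       activity = c("walk", "sit"))
  out <- correct_overlaps(tl)
  expect_equal(nrow(out$timeline), 0)
  expect_equal(out$discarded_s, 80)
})

test_that("invalid intervals are rejected with a pointer to the offender", {
  tl <- tibble::tibble(start_s = c(0, 30), end_s = c(10, 20),
                       activity = c("walk", "sit"))
  expect_error(correct_overlaps(tl), "row 2")
})

test_that("correction is idempotent and conserves duration minus the log", {
  set.seed(42)
  for (rep in 1:50) {
    tl <- random_timeline()
    out <- correct_overlaps(tl)
    again <- correct_overlaps(out$timeline)
    expect_equal(again$timeline, out$timeline, ignore_attr = TRUE)
    expect_equal(nrow(again$log), 0)
    before <- sum(tl$end_s - tl$start_s)
    after <- sum(out$timeline$end_s - out$timeline$start_s)
    expect_equal(before - after, out$discarded_s, tolerance = 1e-9)
  }
})

test_that("correction matches the sequential-rules oracle per second", {
  set.seed(7)
  for (rep in 1:100) {
    tl <- random_timeline()
    out <- correct_overlaps(tl)$timeline
    ref <- oracle_correct(tl)
    got <- per_second_labels(out, 400)
    want <- per_second_labels(ref, 400)
    expect_identical(got, want)
    # no second carries two activities after cleaning
    iv <- out[order(out$start_s), ]
    if (nrow(iv) > 1) {
      expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)] - 1e-9))
    }
  }
})

test_that("per-activity durations sum correctly and report zeros", {
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          activity = character(0))
  d0 <- durations_by_activity(empty, vocabulary = c("walk", "sit"))
  expect_equal(d0$seconds, c(0, 0))
  tl <- tibble::tibble(start_s = c(0, 200), end_s = c(100, 300),
                       activity = c("walk", "walk"))
  d <- durations_by_activity(tl)
  expect_equal(d$seconds[d$activity == "walk"], 200)
})

test_that("cleaning never increases any activity's duration", {
  set.seed(3)
  for (rep in 1:20) {
    tl <- random_timeline()
    out <- correct_overlaps(tl)$timeline
    vocab <- unique(tl$activity)
    pre <- durations_by_activity(tl, vocab)
    post <- durations_by_activity(out, vocab)
    expect_true(all(post$seconds <= pre$seconds + 1e-9))
  }
})

test_that("usable sensor duration counts only sample-covered seconds", {
  st <- gapless_stream(100)
  tl <- tibble::tibble(start_s = 0, end_s = 100, activity = "walk")
  u <- usable_sensor_duration(tl, st, rate = 32)
  expect_equal(u$seconds, 100)
  # carve a 40 s gap out of the middle
  st_gap <- st[st$timestamp_s < 30 | st$timestamp_s >= 70, ]
  attr(st_gap, "rate") <- 32
  u2 <- usable_sensor_duration(tl, st_gap, rate = 32)
  expect_equal(u2$seconds, 60)
  # no samples at all
  st_empty <- st[0, ]; attr(st_empty, "rate") <- 32
  u3 <- usable_sensor_duration(tl, st_empty, rate = 32)
  expect_equal(u3$seconds, 0)
})
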