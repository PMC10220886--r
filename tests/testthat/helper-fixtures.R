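# Shared fixtures, built once per test run.

gapless_stream <- function(dur_s, rate = 32, value = c(0, 0, 1)) {
  n <- round(dur_s * rate)
  s <- tibble::tibble(timestamp_s = (seq_len(n) - 1) / rate,
                      x_g = rep(value[1], n), y_g = rep(value[2], n),
                      z_g = rep(value[3], n))
  attr(s, "rate") <- rate
  attr(s, "subject_id") <- "S01"
  s
}

# A small real-world cohort reused across several test files.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config("real_world", n_subjects = 3,
                           activity_minutes = c(computer_table = 5,
                                                standing_still = 4,
                                                walking = 4, running = 4,
                                                cycling = 4),
                           seed = 101L)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

small_budget <- function() {
  personalization_budget(computer_table = 2, cycling = 1.5, running = 1.5,
                         standing_still = 1.5, walking = 1.5, gap_min = 0.25)
}

small_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- prepare_cohort(small_cohort(), budget = small_budget(),
                               n_chunks = 2)
    }
    cache
  }
})

tiny_arch <- function() cnn_architecture(channels = c(4, 4, 6, 6, 6, 8, 8))

# Two trivially separable synthetic classes of 3 x 384 windows.
separable_windows <- function(n_per_class = 100, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  arr <- array(rnorm(3 * 384 * n, 0, 0.05), c(3, 384, n))
  t_ <- (0:383) / 32
  for (i in seq_len(n_per_class)) {
    arr[1, , i] <- arr[1, , i] + sin(2 * pi * 2 * t_)          # class A: 2 Hz
    arr[1, , n_per_class + i] <- arr[1, , n_per_class + i] + 1 # class B: static
  }
  idx <- tibble::tibble(window_id = seq_len(n), subject = "S01",
                        activity = rep(c("move", "still"), each = n_per_class),
                        start_s = seq_len(n) * 6, interval_id = 1L,
                        offset_s = seq_len(n) * 6)
  structure(list(array = arr, index = idx,
                 durations = tibble::tibble(subject = "S01",
                                            activity = c("move", "still"),
                                            seconds = c(600, 600)),
                 rate = 32, window_s = 12, stride_s = 6,
                 vocabulary = c("move", "still")),
            class = "har_windows")
}
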