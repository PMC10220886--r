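#' Correct overlapping self-report label intervals
#'
#' Self-reported activity intervals routinely overlap: the participant picked
#' a wrong time or forgot to close a previous label, so one span of time ends
#' up labeled with two activities. Since true multi-labeling is implausible
#' for these activities, overlaps are resolved deterministically by a
#' left-to-right sweep in start-time order, re-checking each newly edited
#' pair:
#'
#' * **Partial overlap** - the earlier interval's end is moved back to the
#'   later interval's original start, and the later interval's start is moved
#'   forward to the earlier interval's original end: the contested time range
#'   is excised from both.
#' * **Full nesting** - the enclosing (longer) interval's end is restricted
#'   to the nested (shorter) interval's start and the nested interval is
#'   removed entirely.
#' * **Identical spans** (a tie the longer/shorter rule cannot break) - both
#'   intervals are removed.
#'
#' Zero-length results are dropped. Intervals are half-open `[start, end)`,
#' so touching intervals never count as overlapping.
#'
#' @param timeline A tibble with columns `start_s`, `end_s`, `activity`, and
#'   optionally `subject` (corrected per subject).
#' @return A list of class `har_correction` with elements `timeline` (the
#'   corrected tibble, sorted by start), `log` (one row per edit: `rule`,
#'   `subject`, `activity`, `before_start`, `before_end`, `after_start`,
#'   `after_end`, `discarded_s`) and `discarded_s` (total labeled seconds
#'   removed).
#' @export
correct_overlaps <- function(timeline) {
  validate_timeline(timeline)
  if (!"subject" %in% names(timeline)) {
    out <- correct_overlaps_one(timeline, subject = NA_character_)
  } else {
    parts <- split(timeline, timeline$subject)
    fixed <- purrr::map(parts, function(tl) correct_overlaps_one(tl, tl$subject[1]))
    out <- list(
      timeline = dplyr::bind_rows(purrr::map(fixed, "timeline")),
      log = dplyr::bind_rows(purrr::map(fixed, "log"))
    )
  }
  if (!nrow(out$log)) {
    out$log <- tibble(rule = character(0), subject = character(0),
                      activity = character(0), before_start = numeric(0),
                      before_end = numeric(0), after_start = numeric(0),
                      after_end = numeric(0), discarded_s = numeric(0))
  }
  out$discarded_s <- sum(out$log$discarded_s)
  structure(out, class = "har_correction")
}

#' @export
print.har_correction <- function(x, ...) {
  cat(sprintf("<har_correction> %d intervals kept, %d edits, %.1f s discarded\n",
              nrow(x$timeline), nrow(x$log), x$discarded_s))
  invisible(x)
}

validate_timeline <- function(timeline) {
  need <- c("start_s", "end_s", "activity")
  if (!all(need %in% names(timeline))) {
    abort("timeline needs columns start_s, end_s, activity")
  }
  bad <- which(!(timeline$start_s < timeline$end_s) | is.na(timeline$activity) |
                 !nzchar(timeline$activity))
  if (length(bad)) {
    abort(sprintf("invalid interval at row %d: [%s, %s) '%s'",
                  bad[1], format(timeline$start_s[bad[1]]),
                  format(timeline$end_s[bad[1]]), timeline$activity[bad[1]]))
  }
  invisible(timeline)
}

correct_overlaps_one <- function(timeline, subject) {
  iv <- timeline[order(timeline$start_s, timeline$end_s), ]
  log <- list()
  note <- function(rule, act, bs, be, as_, ae) {
    log[[length(log) + 1]] <<- tibble(
      rule = rule, subject = subject, activity = act,
      before_start = bs, before_end = be, after_start = as_, after_end = ae,
      discarded_s = (be - bs) - (if (is.na(as_)) 0 else ae - as_)
    )
  }
  i <- 1L
  while (i < nrow(iv)) {
    a <- iv[i, ]; b <- iv[i + 1L, ]
    if (b$start_s >= a$end_s - 1e-12) { i <- i + 1L; next }
    if (abs(a$start_s - b$start_s) < 1e-12 && abs(a$end_s - b$end_s) < 1e-12) {
      # identical spans: remove both
      note("tie", a$activity, a$start_s, a$end_s, NA_real_, NA_real_)
      note("tie", b$activity, b$start_s, b$end_s, NA_real_, NA_real_)
      iv <- iv[-c(i, i + 1L), ]
    } else if (abs(a$start_s - b$start_s) < 1e-12) {
      # shared start, different ends: the earlier-sorted (shorter) interval is
      # nested in the longer; restricting the longer's end to the nested
      # start empties it, so both go
      note("nested", b$activity, b$start_s, b$end_s, NA_real_, NA_real_)
      note("nested", a$activity, a$start_s, a$end_s, NA_real_, NA_real_)
      iv <- iv[-c(i, i + 1L), ]
    } else if (b$end_s <= a$end_s + 1e-12) {
      # b nested inside a: restrict a's end to b's start, remove b
      note("nested", a$activity, a$start_s, a$end_s, a$start_s, b$start_s)
      note("nested", b$activity, b$start_s, b$end_s, NA_real_, NA_real_)
      iv$end_s[i] <- b$start_s
      iv <- iv[-(i + 1L), ]
      if (iv$end_s[i] - iv$start_s[i] < 1e-12) iv <- iv[-i, ]
    } else {
      # partial: excise the overlap from both
      a_end0 <- a$end_s; b_start0 <- b$start_s
      note("partial", a$activity, a$start_s, a_end0, a$start_s, b_start0)
      note("partial", b$activity, b_start0, b$end_s, a_end0, b$end_s)
      iv$end_s[i] <- b_start0
      iv$start_s[i + 1L] <- a_end0
      drop <- integer(0)
      if (iv$end_s[i] - iv$start_s[i] < 1e-12) drop <- c(drop, i)
      if (iv$end_s[i + 1L] - iv$start_s[i + 1L] < 1e-12) drop <- c(drop, i + 1L)
      if (length(drop)) iv <- iv[-drop, ]
    }
    iv <- iv[order(iv$start_s, iv$end_s), ]
    i <- max(1L, i - 1L)   # re-check the edited neighbourhood
  }
  list(timeline = iv, log = dplyr::bind_rows(log))
}

#' Total labeled duration per activity
#'
#' @param timeline A timeline tibble (`start_s`, `end_s`, `activity`,
#'   optional `subject`).
#' @param vocabulary Optional activity vocabulary; missing activities report
#'   0 s. Defaults to the activities present.
#' @param by_subject Also group by subject when a `subject` column exists.
#' @return A tibble with columns (`subject`,) `activity`, `seconds`.
#' @export
durations_by_activity <- function(timeline, vocabulary = NULL, by_subject = FALSE) {
  vocabulary <- vocabulary %||% sort(unique(timeline$activity))
  grp <- if (by_subject && "subject" %in% names(timeline)) c("subject", "activity") else "activity"
  got <- timeline |>
    dplyr::mutate(seconds = .data$end_s - .data$start_s) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(seconds = sum(.data$seconds), .groups = "drop")
  if (identical(grp, "activity")) {
    base <- tibble(activity = vocabulary)
    out <- dplyr::left_join(base, got, by = "activity")
  } else {
    base <- tidyr::expand_grid(subject = unique(timeline$subject), activity = vocabulary)
    out <- dplyr::left_join(base, got, by = c("subject", "activity"))
  }
  dplyr::mutate(out, seconds = dplyr::coalesce(.data$seconds, 0))
}

#' Labeled time actually covered by sensor samples
#'
#' Wearables disconnect; labeled time with no sensor data is unusable. For
#' each labeled interval this counts the whole seconds that contain the
#' expected number of samples for the nominal rate (each expected sample slot
#' must be matched by a recorded sample within a quarter sample period).
#'
#' @param timeline A cleaned timeline tibble for one subject.
#' @param stream A stream tibble (`timestamp_s`, ...) for the same subject.
#' @param rate Nominal sampling rate in Hz; taken from the stream's `rate`
#'   attribute when absent.
#' @param vocabulary Optional activity vocabulary for zero-filled rows.
#' @return A tibble `activity`, `seconds`.
#' @export
usable_sensor_duration <- function(timeline, stream, rate = NULL, vocabulary = NULL) {
  rate <- rate %||% attr(stream, "rate")
  if (is.null(rate)) abort("supply `rate` or a stream with a rate attribute")
  vocabulary <- vocabulary %||% sort(unique(timeline$activity))
  ts <- stream$timestamp_s
  grid0 <- if (length(ts)) ts[1] else 0
  out <- purrr::map(seq_len(nrow(timeline)), function(i) {
    s <- timeline$start_s[i]; e <- timeline$end_s[i]
    # anchor the expected-sample grid on the sensor's own sample phase
    s <- grid0 + ceiling((s - grid0) * rate - 1e-9) / rate
    if (length(ts) == 0 || e - s < 1) {
      return(tibble(activity = timeline$activity[i], seconds = 0))
    }
    n_sec <- floor(e - s)
    # index samples onto the interval's expected grid
    rel <- ts[ts >= s - 1e-9 & ts < s + n_sec - 1e-9] - s
    slot <- round(rel * rate)
    ok <- abs(rel - slot / rate) <= 1 / (4 * rate)
    slot <- unique(slot[ok & slot >= 0 & slot < n_sec * rate])
    per_sec <- tabulate(floor(slot / rate) + 1, nbins = n_sec)
    tibble(activity = timeline$activity[i], seconds = sum(per_sec == rate))
  })
  got <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$activity) |>
    dplyr::summarise(seconds = sum(.data$seconds), .groups = "drop")
  base <- tibble(activity = vocabulary)
  dplyr::left_join(base, got, by = "activity") |>
    dplyr::mutate(seconds = dplyr::coalesce(.data$seconds, 0))
}

#' Write a correction log as JSON lines
#'
#' @param correction A `har_correction`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_correction_log <- function(correction, path) {
  lines <- vapply(seq_len(nrow(correction$log)), function(i) {
    jsonlite::toJSON(as.list(correction$log[i, ]), auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
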