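#' Per-activity personalization budgets
#'
#' The amount of each activity reserved (from the start of a participant's
#' data) for model personalization, the leakage gap dropped at the split
#' point, and the minimum hold-out requirement. Defaults are the full-scale
#' budgets: computer table 120 min, cycling/running/walking 10 min, standing
#' still 5 min, a 2 min gap, and at least half the budget again for testing.
#'
#' @param computer_table,cycling,running,standing_still,walking Budget
#'   minutes per activity.
#' @param gap_min Minutes discarded at the split point (leakage gap).
#' @param min_test_fraction Minimum hold-out labeled time as a fraction of
#'   the budget.
#' @return A list of class `har_budget`.
#' @export
personalization_budget <- function(computer_table = 120, cycling = 10,
                                   running = 10, standing_still = 5,
                                   walking = 10, gap_min = 2,
                                   min_test_fraction = 0.5) {
  b <- list(minutes = c(computer_table = computer_table, cycling = cycling,
                        running = running, standing_still = standing_still,
                        walking = walking),
            gap_min = gap_min, min_test_fraction = min_test_fraction)
  assert_positive(unlist(b), "budget")
  structure(b, class = "har_budget")
}

#' Scaled-down budgets for fast demonstrations
#'
#' Computer table 12 min, other activities 3 min, 30 s gap - small enough
#' that a full experiment grid runs in minutes on one CPU. The full-scale
#' budgets ([personalization_budget()]) remain the default for real data.
#'
#' @return A `har_budget`.
#' @export
demo_budget <- function() {
  personalization_budget(computer_table = 12, cycling = 3, running = 3,
                         standing_still = 3, walking = 3, gap_min = 0.5)
}

#' Split each participant's windows into personalization and hold-out sets
#'
#' Per subject and activity, the earliest windows (by cumulative labeled
#' time) filling the budget form the personalization set; windows starting in
#' the following leakage gap are discarded; the remainder is the hold-out
#' test set. An activity whose total labeled time is below
#' `budget + gap + min_test_fraction * budget` is excluded for that subject
#' (the gap counts toward neither side).
#'
#' @param windows A `har_windows` (possibly multi-subject, see
#'   [bind_windows()]).
#' @param budget A [personalization_budget()].
#' @return A partition plan tibble: `subject, activity, window_id, start_s,
#'   offset_s, role` with role in `personalization`, `gap`, `holdout`,
#'   `excluded`. Attribute `exclusions` lists excluded subject/activity
#'   pairs.
#' @export
split_personalization <- function(windows, budget = personalization_budget()) {
  unknown <- setdiff(windows$vocabulary, names(budget$minutes))
  if (length(unknown)) {
    abort(sprintf("no budget defined for activity '%s'", unknown[1]))
  }
  idx <- windows$index
  dur <- windows$durations
  gap_s <- budget$gap_min * 60
  plan <- idx |>
    dplyr::left_join(dur, by = c("subject", "activity")) |>
    dplyr::mutate(
      budget_s = budget$minutes[.data$activity] * 60,
      need_s = .data$budget_s + gap_s + budget$min_test_fraction * .data$budget_s,
      role = dplyr::case_when(
        .data$seconds < .data$need_s ~ "excluded",
        .data$offset_s + windows$window_s <= .data$budget_s ~ "personalization",
        .data$offset_s < .data$budget_s + gap_s ~ "gap",
        TRUE ~ "holdout"
      )
    ) |>
    dplyr::select("subject", "activity", "window_id", "start_s", "offset_s", "role")
  exclusions <- dur |>
    dplyr::mutate(need_s = budget$minutes[.data$activity] * 60 * (1 + budget$min_test_fraction) + gap_s) |>
    dplyr::filter(.data$seconds < .data$need_s) |>
    dplyr::select("subject", "activity", "seconds")
  attr(plan, "exclusions") <- exclusions
  attr(plan, "budget") <- budget
  plan
}

#' Assign every window to an absolute-time chunk
#'
#' The pooled collection span (over all participants) is cut into
#' `n_chunks` time-ordered pieces; the cut points are the same for every
#' participant, so participants who started late simply have empty early
#' chunks. Boundaries default to equal-duration bins over the pooled range of
#' window start times.
#'
#' @param plan A partition plan from [split_personalization()] (or any tibble
#'   with `window_id` and `start_s`).
#' @param n_chunks Number of chunks (default 8).
#' @param boundaries Optional increasing interior cut points (length
#'   `n_chunks - 1`, in seconds).
#' @return The plan with a `chunk` column (1-based).
#' @export
assign_chunks <- function(plan, n_chunks = 8, boundaries = NULL) {
  rng <- range(plan$start_s)
  if (is.null(boundaries)) {
    boundaries <- seq(rng[1], rng[2], length.out = n_chunks + 1)[-c(1, n_chunks + 1)]
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("chunk boundaries must be strictly increasing")
  }
  plan$chunk <- findInterval(plan$start_s, boundaries) + 1L
  attr(plan, "chunk_boundaries") <- boundaries
  plan
}

#' Window ids of a cumulative dataset (CDS)
#'
#' CDS k is the union of time-ordered chunks 1..k; the sets are nested and
#' grow with k. Excluded and gap windows never enter a CDS.
#'
#' @param plan A chunked partition plan ([assign_chunks()]).
#' @param k Chunk count, `1..max(chunk)`.
#' @return Integer vector of window ids.
#' @export
make_cds <- function(plan, k) {
  n_chunks <- max(plan$chunk)
  if (length(k) != 1 || k < 1 || k > n_chunks) {
    abort(sprintf("k must be in 1..%d", n_chunks))
  }
  plan$window_id[plan$chunk <= k & !plan$role %in% c("excluded", "gap")]
}

#' Leave-one-participant-out training set for one CDS
#'
#' The training pool for participant X's general model is CDS k minus X's
#' own windows. Participants with no windows in the CDS share the identical
#' full-CDS training set, flagged by a common `reuse_key` so the model is
#' trained once and reused.
#'
#' @param plan A chunked partition plan.
#' @param cds_k CDS index.
#' @param held_out_subject Subject whose data is removed.
#' @return A list with `window_ids`, `reuse_key`, and `empty` (TRUE when the
#'   training set has no windows).
#' @export
lopo_training_set <- function(plan, cds_k, held_out_subject) {
  if (!held_out_subject %in% plan$subject) {
    abort(sprintf("unknown subject '%s'", held_out_subject))
  }
  ids <- make_cds(plan, cds_k)
  own <- plan$window_id[plan$subject == held_out_subject]
  train <- setdiff(ids, own)
  key <- if (length(intersect(ids, own)) == 0) {
    sprintf("cds%d-full", cds_k)
  } else {
    sprintf("cds%d-minus-%s", cds_k, held_out_subject)
  }
  list(window_ids = train, reuse_key = key, empty = length(train) == 0)
}

#' Time-ordered prefix of a subject's personalization set
#'
#' For each activity, the earliest `floor(fraction * n)` personalization
#' windows. Prefixes nest: the 20% set is contained in the 40% set, and so
#' on.
#'
#' @param plan A partition plan.
#' @param subject Subject id.
#' @param fraction One of 0.2, 0.4, 0.6, 0.8, 1.0 (any value in (0, 1\] with
#'   `strict = FALSE`).
#' @param strict Enforce the canonical fraction grid.
#' @return Integer vector of window ids.
#' @export
personalization_fraction <- function(plan, subject, fraction, strict = TRUE) {
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  if (strict && !any(abs(fraction - grid) < 1e-9)) {
    abort("fraction must be one of 0.2, 0.4, 0.6, 0.8, 1.0 (or use strict = FALSE)")
  }
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  pers <- plan |>
    dplyr::filter(.data$subject == !!subject, .data$role == "personalization") |>
    dplyr::arrange(.data$activity, .data$offset_s)
  if (nrow(pers) == 0) {
    abort(sprintf("subject '%s' has no personalization windows", subject))
  }
  out <- pers |>
    dplyr::group_by(.data$activity) |>
    dplyr::filter(dplyr::row_number() <= floor(fraction * dplyr::n())) |>
    dplyr::ungroup()
  out$window_id
}

#' Write a partition plan as CSV
#' @param plan A partition plan tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_plan <- function(plan, path) {
  utils::write.csv(plan, path, row.names = FALSE)
  invisible(path)
}
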