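make_plan_fixture <- function() {
  # two subjects; S01 rich in everything, S02 missing computer_table
  st <- gapless_stream(9000)
  tl1 <- tibble::tibble(
    start_s = c(0, 7300, 7800, 8200, 8600),
    end_s = c(7260, 7760, 8160, 8560, 8960),
    activity = c("computer_table", "cycling", "running", "standing_still", "walking"))
  w1 <- segment_windows(st, tl1, subject = "S01",
                        vocabulary = har_activities())
  tl2 <- tibble::tibble(start_s = c(0, 1200), end_s = c(1100, 2350),
                        activity = c("cycling", "walking"))
  w2 <- segment_windows(st, tl2, subject = "S02",
                        vocabulary = har_activities())
  bind_windows(w1, w2)
}

test_that("personalization split honours budgets, gap and minimum-test rule", {
  ws <- make_plan_fixture()
  bud <- personalization_budget(computer_table = 120, cycling = 10,
                                running = 10, standing_still = 5,
                                walking = 10, gap_min = 2)
  plan <- split_personalization(ws, bud)
  # S01 computer_table: 121 min labeled < 120*1.5 + 2 -> excluded
  s1ct <- plan[plan$subject == "S01" & plan$activity == "computer_table", ]
  expect_true(all(s1ct$role == "excluded"))
  # S02 has no computer_table at all: no windows, listed as excluded pair
  expect_false(any(plan$subject == "S02" & plan$activity == "computer_table"))
  exc <- attr(plan, "exclusions")
  expect_true(any(exc$subject == "S02" & exc$activity == "computer_table"))
  # S02 cycling: 16 min labeled >= 10 + 2 + 5 -> split; personalization
  # windows are those fully inside the first 10 budget minutes
  s2cyc <- plan[plan$subject == "S02" & plan$activity == "cycling", ]
  expect_equal(sum(s2cyc$role == "personalization"), floor((600 - 12) / 6) + 1)
  expect_true(all(s2cyc$offset_s[s2cyc$role == "holdout"] >= 600 + 120))
  # personalization and hold-out never intersect
  expect_equal(intersect(s2cyc$window_id[s2cyc$role == "personalization"],
                         s2cyc$window_id[s2cyc$role == "holdout"]), integer(0))
})

test_that("a 120-min budget over gapless data yields 1199 personalization windows", {
  st <- gapless_stream(12000)
  tl <- tibble::tibble(start_s = 0, end_s = 7200 + 120 + 3600,
                       activity = "computer_table")
  ws <- segment_windows(st, tl, subject = "S14", vocabulary = har_activities())
  plan <- split_personalization(ws, personalization_budget())
  expect_equal(sum(plan$role == "personalization"), 1199)
})

test_that("an activity with exactly its budget and nothing more is excluded", {
  st <- gapless_stream(700)
  tl <- tibble::tibble(start_s = 0, end_s = 600, activity = "cycling")
  ws <- segment_windows(st, tl, subject = "S01", vocabulary = har_activities())
  plan <- split_personalization(ws, personalization_budget())
  expect_true(all(plan$role == "excluded"))
})

test_that("unknown activities in the dataset are rejected", {
  ws <- separable_windows(5)
  expect_error(split_personalization(ws, personalization_budget()),
               "no budget")
})

test_that("chunk assignment is monotone in time and shared across subjects", {
  ws <- make_plan_fixture()
  plan <- split_personalization(ws, small_budget())
  plan <- assign_chunks(plan, n_chunks = 8)
  expect_true(all(plan$chunk >= 1 & plan$chunk <= 8))
  for (sub in unique(plan$subject)) {
    p <- plan[plan$subject == sub, ]
    expect_true(all(diff(p$chunk[order(p$start_s)]) >= 0))
  }
  # custom boundaries equal to the default give the identical assignment
  b <- attr(plan, "chunk_boundaries")
  plan2 <- assign_chunks(split_personalization(ws, small_budget()),
                         n_chunks = 8, boundaries = b)
  expect_equal(plan2$chunk, plan$chunk)
  expect_error(assign_chunks(plan, boundaries = c(5, 3)), "increasing")
  # a subject starting late has empty early chunks
  s2 <- plan[plan$subject == "S02", ]
  s1 <- plan[plan$subject == "S01", ]
  expect_true(min(s1$chunk) <= min(s2$chunk) || min(s2$chunk) == 1)
})

test_that("cumulative datasets are nested and k is validated", {
  ws <- make_plan_fixture()
  plan <- assign_chunks(split_personalization(ws, small_budget()), n_chunks = 8)
  sizes <- integer(8)
  prev <- integer(0)
  for (k in 1:8) {
    ids <- make_cds(plan, k)
    expect_true(all(prev %in% ids))
    sizes[k] <- length(ids)
    prev <- ids
  }
  expect_true(all(diff(sizes) >= 0))
  keep <- plan[!plan$role %in% c("excluded", "gap"), ]
  expect_setequal(make_cds(plan, 8), keep$window_id)
  expect_error(make_cds(plan, 0), "must be in")
  expect_error(make_cds(plan, 9), "must be in")
})

test_that("LOPO sets exclude the held-out subject and share full-CDS reuse", {
  ws <- make_plan_fixture()
  plan <- assign_chunks(split_personalization(ws, small_budget()), n_chunks = 8)
  tr <- lopo_training_set(plan, 8, "S01")
  expect_false(any(tr$window_ids %in% plan$window_id[plan$subject == "S01"]))
  # find a chunk with no S02 windows: its LOPO set is the full CDS
  s2chunks <- unique(plan$chunk[plan$subject == "S02" &
                                  !plan$role %in% c("excluded", "gap")])
  k_empty <- seq_len(min(s2chunks) - 1)   # CDS k lacks S02 iff k < min chunk
  k_empty <- k_empty[vapply(k_empty, function(k)
    length(make_cds(plan, k)) > 0, logical(1))]
  if (length(k_empty)) {
    k <- min(k_empty)
    tr2 <- lopo_training_set(plan, k, "S02")
    expect_setequal(tr2$window_ids, make_cds(plan, k))
    expect_match(tr2$reuse_key, "full")
  }
  expect_error(lopo_training_set(plan, 1, "nobody"), "unknown subject")
  # union over subjects of LOPO sets at k = 8 covers CDS(8)
  u <- unique(c(lopo_training_set(plan, 8, "S01")$window_ids,
                lopo_training_set(plan, 8, "S02")$window_ids))
  expect_setequal(u, make_cds(plan, 8))
})

test_that("no window lands in both a LOPO training set and the owner's hold-out", {
  prep <- small_prep()
  plan <- prep$plan
  for (k in seq_len(max(plan$chunk))) {
    for (sub in unique(plan$subject)) {
      tr <- lopo_training_set(plan, k, sub)
      ho <- plan$window_id[plan$subject == sub & plan$role == "holdout"]
      expect_length(intersect(tr$window_ids, ho), 0)
    }
  }
})

test_that("hold-out time meets the minimum-test rule for retained activities", {
  prep <- small_prep()
  plan <- prep$plan
  bud <- small_budget()
  kept <- unique(plan[plan$role != "excluded", c("subject", "activity")])
  for (i in seq_len(nrow(kept))) {
    p <- plan[plan$subject == kept$subject[i] & plan$activity == kept$activity[i], ]
    dur <- prep$windows$durations
    d <- dur$seconds[dur$subject == kept$subject[i] &
                       dur$activity == kept$activity[i]]
    need <- bud$minutes[[kept$activity[i]]] * 60 * (1 + bud$min_test_fraction) +
      bud$gap_min * 60
    expect_gte(d, need)
  }
})

test_that("personalization fractions take nested time-ordered prefixes", {
  st <- gapless_stream(1300)
  tl <- tibble::tibble(start_s = 0, end_s = 1300, activity = "cycling")
  ws <- segment_windows(st, tl, subject = "S01", vocabulary = har_activities())
  bud <- personalization_budget(cycling = 10, gap_min = 1)
  plan <- split_personalization(ws, bud)
  expect_equal(sum(plan$role == "personalization"), 99)
  f02 <- personalization_fraction(plan, "S01", 0.2)
  expect_length(f02, 19)     # floor(0.2 * 99)
  prev <- integer(0)
  for (fr in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    ids <- personalization_fraction(plan, "S01", fr)
    expect_true(all(prev %in% ids))
    prev <- ids
  }
  expect_length(personalization_fraction(plan, "S01", 1.0), 99)
  expect_error(personalization_fraction(plan, "S01", 0.3), "0.2")
  expect_length(personalization_fraction(plan, "S01", 0.3, strict = FALSE), 29)
})
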