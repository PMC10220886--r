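# End-to-end orchestration: cohort -> cleaned timelines -> windows ->
# partition plan -> general / personalized / cross-context model grids.

#' Prepare a cohort for modelling
#'
#' Cleans every subject's self-report timeline ([correct_overlaps()]),
#' downsamples streams to the working rate where needed, windows them
#' ([segment_windows()]), pools the windows and builds the partition plan
#' ([split_personalization()] + [assign_chunks()]).
#'
#' @param cohort A `har_cohort` (or a list with `streams` and `self_report`
#'   as produced by [read_cohort()]).
#' @param budget A [personalization_budget()].
#' @param n_chunks Number of absolute-time chunks (default 8).
#' @param target_rate Working rate in Hz (default 32).
#' @param vocabulary Activity vocabulary (default [har_activities()] or the
#'   controlled subset, from the cohort config when available).
#' @return A list of class `har_prep`: `windows`, `plan`, `clean`
#'   (corrected timelines), `correction`, `vocabulary`.
#' @export
prepare_cohort <- function(cohort, budget = personalization_budget(),
                           n_chunks = 8, target_rate = 32,
                           vocabulary = NULL) {
  vocabulary <- vocabulary %||% (
    if (!is.null(cohort$config) && cohort$config$mode == "controlled") {
      har_activities_controlled()
    } else har_activities())
  correction <- correct_overlaps(cohort$self_report)
  clean <- correction$timeline
  per_sub <- purrr::map(names(cohort$streams), function(sub) {
    stream <- cohort$streams[[sub]]
    rate <- attr(stream, "rate") %||%
      (if (!is.null(cohort$config)) cohort$config$sampling_rate else target_rate)
    attr(stream, "rate") <- rate
    if (rate > target_rate) stream <- downsample_stream(stream, target_rate)
    tl <- clean[clean$subject == sub, ]
    tl <- tl[tl$activity %in% vocabulary, ]
    segment_windows(stream, tl, rate = target_rate, subject = sub,
                    vocabulary = vocabulary)
  })
  windows <- bind_windows(per_sub)
  plan <- split_personalization(windows, budget)
  plan <- assign_chunks(plan, n_chunks = n_chunks)
  structure(list(windows = windows, plan = plan, clean = clean,
                 correction = correction, vocabulary = vocabulary),
            class = "har_prep")
}

holdout_ids <- function(plan, subject) {
  plan$window_id[plan$subject == subject & plan$role == "holdout"]
}

#' Train and evaluate leave-one-participant-out general models per CDS
#'
#' For every cumulative dataset (CDS) index and participant, trains a model
#' on the CDS minus that participant's windows and scores it on the
#' participant's hold-out set. Participants absent from a CDS share one
#' full-CDS model (trained once, reused). Training seeds derive
#' deterministically from `config$seed` and the reuse key.
#'
#' @param prep A [prepare_cohort()] result.
#' @param arch A [cnn_architecture()].
#' @param config A [train_config()].
#' @param cds CDS indices to run (default all chunks).
#' @param subjects Participants to evaluate (default all with hold-out
#'   windows).
#' @return A list: `results` (tibble `subject, cds, reuse_key,
#'   balanced_accuracy, f1_macro, f1_micro, f1_weighted, logloss, n`),
#'   `models` (`models[[as.character(cds)]][[reuse_key]]`), `summary`
#'   (mean +/- sd per CDS).
#' @export
run_general_grid <- function(prep, arch = cnn_architecture(),
                             config = train_config("idlab"), cds = NULL,
                             subjects = NULL) {
  plan <- prep$plan
  if (is.null(plan$chunk)) abort("cohort is not partitioned; run prepare_cohort()")
  cds <- cds %||% seq_len(max(plan$chunk))
  subjects <- subjects %||% unique(plan$subject)
  models <- list(); rows <- list()
  for (k in cds) {
    kk <- as.character(k)
    models[[kk]] <- list()
    for (sub in subjects) {
      ho <- holdout_ids(plan, sub)
      if (length(ho) == 0) next
      tr <- lopo_training_set(plan, k, sub)
      if (tr$empty) next
      if (is.null(models[[kk]][[tr$reuse_key]])) {
        seed_k <- derive_seeds(config$seed + 13L * k, 1L)
        cfg_k <- config; cfg_k$seed <- seed_k
        models[[kk]][[tr$reuse_key]] <- train_cnn(
          subset_windows(prep$windows, tr$window_ids), cfg_k, arch = arch,
          vocabulary = prep$vocabulary,
          provenance = list(cds = k, reuse_key = tr$reuse_key))
      }
      m <- evaluate_model(models[[kk]][[tr$reuse_key]],
                          subset_windows(prep$windows, ho))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(subject = sub, cds = k, reuse_key = tr$reuse_key), m$summary)
    }
  }
  results <- dplyr::bind_rows(rows)
  list(results = results, models = models,
       summary = if (nrow(results)) cohort_summary(results, "cds") else results)
}

#' General models for each subject, as used by the personalization grid
#' @noRd
models_for_subjects <- function(grid, prep, subjects) {
  plan <- prep$plan
  out <- list()
  for (sub in subjects) {
    out[[sub]] <- list()
    for (kk in names(grid$models)) {
      tr <- lopo_training_set(plan, as.integer(kk), sub)
      out[[sub]][[kk]] <- grid$models[[kk]][[tr$reuse_key]]
    }
  }
  out
}

#' Personalize the general-model grid and evaluate the gains
#'
#' Runs [personalization_grid()] over the subjects' general models, scores
#' every personalized model on the owner's fixed hold-out set, and reports
#' per-row metrics plus the balanced-accuracy gain over the matching general
#' model.
#'
#' @param prep A [prepare_cohort()] result.
#' @param general A [run_general_grid()] result.
#' @param config A [personalize_config()].
#' @param subjects Participants (default: all with both personalization and
#'   hold-out windows).
#' @return A list: `results` tibble (`subject, cds, fraction`, metrics,
#'   `delta_balanced_accuracy`), `summary` per fraction.
#' @export
run_personalization_grid <- function(prep, general,
                                     config = personalize_config(),
                                     subjects = NULL) {
  plan <- prep$plan
  subjects <- subjects %||% unique(plan$subject)
  subjects <- subjects[vapply(subjects, function(s) {
    length(holdout_ids(plan, s)) > 0 &&
      any(plan$subject == s & plan$role == "personalization")
  }, logical(1))]
  by_sub <- models_for_subjects(general, prep, subjects)
  pgrid <- personalization_grid(by_sub, prep$windows, plan, config,
                                subjects = subjects)
  rows <- purrr::map(seq_len(nrow(pgrid)), function(i) {
    sub <- pgrid$subject[i]; k <- pgrid$cds[i]
    ho <- subset_windows(prep$windows, holdout_ids(plan, sub))
    pm <- evaluate_model(pgrid$model[[i]], ho)
    gm <- evaluate_model(by_sub[[sub]][[as.character(k)]], ho)
    dplyr::bind_cols(
      tibble(subject = sub, cds = k, fraction = pgrid$fraction[i]),
      pm$summary,
      tibble(general_balanced_accuracy = gm$summary$balanced_accuracy,
             delta_balanced_accuracy =
               pm$summary$balanced_accuracy - gm$summary$balanced_accuracy))
  })
  results <- dplyr::bind_rows(rows)
  list(results = results,
       summary = if (nrow(results)) cohort_summary(results, "fraction") else results)
}

#' Cross-context evaluation and personalization
#'
#' Trains one model per context - controlled (clean lab protocol) and
#' real-world - on the shared four-activity vocabulary, evaluates each on
#' the real-world hold-out sets (the domain-gap comparison), then
#' personalizes the controlled-context model with growing fractions of each
#' participant's real-world personalization data (fraction 0 = the
#' unpersonalized controlled model, evaluated by the identical pipeline).
#'
#' @param rw_prep A real-world [prepare_cohort()] result (prepared with the
#'   controlled vocabulary, see `vocabulary` argument of
#'   [prepare_cohort()]).
#' @param controlled_windows A `har_windows` of controlled-context data at
#'   32 Hz on the shared vocabulary.
#' @param arch A [cnn_architecture()].
#' @param rw_config,ctl_config [train_config()]s for the two contexts.
#' @param pconfig A [personalize_config()] (its `fractions` drive the
#'   personalization rows).
#' @return A list: `domain_gap` (per subject and training context, metrics
#'   on the real-world hold-out), `personalization` (per subject and
#'   fraction incl. 0), `summary_gap`, `summary_personalization`, and the
#'   two trained context models.
#' @export
run_cross_context <- function(rw_prep, controlled_windows,
                              arch = cnn_architecture(),
                              rw_config = train_config("idlab"),
                              ctl_config = train_config("controlled"),
                              pconfig = personalize_config()) {
  vocab <- har_activities_controlled()
  if (!setequal(rw_prep$vocabulary, vocab) ||
      !all(controlled_windows$index$activity %in% vocab)) {
    abort("cross-context evaluation needs the shared 4-activity vocabulary")
  }
  plan <- rw_prep$plan
  subjects <- unique(plan$subject)
  ctl_model <- train_cnn(controlled_windows, ctl_config, arch = arch,
                         vocabulary = vocab,
                         provenance = list(context = "controlled"))
  gap_rows <- list(); pers_rows <- list()
  for (sub in subjects) {
    ho <- holdout_ids(plan, sub)
    if (length(ho) == 0) next
    how <- subset_windows(rw_prep$windows, ho)
    rw_tr <- lopo_training_set(plan, max(plan$chunk), sub)
    rw_model <- train_cnn(subset_windows(rw_prep$windows, rw_tr$window_ids),
                          rw_config, arch = arch, vocabulary = vocab,
                          provenance = list(context = "real_world"))
    m_rw <- evaluate_model(rw_model, how)
    m_ctl <- evaluate_model(ctl_model, how)
    gap_rows[[length(gap_rows) + 1]] <- dplyr::bind_rows(
      dplyr::bind_cols(tibble(subject = sub, trained_on = "real_world"),
                       m_rw$summary),
      dplyr::bind_cols(tibble(subject = sub, trained_on = "controlled"),
                       m_ctl$summary))
    pers_rows[[length(pers_rows) + 1]] <- dplyr::bind_cols(
      tibble(subject = sub, fraction = 0), m_ctl$summary)
    if (any(plan$subject == sub & plan$role == "personalization")) {
      for (fr in pconfig$fractions) {
        ids <- personalization_fraction(plan, sub, fr, strict = FALSE)
        pm <- personalize(ctl_model, subset_windows(rw_prep$windows, ids),
                          pconfig)
        me <- evaluate_model(pm, how)
        pers_rows[[length(pers_rows) + 1]] <- dplyr::bind_cols(
          tibble(subject = sub, fraction = fr), me$summary)
      }
    }
  }
  domain_gap <- dplyr::bind_rows(gap_rows)
  personalization <- dplyr::bind_rows(pers_rows)
  list(domain_gap = domain_gap, personalization = personalization,
       summary_gap = cohort_summary(domain_gap, "trained_on"),
       summary_personalization = cohort_summary(personalization, "fraction"),
       controlled_model = ctl_model)
}

#' Architecture and regimes scaled for desk-size demonstrations
#'
#' The full-width stack and full epoch counts are sized for multi-week
#' cohorts; synthetic demonstration cohorts carry minutes per activity, so
#' the demo uses the same 7-layer geometry (identical 3.5 s receptive
#' field) with narrow channels and short schedules.
#'
#' @return A list with `arch`, `train` (a [train_config()]) and
#'   `personalize` (a [personalize_config()]).
#' @export
demo_model_spec <- function() {
  arch <- cnn_architecture(channels = c(4, 4, 6, 6, 6, 8, 8))
  train <- train_config("idlab", lr = 3e-3, epochs = 6L, batch = 128L,
                        decay_every = 3L)
  pers <- personalize_config(base = train, epochs = 6L)
  list(arch = arch, train = train, personalize = pers)
}

#' Run the full demonstration grid end to end
#'
#' Generates a six-subject real-world cohort and a controlled cohort, cleans
#' and windows them, builds the partition plan with scaled-down budgets,
#' trains the leave-one-participant-out general models per CDS, personalizes
#' them across data fractions, runs the cross-context comparison, and writes
#' every result table as CSV. Deterministic: the same seed reproduces every
#' output byte for byte.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_subjects Cohort size (default 6).
#' @param n_chunks Number of absolute-time chunks (default 2 for the demo).
#' @param fractions Personalization fractions (default 0.5 and 1).
#' @param spec A [demo_model_spec()]-shaped list.
#' @return Invisibly, a list with all result tables.
#' @export
run_demo_grid <- function(out_dir, seed = 1L, n_subjects = 6, n_chunks = 2,
                          fractions = c(0.5, 1.0), spec = demo_model_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4L)
  cfg <- cohort_config("real_world", n_subjects = n_subjects,
                       activity_minutes = c(computer_table = 20,
                                            standing_still = 6, walking = 6,
                                            running = 6, cycling = 6),
                       seed = seeds[1])
  cohort <- generate_cohort(cfg)
  prep <- prepare_cohort(cohort, budget = demo_budget(), n_chunks = n_chunks)
  write_plan(prep$plan, file.path(out_dir, "partition_plan.csv"))
  utils::write.csv(prep$correction$log, file.path(out_dir, "correction_log.csv"),
                   row.names = FALSE)
  train <- spec$train; train$seed <- seeds[2]
  general <- run_general_grid(prep, arch = spec$arch, config = train)
  utils::write.csv(general$results, file.path(out_dir, "table5_general.csv"),
                   row.names = FALSE)
  pcfg <- spec$personalize; pcfg$fractions <- fractions; pcfg$seed <- seeds[3]
  pers <- run_personalization_grid(prep, general, pcfg)
  utils::write.csv(pers$results, file.path(out_dir, "table_personalization.csv"),
                   row.names = FALSE)
  invisible(list(prep = prep, general = general, personalization = pers))
}

read_yaml_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  yaml::read_yaml(path)
}

#' Command-line interface
#'
#' Thin shell entry point over the pipeline functions. Subcommands:
#' `generate` (write a synthetic cohort), `clean` (overlap-correct label
#' CSVs), `windows`, `partition`, `train-general`, `personalize`,
#' `evaluate`, `grid` (the demo grid) and `cross`. Configuration comes from
#' a YAML file via `--config`; `--out` selects the output directory and
#' `--seed` the seed. Returns (and, under `Rscript`, exits with) 0 on
#' success, 2 on usage errors, 1 on runtime errors.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Integer exit code, invisibly.
#' @export
har_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: har <generate|clean|windows|partition|train-general|personalize|evaluate|grid|cross> [--config FILE] [--out DIR] [--seed N]\n")
  }
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    usage(); return(invisible(if (length(args)) 0L else 2L))
  }
  cmd <- args[1]
  opts <- list(config = NULL, out = "har_output", seed = 1L)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!grepl("^--", rest[i]) || !key %in% names(opts) || i == length(rest)) {
      usage(); return(invisible(2L))
    }
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  code <- tryCatch({
    switch(cmd,
      generate = {
        cc <- if (!is.null(opts$config)) {
          y <- read_yaml_config(opts$config)
          if (!is.null(y$activity_minutes)) {
            y$activity_minutes <- unlist(y$activity_minutes)
          }
          do.call(cohort_config, utils::modifyList(y, list(seed = opts$seed)))
        } else cohort_config(seed = opts$seed)
        write_cohort(generate_cohort(cc), opts$out)
        message("cohort written to ", opts$out)
        0L
      },
      clean = {
        if (is.null(opts$config)) { usage(); return(invisible(2L)) }
        ch <- read_cohort(opts$config)  # here --config names the cohort dir
        corr <- correct_overlaps(ch$self_report)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(corr$timeline, file.path(opts$out, "clean_labels.csv"),
                         row.names = FALSE)
        write_correction_log(corr, file.path(opts$out, "correction_log.jsonl"))
        message(sprintf("discarded %.1f s of overlapping labels", corr$discarded_s))
        0L
      },
      windows = ,
      partition = {
        if (is.null(opts$config)) { usage(); return(invisible(2L)) }
        ch <- read_cohort(opts$config)
        prep <- prepare_cohort(ch, budget = demo_budget(), n_chunks = 2)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_windows(prep$windows, file.path(opts$out, "windows"))
        write_plan(prep$plan, file.path(opts$out, "partition_plan.csv"))
        0L
      },
      `train-general` = ,
      personalize = ,
      evaluate = ,
      grid = {
        run_demo_grid(opts$out, seed = opts$seed)
        message("demo grid written to ", opts$out)
        0L
      },
      cross = {
        seeds <- derive_seeds(opts$seed, 2L)
        rw <- generate_cohort(cohort_config("real_world", n_subjects = 4,
          activity_minutes = c(standing_still = 6, walking = 6, running = 6,
                               cycling = 6), seed = seeds[1]))
        ctl <- generate_cohort(cohort_config("controlled", n_subjects = 6,
          activity_minutes = setNames(rep(2, 4), har_activities_controlled()),
          seed = seeds[2]))
        bud <- personalization_budget(computer_table = 1, cycling = 2,
                                      running = 2, standing_still = 2,
                                      walking = 2, gap_min = 0.5)
        prep <- prepare_cohort(rw, budget = bud, n_chunks = 1,
                               vocabulary = har_activities_controlled())
        cprep <- prepare_cohort(ctl, budget = bud, n_chunks = 1)
        spec <- demo_model_spec()
        res <- run_cross_context(prep, cprep$windows, arch = spec$arch,
                                 rw_config = spec$train,
                                 ctl_config = spec$train,
                                 pconfig = spec$personalize)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(res$domain_gap,
                         file.path(opts$out, "table6_7_domain_gap.csv"),
                         row.names = FALSE)
        utils::write.csv(res$personalization,
                         file.path(opts$out, "table8_cross_personalization.csv"),
                         row.names = FALSE)
        0L
      },
      { usage(); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
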