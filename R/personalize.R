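#' Configuration for transfer-learning personalization
#'
#' Personalization continues training only convolutional layers 4-7 of a
#' general model on the target subject's small personalization set; conv
#' layers 1-3 and both dense layers are frozen, and by default the softmax
#' layer too (only the mid/high-level temporal filters adapt; flip
#' `freeze_softmax` for sensitivity analysis). Because the personal set is
#' tiny, the optimizer switches to SGD with a raised learning rate and
#' regularization is strengthened by multiplying the Gaussian noise and the
#' dropout rates.
#'
#' @param base A [train_config()] giving the general regime whose rates are
#'   scaled.
#' @param lr_mult Learning-rate multiplier over the general regime (default
#'   10).
#' @param noise_mult,dropout_mult Multipliers on input/weight noise and on
#'   both dropout rates (default 2).
#' @param epochs Personalization epochs (default 60).
#' @param freeze_softmax Keep the softmax layer frozen (default TRUE).
#' @param fractions Allowed personalization-data fractions.
#' @param seed Integer seed.
#' @return A list of class `har_personalize_config`.
#' @export
personalize_config <- function(base = train_config("idlab"), lr_mult = 10,
                               noise_mult = 2, dropout_mult = 2, epochs = 60,
                               freeze_softmax = TRUE,
                               fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                               seed = 1L) {
  structure(list(base = base, lr_mult = lr_mult, noise_mult = noise_mult,
                 dropout_mult = dropout_mult, epochs = as.integer(epochs),
                 freeze_softmax = freeze_softmax, fractions = fractions,
                 seed = as.integer(seed)),
            class = "har_personalize_config")
}

personalize_freeze <- function(arch, freeze_softmax) {
  n_conv <- length(arch$kernels)
  frozen <- c(paste0("conv", seq_len(min(3, n_conv - 1))), "dense1", "dense2")
  if (freeze_softmax) frozen <- c(frozen, "softmax")
  frozen
}

#' Personalize a general model on one subject's data
#'
#' @param general A trained `har_model`.
#' @param personal_windows A `har_windows` holding only the subject's
#'   personalization windows (never hold-out data).
#' @param config A [personalize_config()].
#' @return A `har_model` whose frozen-layer parameters are bit-identical to
#'   `general`'s; provenance records the source model and seed.
#' @export
personalize <- function(general, personal_windows, config = personalize_config()) {
  if (n_windows(personal_windows) == 0) abort("empty personalization set")
  if (!all(personal_windows$index$activity %in% general$vocabulary)) {
    abort("personalization labels outside the model vocabulary")
  }
  frozen <- personalize_freeze(general$arch, config$freeze_softmax)
  base <- config$base
  cfg <- train_config(
    base$regime,
    optimizer = "sgd",
    lr = base$lr * config$lr_mult,
    epochs = config$epochs,
    spatial_dropout = min(0.9, base$spatial_dropout * config$dropout_mult),
    dense_dropout = min(0.9, base$dense_dropout * config$dropout_mult),
    input_noise_sd = base$input_noise_sd * config$noise_mult,
    weight_noise_sd = base$weight_noise_sd * config$noise_mult,
    rotation_strength = base$rotation_strength,
    lr_decay = base$lr_decay, decay_every = base$decay_every,
    batch = base$batch, seed = config$seed
  )
  model <- train_cnn(personal_windows, cfg, arch = general$arch,
                     vocabulary = general$vocabulary, freeze = frozen,
                     init = general,
                     provenance = list(personalized_from = general$provenance$seed,
                                       subject = personal_windows$index$subject[1]))
  model
}

#' Personalize every general model over the CDS x fraction grid
#'
#' For each subject with personalization data, each available general model
#' (one per cumulative dataset) is personalized once per data fraction,
#' using time-ordered prefixes of the personalization set
#' ([personalization_fraction()]). Missing general models and subjects
#' without personalization data are recorded and skipped.
#'
#' @param general_models Named list of `har_model`, one per CDS index
#'   (`"1"`..`"8"`), or a nested list per subject
#'   (`models[[subject]][[cds]]`).
#' @param windows The full `har_windows`.
#' @param plan A chunked partition plan.
#' @param config A [personalize_config()].
#' @param subjects Subjects to process (default: all in the plan).
#' @return A tibble `subject, cds, fraction, model` (list column), with
#'   skipped combinations in attribute `skipped`.
#' @export
personalization_grid <- function(general_models, windows, plan,
                                 config = personalize_config(),
                                 subjects = NULL) {
  subjects <- subjects %||% unique(plan$subject)
  rows <- list(); skipped <- list()
  nested <- !is.null(names(general_models)) &&
    all(names(general_models) %in% subjects)
  for (sub in subjects) {
    has_pers <- any(plan$subject == sub & plan$role == "personalization")
    if (!has_pers) {
      skipped[[length(skipped) + 1]] <- tibble(subject = sub, cds = NA_integer_,
                                               reason = "no personalization data")
      next
    }
    models <- if (nested) general_models[[sub]] else general_models
    for (cds in names(models)) {
      gm <- models[[cds]]
      if (is.null(gm)) {
        skipped[[length(skipped) + 1]] <- tibble(subject = sub,
                                                 cds = as.integer(cds),
                                                 reason = "missing general model")
        next
      }
      for (fr in config$fractions) {
        ids <- personalization_fraction(plan, sub, fr, strict = FALSE)
        pw <- subset_windows(windows, ids)
        pm <- personalize(gm, pw, config)
        rows[[length(rows) + 1]] <- tibble(subject = sub, cds = as.integer(cds),
                                           fraction = fr, model = list(pm))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}
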