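#' @useDynLib wristhar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif predict setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' Activity vocabularies
#'
#' `har_activities()` returns the five-activity vocabulary used in the
#' real-world regime (sitting at a computer table, standing still, walking,
#' running, cycling). `har_activities_controlled()` returns the four-activity
#' subset shared with the controlled (lab-protocol) regime, which lacks the
#' computer-table class.
#'
#' @return Character vector of activity names.
#' @export
har_activities <- function() {
  c("computer_table", "standing_still", "walking", "running", "cycling")
}

#' @rdname har_activities
#' @export
har_activities_controlled <- function() {
  c("standing_still", "walking", "running", "cycling")
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be %s.", name, if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}

#' Format a mean and standard deviation as "mean±sd"
#'
#' Helper used for cohort summary tables reported across participants.
#'
#' @param mean,sd Numeric vectors.
#' @param digits Number of decimal places (default 2).
#' @return Character vector like `"0.80±0.12"`.
#' @export
fmt_mean_sd <- function(mean, sd, digits = 2) {
  sprintf(paste0("%.", digits, "f±%.", digits, "f"), mean, sd)
}
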