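#' Rescale raw accelerometer counts to the +/-2 g working range
#'
#' Maps a device's raw dynamic range affinely onto \[-2, 2\] (units of g) and
#' clips anything outside. Synthetic data already in g passes through
#' unchanged under the identity range `c(-2, 2)`.
#'
#' @param stream A stream tibble with columns `timestamp_s, x_g, y_g, z_g`
#'   (values in raw device units before rescaling).
#' @param device_range Length-2 numeric: the raw values that map to -2 g and
#'   +2 g.
#' @return The rescaled stream; the number of clipped values is attached as
#'   attribute `clipped`.
#' @export
rescale_stream <- function(stream, device_range = c(-2, 2)) {
  if (length(device_range) != 2 || diff(device_range) == 0) {
    abort("`device_range` must be two distinct values")
  }
  cols <- c("x_g", "y_g", "z_g")
  v <- as.matrix(stream[cols])
  g <- -2 + 4 * (v - device_range[1]) / diff(device_range)
  clipped <- sum(g < -2 | g > 2)
  g <- pmin(pmax(g, -2), 2)
  out <- stream
  out[cols] <- as.data.frame(g)
  attr(out, "clipped") <- clipped
  attr(out, "subject_id") <- attr(stream, "subject_id")
  attr(out, "rate") <- attr(stream, "rate")
  out
}

#' Downsample a stream by mean-aggregating time bins
#'
#' The time axis is partitioned into contiguous bins of width
#' `1/target_rate`; each output sample is the arithmetic mean of the input
#' samples falling in its bin, timestamped at the bin start. Empty bins
#' (sensor gaps) produce no output sample, so gaps propagate.
#'
#' @param stream A stream tibble.
#' @param target_rate Target rate in Hz, strictly below the nominal rate.
#' @param nominal_rate Source rate; taken from the stream attribute when
#'   absent.
#' @return A stream tibble at `target_rate` (attribute `rate` updated).
#' @export
downsample_stream <- function(stream, target_rate, nominal_rate = NULL) {
  nominal_rate <- nominal_rate %||% attr(stream, "rate")
  if (!is.null(nominal_rate) && target_rate >= nominal_rate) {
    abort("target_rate must be below the nominal rate (no upsampling)")
  }
  if (nrow(stream) == 0) return(stream)
  t0 <- stream$timestamp_s[1]
  bin <- floor((stream$timestamp_s - t0) * target_rate + 1e-9)
  agg <- rowsum(as.matrix(stream[c("x_g", "y_g", "z_g")]), bin, reorder = TRUE)
  counts <- rowsum(rep(1, length(bin)), bin, reorder = TRUE)[, 1]
  out <- tibble(
    timestamp_s = t0 + as.numeric(rownames(agg)) / target_rate,
    x_g = unname(agg[, 1] / counts), y_g = unname(agg[, 2] / counts),
    z_g = unname(agg[, 3] / counts)
  )
  attr(out, "subject_id") <- attr(stream, "subject_id")
  attr(out, "rate") <- target_rate
  out
}

#' Segment a labeled stream into fixed-length windows
#'
#' Cuts each cleaned label interval into windows of `window_s` seconds with
#' stride `stride_s` (50% overlap by default), restarting the window grid at
#' every interval start. A window is emitted only when it lies entirely
#' inside one label interval and all of its expected samples are present
#' (each expected timestamp matched within a quarter sample period) - windows
#' touching a sensor gap are dropped, never imputed. A gapless interval of
#' `T >= 12` seconds therefore yields `floor((T - 12)/6) + 1` windows.
#'
#' @param stream A rescaled stream at `rate` Hz.
#' @param timeline The subject's cleaned timeline tibble.
#' @param window_s Window length in seconds (default 12).
#' @param stride_s Stride in seconds (default 6).
#' @param rate Required sampling rate in Hz (default 32); the stream's rate
#'   attribute, when present, must match or an error directs to
#'   [downsample_stream()].
#' @param subject Subject id; taken from the stream attribute when absent.
#' @param vocabulary Activity vocabulary recorded on the dataset.
#' @return A `har_windows` object: list with `array` (3 x n_samples x
#'   n_windows), `index` (tibble `window_id, subject, activity, start_s,
#'   interval_id, offset_s` where `offset_s` is the window start's cumulative
#'   labeled-time offset within its subject/activity), `durations` (labeled
#'   seconds per subject/activity), `rate`, `window_s`, `stride_s`,
#'   `vocabulary`.
#' @export
segment_windows <- function(stream, timeline, window_s = 12, stride_s = 6,
                            rate = 32, subject = NULL, vocabulary = NULL) {
  srate <- attr(stream, "rate")
  if (!is.null(srate) && abs(srate - rate) > 1e-9) {
    abort(sprintf("stream is at %.4g Hz, not %g Hz; downsample_stream() it first",
                  srate, rate))
  }
  subject <- subject %||% attr(stream, "subject_id") %||% "S?"
  vocabulary <- vocabulary %||% sort(unique(timeline$activity))
  n_per <- as.integer(round(window_s * rate))
  tl <- timeline[order(timeline$start_s), ]
  ts <- stream$timestamp_s
  vals <- t(as.matrix(stream[c("x_g", "y_g", "z_g")]))  # 3 x N

  mats <- list(); idx <- list()
  cum <- setNames(rep(0, length(unique(tl$activity))), unique(tl$activity))
  grid0 <- if (length(ts)) ts[1] else 0   # sensor sample-grid phase
  for (i in seq_len(nrow(tl))) {
    s_lab <- tl$start_s[i]; e <- tl$end_s[i]; act <- tl$activity[i]
    # window grid starts at the first on-grid sample inside the interval
    s <- grid0 + ceiling((s_lab - grid0) * rate - 1e-9) / rate
    dur <- e - s
    if (dur >= window_s && length(ts)) {
      # map samples in [s, e) onto the interval's expected grid
      in_iv <- which(ts >= s - 1e-9 & ts < e - 1e-9)
      rel <- ts[in_iv] - s
      slot <- round(rel * rate)
      ok <- abs(rel - slot / rate) <= 1 / (4 * rate) & slot >= 0
      slot_max <- floor((dur - 1e-9) * rate)
      present <- integer(0)
      if (any(ok)) present <- slot[ok][slot[ok] <= slot_max]
      have <- logical(slot_max + 1)
      have[present + 1] <- TRUE
      row_of <- integer(slot_max + 1)
      row_of[present + 1] <- in_iv[ok][match(present, slot[ok])]
      starts <- seq(0, dur - window_s + 1e-9, by = stride_s)
      for (w in starts) {
        s0 <- as.integer(round(w * rate))
        slots <- s0:(s0 + n_per - 1)
        if (slots[n_per] > slot_max || !all(have[slots + 1])) next
        mats[[length(mats) + 1]] <- vals[, row_of[slots + 1], drop = FALSE]
        idx[[length(idx) + 1]] <- tibble(
          subject = subject, activity = act, start_s = s + w,
          interval_id = i, offset_s = unname(cum[act]) + w
        )
      }
    }
    cum[act] <- (if (is.na(cum[act])) 0 else cum[act]) + (e - s_lab)
  }
  n <- length(mats)
  arr <- array(0, dim = c(3, n_per, n))
  if (n > 0) for (j in seq_len(n)) arr[, , j] <- mats[[j]]
  index <- if (n > 0) {
    dplyr::bind_rows(idx) |> dplyr::mutate(window_id = dplyr::row_number(), .before = 1)
  } else {
    tibble(window_id = integer(0), subject = character(0), activity = character(0),
           start_s = numeric(0), interval_id = integer(0), offset_s = numeric(0))
  }
  durations <- durations_by_activity(tl, vocabulary = vocabulary) |>
    dplyr::mutate(subject = subject, .before = 1)
  new_har_windows(arr, index, durations, rate, window_s, stride_s, vocabulary)
}

new_har_windows <- function(array, index, durations, rate, window_s, stride_s,
                            vocabulary) {
  structure(list(array = array, index = index, durations = durations,
                 rate = rate, window_s = window_s, stride_s = stride_s,
                 vocabulary = vocabulary),
            class = "har_windows")
}

#' @export
print.har_windows <- function(x, ...) {
  cat(sprintf("<har_windows> %d windows of %gs @ %g Hz (3x%d), %d subject(s)\n",
              n_windows(x), x$window_s, x$rate, dim(x$array)[2],
              dplyr::n_distinct(x$index$subject)))
  tab <- table(x$index$activity)
  if (length(tab)) {
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of windows in a dataset
#' @param x A `har_windows`.
#' @return Integer count.
#' @export
n_windows <- function(x) nrow(x$index)

#' Combine window datasets from several subjects
#' @param ... `har_windows` objects with identical geometry.
#' @return A single `har_windows`.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "har_windows")) {
    parts <- parts[[1]]
  }
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (p$rate != ref$rate || p$window_s != ref$window_s) {
      abort("window datasets have mismatched geometry")
    }
  }
  arrs <- purrr::map(parts, "array")
  n <- sum(vapply(arrs, function(a) dim(a)[3], integer(1)))
  arr <- array(0, dim = c(3, dim(ref$array)[2], n))
  at <- 0
  for (a in arrs) {
    k <- dim(a)[3]
    if (k > 0) arr[, , at + seq_len(k)] <- a
    at <- at + k
  }
  index <- dplyr::bind_rows(purrr::map(parts, "index")) |>
    dplyr::mutate(window_id = dplyr::row_number())
  durations <- dplyr::bind_rows(purrr::map(parts, "durations"))
  vocab <- Reduce(union, purrr::map(parts, "vocabulary"))
  new_har_windows(arr, index, durations, ref$rate, ref$window_s, ref$stride_s, vocab)
}

#' Subset a window dataset by window id
#' @param x A `har_windows`.
#' @param ids Window ids to keep (values of `index$window_id`).
#' @return A `har_windows` with the selected windows (ids renumbered;
#'   original ids kept in `index$orig_id`).
#' @export
subset_windows <- function(x, ids) {
  keep <- match(ids, x$index$window_id)
  if (anyNA(keep)) abort("unknown window id")
  index <- x$index[keep, ]
  index$orig_id <- index$window_id
  index$window_id <- seq_len(nrow(index))
  arr <- x$array[, , keep, drop = FALSE]
  new_har_windows(arr, index, x$durations, x$rate, x$window_s, x$stride_s,
                  x$vocabulary)
}

#' Serialize a window dataset
#'
#' Writes one little-endian float64 binary file of stacked 3 x n matrices per
#' subject plus a CSV index (`subject,activity,start_s,file,offset`).
#'
#' @param x A `har_windows`.
#' @param dir Output directory.
#' @return Invisibly, the index path.
#' @export
write_windows <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- x$index
  idx$file <- paste0(idx$subject, ".bin")
  idx$offset <- stats::ave(seq_len(nrow(idx)), idx$subject, FUN = seq_along) - 1L
  for (sub in unique(idx$subject)) {
    rows <- which(idx$subject == sub)
    con <- file(file.path(dir, paste0(sub, ".bin")), "wb")
    writeBin(as.vector(x$array[, , rows]), con, size = 8, endian = "little")
    close(con)
  }
  ip <- file.path(dir, "index.csv")
  utils::write.csv(idx[c("subject", "activity", "start_s", "file", "offset")],
                   ip, row.names = FALSE)
  meta <- list(rate = x$rate, window_s = x$window_s, stride_s = x$stride_s,
               n_per = dim(x$array)[2], vocabulary = x$vocabulary)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(ip)
}

#' Read a window dataset written by [write_windows()]
#' @param dir Directory with `index.csv`, `meta.json` and per-subject `.bin`.
#' @return A `har_windows`.
#' @export
read_windows <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n_per <- meta$n_per
  arr <- array(0, dim = c(3, n_per, nrow(idx)))
  for (sub in unique(idx$subject)) {
    rows <- which(idx$subject == sub)
    con <- file(file.path(dir, paste0(sub, ".bin")), "rb")
    v <- readBin(con, "double", n = 3 * n_per * length(rows), size = 8,
                 endian = "little")
    close(con)
    block <- array(v, dim = c(3, n_per, length(rows)))
    arr[, , rows[order(idx$offset[rows])]] <- block
  }
  index <- as_tibble(idx[c("subject", "activity", "start_s")])
  index$window_id <- seq_len(nrow(index))
  index$interval_id <- NA_integer_
  index$offset_s <- NA_real_
  index <- index[c("window_id", "subject", "activity", "start_s", "interval_id", "offset_s")]
  new_har_windows(arr, index, durations = tibble(), meta$rate, meta$window_s,
                  meta$stride_s, meta$vocabulary)
}
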