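## Plain-text interchange formats: CSV payloads with JSON attribute sidecars.

fmt_num <- function(x, digits = 10) formatC(x, format = "g", digits = digits)

#' Write / read a stimulus container
#'
#' The stimulus (and optionally the voltage command) is stored as a CSV of
#' `(sample_index, value)` pairs next to a JSON sidecar holding the sampling
#' rate, seed and standardization constants.
#'
#' @param stimulus a `stimulus_trace`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @param voltage optional `voltage_command` written as a third column.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(stimulus, path, voltage = NULL) {
  df <- data.frame(sample_index = seq_along(stimulus) - 1L,
                   value = fmt_num(as_samples(stimulus)))
  if (!is.null(voltage)) df$voltage <- fmt_num(as.numeric(voltage))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = stim_rate(stimulus),
               seed = attr(stimulus, "seed"),
               standardization = attr(stimulus, "standardization"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  st <- stimulus_trace(df$value, sampling_rate = meta$sampling_rate,
                       standardization = meta$standardization)
  attr(st, "seed") <- meta$seed
  if (!is.null(df$voltage)) {
    attr(st, "voltage") <- structure(as.numeric(df$voltage),
                                     sampling_rate = meta$sampling_rate,
                                     class = "voltage_command")
  }
  st
}

#' Write / read spike trains
#'
#' CSV with columns `cell_id`, `repetition`, `time_s` (seconds, 6 decimals).
#'
#' @param trains a list of [spike_train()]s, or a named list of such lists
#'   (one per cell).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(trains, path) {
  if (length(trains) && inherits(trains[[1]], "spike_train"))
    trains <- list(cell = trains)
  rows <- list()
  for (cid in names(trains)) {
    for (tr in trains[[cid]]) {
      if (!length(tr)) next
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cid, repetition = attr(tr, "repetition_id"),
        time_s = sprintf("%.6f", as.numeric(tr)))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(cell_id = character(), repetition = integer(),
                        time_s = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @param duration recording duration attached to the returned trains.
#' @export
read_spikes <- function(path, duration = NA_real_) {
  df <- utils::read.csv(path, colClasses = c(cell_id = "character"))
  out <- list()
  for (cid in unique(df$cell_id)) {
    sub <- df[df$cell_id == cid, ]
    out[[cid]] <- lapply(sort(unique(sub$repetition)), function(r) {
      spike_train(sort(sub$time_s[sub$repetition == r]), repetition_id = r,
                  cell_id = cid, duration = duration)
    })
  }
  out
}

#' Write / read linear filters
#'
#' Long CSV with columns `cell_id`, `method`, `tap_time_ms`, `value`.
#'
#' @param filters named list of [linear_filter()]s.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_filters <- function(filters, path) {
  rows <- lapply(names(filters), function(cid) {
    f <- filters[[cid]]
    data.frame(cell_id = cid, method = attr(f, "method"),
               tap_time_ms = sprintf("%.1f", attr(f, "tap_times")),
               value = fmt_num(as.numeric(f)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_filters <- function(path) {
  df <- utils::read.csv(path, colClasses = c(cell_id = "character"))
  out <- list()
  for (cid in unique(df$cell_id)) {
    sub <- df[df$cell_id == cid, ]
    sub <- sub[order(sub$tap_time_ms), ]
    out[[cid]] <- linear_filter(sub$value, method = sub$method[1])
  }
  out
}

#' Write a metrics table
#'
#' CSV with one row per cell: `cell_id`, `ri`, `reliable`, `bias_index`,
#' `transiency_index`, `polarity_class`.
#'
#' @param metrics data.frame with those columns.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  m <- metrics
  for (cl in c("ri", "bias_index", "transiency_index"))
    if (cl %in% names(m)) m[[cl]] <- fmt_num(m[[cl]])
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Report-only format checks: spike CSVs must have the expected columns and
#' monotone per-repetition times; stimulus containers must have a readable
#' sidecar and finite samples. Durations are cross-checked when both a
#' stimulus and a spike file are given.
#'
#' @param paths named character vector or list; names among `stimulus`,
#'   `spikes`.
#' @return data.frame of class `validation_report` with columns `file`,
#'   `check`, `status` (`"pass"`, `"warn"`, `"fail"`) and `detail`.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  rows <- list()
  add <- function(file, check, status, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(file = file, check = check,
                                            status = status, detail = detail)
  }
  dur_stim <- NA_real_; max_spike <- NA_real_
  if (!is.null(paths$stimulus)) {
    p <- paths$stimulus
    if (!file.exists(p)) {
      add(p, "exists", "fail", "file not found")
    } else {
      st <- tryCatch(read_stimulus(p), error = function(e) e)
      if (inherits(st, "error")) {
        add(p, "readable", "fail", conditionMessage(st))
      } else {
        add(p, "readable", "pass")
        dur_stim <- length(st) / stim_rate(st)
        if (any(!is.finite(as_samples(st)))) add(p, "finite", "fail",
                                                 "non-finite samples")
        else add(p, "finite", "pass")
      }
    }
  }
  if (!is.null(paths$spikes)) {
    p <- paths$spikes
    if (!file.exists(p)) {
      add(p, "exists", "fail", "file not found")
    } else {
      df <- tryCatch(utils::read.csv(p), error = function(e) e)
      if (inherits(df, "error")) {
        add(p, "readable", "fail", conditionMessage(df))
      } else if (!all(c("cell_id", "repetition", "time_s") %in% names(df))) {
        add(p, "columns", "fail", "expected cell_id, repetition, time_s")
      } else {
        add(p, "columns", "pass")
        bad <- c()
        for (key in unique(paste(df$cell_id, df$repetition))) {
          idx <- which(paste(df$cell_id, df$repetition) == key)
          if (is.unsorted(df$time_s[idx]))
            bad <- c(bad, idx[which(diff(df$time_s[idx]) < 0) + 1])
        }
        if (length(bad)) add(p, "sorted_times", "fail",
                             paste("unsorted rows:", paste(bad + 1, collapse = " ")))
        else add(p, "sorted_times", "pass")
        if (nrow(df)) max_spike <- max(df$time_s)
      }
    }
  }
  if (!is.na(dur_stim) && !is.na(max_spike)) {
    if (max_spike > dur_stim)
      add("(cross)", "duration", "warn",
          sprintf("spikes up to %.3f s exceed stimulus %.3f s", max_spike, dur_stim))
    else add("(cross)", "duration", "pass")
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(file = character(), check = character(),
                         status = character(), detail = character())
  class(out) <- c("validation_report", "data.frame")
  out
}
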