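#' Construct an event table
#'
#' Long-format table of stimulus/response events for one recording.
#' Onset times are seconds from recording start; sample indices elsewhere in
#' the package are 0-based and epoch windows are half-open `[start, end)`.
#'
#' @param onset_time numeric, seconds from recording start
#' @param code character, device marker code (e.g. `"S  1"`)
#' @param modality one of `"auditory"`, `"visual"`, `"click_train"`,
#'   `"response"`
#' @param condition one of `"standard"`, `"deviant"`, `"target"`, `"novel"`,
#'   `"train"`, `"button"`, `"unknown"`
#' @param run_index 1-based run number
#' @param paradigm one of `"mmn_vod"`, `"aod"`, `"assr"`, `"rest_open"`,
#'   `"rest_closed"`
#' @return a `data.frame` of class `event_table`
#' @export
event_table <- function(onset_time, code, modality, condition, run_index,
                        paradigm) {
  df <- data.frame(
    onset_time = as.numeric(onset_time),
    code = as.character(code),
    modality = as.character(modality),
    condition = as.character(condition),
    run_index = as.integer(run_index),
    paradigm = as.character(paradigm),
    stringsAsFactors = FALSE
  )
  validate_event_table(df)
  class(df) <- c("event_table", "data.frame")
  df
}

validate_event_table <- function(df) {
  mods <- c("auditory", "visual", "click_train", "response")
  conds <- c("standard", "deviant", "target", "novel", "train", "button",
             "unknown")
  pars <- c("mmn_vod", "aod", "assr", "rest_open", "rest_closed")
  stopifnot(all(df$modality %in% mods), all(df$condition %in% conds),
            all(df$paradigm %in% pars))
  # stimulus onsets must be strictly increasing within a paradigm
  for (p in unique(df$paradigm)) {
    on <- df$onset_time[df$paradigm == p & df$modality != "response"]
    if (is.unsorted(on, strictly = FALSE) || anyDuplicated(on))
      stop("event onsets not strictly increasing within paradigm ", p)
  }
  invisible(df)
}

#' Construct a raw EEG session
#'
#' @param data channels x samples numeric matrix in microvolts, with rownames
#'   equal to the montage's recorded channel labels
#' @param sampling_rate sampling rate in Hz (1000 for acquisition, 250 after
#'   downsampling)
#' @param montage a [standard_montage()]-style montage
#' @param events an [event_table()]
#' @param meta list with `subject_id`, `group` (`"CHR"`/`"CON"`), `occasion`
#'   (`"baseline"`/`"month2"`), optionally `interval_days` and `seed`
#' @param reference current reference label (default the montage reference)
#' @return object of class `raw_session`
#' @export
raw_session <- function(data, sampling_rate, montage, events,
                        meta = list(), reference = montage$reference_label) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  if (!all(rownames(data) %in% rownames(montage$positions)))
    stop("data rows not in montage: ",
         paste(setdiff(rownames(data), rownames(montage$positions)),
               collapse = ", "))
  dur <- ncol(data) / sampling_rate
  if (nrow(events) && any(events$onset_time >= dur))
    stop("event onsets beyond recording duration")
  structure(
    list(data = data, sampling_rate = sampling_rate, montage = montage,
         events = events, meta = meta, reference = reference),
    class = "raw_session"
  )
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %d ch x %.1f s @ %g Hz, %d events, ref %s\n",
              nrow(x$data), ncol(x$data) / x$sampling_rate, x$sampling_rate,
              nrow(x$events), x$reference))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Duration of a raw session in seconds
#' @param session a `raw_session`
#' @return numeric seconds
#' @export
session_duration <- function(session) {
  ncol(session$data) / session$sampling_rate
}

empty_event_table <- function() {
  df <- data.frame(onset_time = numeric(0), code = character(0),
                   modality = character(0), condition = character(0),
                   run_index = integer(0), paradigm = character(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_table", "data.frame")
  df
}

#' Construct a measure table
#'
#' The analysis-ready long table consumed by the reliability module: one row
#' per (subject, occasion, run, measure). `run_index` is `"all"` for
#' session-level scores or the run number as character.
#'
#' @param subject_id,group,occasion,run_index,measure_name,value columns
#' @return a `data.frame` of class `measure_table`
#' @export
measure_table <- function(subject_id, group, occasion, run_index,
                          measure_name, value) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    group = as.character(group),
    occasion = as.character(occasion),
    run_index = as.character(run_index),
    measure_name = as.character(measure_name),
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  key <- do.call(paste, c(df[c("subject_id", "occasion", "run_index",
                               "measure_name")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (subject, occasion, run, measure) keys in measure table")
  class(df) <- c("measure_table", "data.frame")
  df
}

#' Combine measure tables
#' @param ... measure tables
#' @return a `measure_table`
#' @export
bind_measures <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0,
                        logical(1))]
  if (!length(parts)) return(measure_table(character(0), character(0),
                                           character(0), character(0),
                                           character(0), numeric(0)))
  df <- do.call(rbind, lapply(parts, as.data.frame))
  measure_table(df$subject_id, df$group, df$occasion, df$run_index,
                df$measure_name, df$value)
}

.measure_cols <- c("subject_id", "group", "occasion", "run_index",
                   "measure_name", "value")

#' Write a measure table to tab-separated text
#'
#' @param table a `measure_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_measures <- function(table, path) {
  stopifnot(inherits(table, "measure_table"))
  utils::write.table(as.data.frame(table)[, .measure_cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measure table written by [write_measures()]
#'
#' Errors on duplicate (subject, occasion, run, measure) keys.
#'
#' @param path file path
#' @return a `measure_table`
#' @export
read_measures <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "character", "character", "numeric"))
  if (!identical(names(df), .measure_cols))
    stop("unexpected measure table columns in ", path)
  measure_table(df$subject_id, df$group, df$occasion, df$run_index,
                df$measure_name, df$value)
}
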