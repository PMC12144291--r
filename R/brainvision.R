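#' Default marker code map
#'
#' Maps BrainVision marker descriptions to (modality, condition). The stimulus
#' delivery codes are configurable because acquisition software varies; these
#' defaults are the package's own convention and are what [write_session()]
#' emits.
#'
#' @return data.frame with columns `code`, `modality`, `condition`
#' @export
default_code_map <- function() {
  data.frame(
    code = c("S  1", "S  2", "S  3", "S  4", "S  5", "S 10", "R  1"),
    modality = c("auditory", "auditory", "visual", "visual", "visual",
                 "click_train", "response"),
    condition = c("standard", "deviant", "standard", "target", "novel",
                  "train", "button"),
    stringsAsFactors = FALSE
  )
}

#' Read a BrainVision recording
#'
#' Reads a `.vhdr`/`.vmrk`/`.eeg` triplet (multiplexed binary, IEEE float32 or
#' 16-bit signed integer with per-channel resolution) into a [raw_session()].
#' Marker descriptions are mapped through `code_map`; unmapped stimulus codes
#' are retained with condition `"unknown"` and a warning.
#'
#' @param header_path path to the `.vhdr` file
#' @param code_map marker code map, see [default_code_map()]
#' @param montage montage to attach (default [standard_montage()])
#' @param paradigm paradigm label for the parsed events
#' @param run_index run number for the parsed events
#' @param meta session metadata list
#' @return a `raw_session`
#' @export
read_brainvision <- function(header_path, code_map = default_code_map(),
                             montage = standard_montage(),
                             paradigm = "mmn_vod", run_index = 1L,
                             meta = list()) {
  if (!file.exists(header_path)) stop("missing header file: ", header_path)
  hdr <- .bv_parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  dir <- dirname(header_path)
  data_file <- file.path(dir, ci[["DataFile"]])
  marker_file <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(data_file)) stop("missing data file: ", data_file)
  if (!file.exists(marker_file)) stop("missing marker file: ", marker_file)
  if (toupper(ci[["DataOrientation"]]) != "MULTIPLEXED")
    stop("unsupported data orientation: ", ci[["DataOrientation"]])
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])

  chs <- hdr[["Channel Infos"]]
  labels <- character(n_ch); resolution <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    parts <- strsplit(chs[[sprintf("Ch%d", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[i] <- as.numeric(parts[3])
  }

  fmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]])
  sz <- file.info(data_file)$size
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    n <- sz / 4
    raw <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    n <- sz / 2
    raw <- readBin(con, "integer", n = n, size = 2, signed = TRUE,
                   endian = "little")
  } else stop("unsupported binary format: ", fmt)
  n_samp <- length(raw) %/% n_ch
  data <- matrix(raw[seq_len(n_samp * n_ch)], nrow = n_ch)  # multiplexed
  data <- data * resolution
  rownames(data) <- labels

  ev <- .bv_parse_markers(readLines(marker_file, warn = FALSE), fs, code_map,
                          paradigm, run_index)
  raw_session(data, fs, montage, ev, meta = meta)
}

.bv_parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); sect <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sect <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[sect]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(sect)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[sect]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

.bv_parse_markers <- function(lines, fs, code_map, paradigm, run_index) {
  mk <- grep("^Mk[0-9]+=", lines, value = TRUE)
  if (!length(mk)) return(empty_event_table())
  onset <- numeric(0); code <- character(0); modality <- character(0)
  condition <- character(0)
  unmapped <- character(0)
  for (ln in mk) {
    val <- sub("^Mk[0-9]+=", "", ln)
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    type <- parts[1]; desc <- parts[2]
    if (!type %in% c("Stimulus", "Response")) next
    # marker positions are 1-based sample indices; internal times are seconds
    t0 <- (as.numeric(parts[3]) - 1) / fs
    hit <- match(desc, code_map$code)
    if (is.na(hit)) {
      unmapped <- c(unmapped, desc)
      onset <- c(onset, t0); code <- c(code, desc)
      modality <- c(modality,
                    if (type == "Response") "response" else "auditory")
      condition <- c(condition, "unknown")
    } else {
      onset <- c(onset, t0); code <- c(code, desc)
      modality <- c(modality, code_map$modality[hit])
      condition <- c(condition, code_map$condition[hit])
    }
  }
  if (length(unmapped))
    warning("unmapped marker codes retained as unknown: ",
            paste(unique(unmapped), collapse = ", "))
  o <- order(onset)
  event_table(onset[o], code[o], modality[o], condition[o], run_index,
              paradigm)
}

#' Write a session to disk
#'
#' `format = "brainvision"` writes a `.vhdr`/`.vmrk`/`.eeg` triplet
#' (multiplexed IEEE float32, resolution 1); `format = "archive"` writes a
#' directory holding the binary channel matrix, structured-text metadata, and
#' a tab-separated event table, sufficient to reconstruct the session exactly.
#'
#' @param session a `raw_session`
#' @param path output path: basename (without extension) for brainvision, a
#'   directory for archive
#' @param format `"brainvision"` or `"archive"`
#' @param code_map used to translate conditions back to marker codes
#' @return path to the primary output file, invisibly
#' @export
write_session <- function(session, path, format = c("brainvision", "archive"),
                          code_map = default_code_map()) {
  format <- match.arg(format)
  if (format == "brainvision") .bv_write(session, path, code_map)
  else .archive_write(session, path)
}

.bv_write <- function(session, path, code_map) {
  base <- basename(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  vhdr <- file.path(dir, paste0(base, ".vhdr"))
  vmrk <- file.path(dir, paste0(base, ".vmrk"))
  eeg <- file.path(dir, paste0(base, ".eeg"))
  n_ch <- nrow(session$data)
  lines <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / session$sampling_rate,
                                       scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rownames(session$data))
  )
  writeLines(lines, vhdr)

  ev <- session$events
  cond_key <- paste(code_map$modality, code_map$condition)
  mlines <- c(
    "BrainVision Data Exchange Marker File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (nrow(ev)) {
    idx <- match(paste(ev$modality, ev$condition), cond_key)
    code <- ifelse(is.na(idx), ev$code, code_map$code[idx])
    type <- ifelse(ev$modality == "response", "Response", "Stimulus")
    pos <- round(ev$onset_time * session$sampling_rate) + 1
    mlines <- c(mlines, sprintf("Mk%d=%s,%s,%d,1,0",
                                seq_len(nrow(ev)) + 1L, type, code, pos))
  }
  writeLines(mlines, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(session$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

.archive_write <- function(session, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  # metadata as key: value structured text
  meta <- c(
    paste0("sampling_rate: ", format(session$sampling_rate)),
    paste0("n_channels: ", nrow(session$data)),
    paste0("n_samples: ", ncol(session$data)),
    paste0("reference: ", session$reference),
    paste0("channels: ", paste(rownames(session$data), collapse = ",")),
    vapply(names(session$meta), function(k)
      paste0("meta_", k, ": ", format(session$meta[[k]])), character(1))
  )
  writeLines(meta, file.path(path, "metadata.txt"))
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.numeric(session$data), con, size = 8, endian = "little")
  close(con)
  utils::write.table(as.data.frame(session$events),
                     file.path(path, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a session archive written by [write_session()]
#'
#' @param path archive directory
#' @param montage montage to attach
#' @return a `raw_session`
#' @export
read_session_archive <- function(path, montage = standard_montage()) {
  meta_lines <- readLines(file.path(path, "metadata.txt"))
  kv <- strsplit(meta_lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  get <- function(k) vals[match(k, keys)]
  fs <- as.numeric(get("sampling_rate"))
  n_ch <- as.integer(get("n_channels"))
  n_samp <- as.integer(get("n_samples"))
  labels <- strsplit(get("channels"), ",", fixed = TRUE)[[1]]
  con <- file(file.path(path, "data.bin"), "rb")
  data <- matrix(readBin(con, "numeric", n = n_ch * n_samp, size = 8,
                         endian = "little"), nrow = n_ch)
  close(con)
  rownames(data) <- labels
  evf <- file.path(path, "events.tsv")
  ev <- utils::read.table(evf, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character", "character",
                                         "character", "integer", "character"))
  ev <- if (nrow(ev)) event_table(ev$onset_time, ev$code, ev$modality,
                                  ev$condition, ev$run_index, ev$paradigm)
        else empty_event_table()
  meta_keys <- grep("^meta_", keys, value = TRUE)
  meta <- as.list(vals[match(meta_keys, keys)])
  names(meta) <- sub("^meta_", "", meta_keys)
  raw_session(data, fs, montage, ev, meta = meta,
              reference = get("reference"))
}
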