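# Import/export: BrainVision and EDF signal files, CSV event tables, and a
# lossless JSON container for recordings and epochs.

#' Write an event table to CSV
#'
#' Columns: `trial`, `stim_time_s`, `move_time_s`, `hand`.
#'
#' @param stim_times stimulus-onset times, s.
#' @param hand per-trial `"L"`/`"R"` labels.
#' @param move_times movement-onset times, s (`NA` allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(stim_times, hand, move_times = NA, path) {
  df <- data.frame(trial = seq_along(stim_times), stim_time_s = stim_times,
                   move_time_s = move_times, hand = as.character(hand))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV (or TSV)
#'
#' Expects at least `stim_time_s` and `hand` columns.
#'
#' @param path file path.
#' @return data.frame with `trial`, `stim_time_s`, `move_time_s`, `hand`.
#' @export
read_events_csv <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("stim_time_s", "hand")
  if (!all(need %in% names(df))) {
    stop("event table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$trial)) df$trial <- seq_len(nrow(df))
  if (is.null(df$move_time_s)) df$move_time_s <- NA_real_
  df[, c("trial", "stim_time_s", "move_time_s", "hand")]
}

#' Save / load recordings and epochs losslessly
#'
#' JSON containers (via jsonlite's schema-preserving serialization) holding
#' a full [eeg_recording()] or [eeg_epochs()] object, including events,
#' labels and processing log.
#'
#' @param recording an [eeg_recording()].
#' @param path file path.
#' @return `path` invisibly (writers); the restored object (readers).
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  writeLines(as.character(jsonlite::serializeJSON(recording, digits = NA)), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  stopifnot(inherits(obj, "eeg_recording"))
  obj
}

#' @rdname write_recording
#' @param epochs an [eeg_epochs()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  writeLines(as.character(jsonlite::serializeJSON(epochs, digits = NA)), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_epochs <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  stopifnot(inherits(obj, "eeg_epochs"))
  obj
}

#' Write a recording in BrainVision format
#'
#' Produces the `.vhdr` (header), `.vmrk` (markers) and `.eeg`
#' (multiplexed IEEE float32, microvolts) triplet. Events are written as
#' `Stimulus` markers whose description is the hand label.
#'
#' @param recording an [eeg_recording()].
#' @param basepath output path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(recording, basepath) {
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  con <- file(paste0(basepath, ".eeg"), "wb")
  writeBin(as.numeric(recording$data), con, size = 4)  # column-major = multiplexed
  close(con)
  nch <- nrow(recording$data)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / recording$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$channels))
  writeLines(header, vhdr)
  markers <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0")
  if (length(recording$events) > 0) {
    lab <- if (is.null(recording$labels)) rep("S  1", length(recording$events))
           else recording$labels
    markers <- c(markers,
                 sprintf("Mk%d=Stimulus,%s,%d,1,0",
                         seq_along(recording$events) + 1L, lab,
                         round(recording$events * recording$fs) + 1L))
  }
  writeLines(markers, paste0(basepath, ".vmrk"))
  invisible(vhdr)
}

# Parse a BrainVision INI-style section into a named character vector.
bv_section <- function(lines, section) {
  starts <- grep("^\\[", lines)
  i <- grep(paste0("^\\[", section, "\\]$"), lines, ignore.case = TRUE)
  if (length(i) == 0) return(character(0))
  end <- c(starts[starts > i[1]], length(lines) + 1)[1] - 1
  body <- lines[(i[1] + 1):end]
  body <- body[grepl("=", body, fixed = TRUE)]
  kv <- regmatches(body, regexpr("=", body), invert = TRUE)
  stats::setNames(trimws(vapply(kv, `[`, "", 2)),
                  trimws(vapply(kv, `[`, "", 1)))
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE_FLOAT_32 or INT_16 (with
#' per-channel resolution). `Stimulus` markers become events; marker
#' descriptions `L`/`R` become hand labels.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return an [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  common <- bv_section(lines, "Common Infos")
  binary <- bv_section(lines, "Binary Infos")
  chinfo <- bv_section(lines, "Channel Infos")
  nch <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  if (!is.null(common["DataOrientation"]) && !is.na(common["DataOrientation"]) &&
      toupper(common[["DataOrientation"]]) != "MULTIPLEXED") {
    stop("only MULTIPLEXED BrainVision data supported")
  }
  parts <- strsplit(unname(chinfo), ",")
  channels <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3])); if (is.na(r)) 1 else r
  }, 0)
  datafile <- file.path(dirname(vhdr), common[["DataFile"]])
  fmt <- toupper(binary[["BinaryFormat"]])
  sz <- file.info(datafile)$size
  con <- file(datafile, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = sz / 4, size = 4)
  } else if (fmt == "INT_16") {
    raw <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE)
  } else stop("unsupported BinaryFormat: ", fmt)
  ns <- length(raw) %/% nch
  data <- matrix(raw[seq_len(ns * nch)], nrow = nch)
  if (fmt == "INT_16") data <- data * res
  events <- numeric(0); labels <- character(0)
  vmrk <- file.path(dirname(vhdr), common[["MarkerFile"]])
  if (!is.na(vmrk) && file.exists(vmrk)) {
    mk <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    fields <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    for (f in fields) {
      if (toupper(f[1]) == "STIMULUS") {
        events <- c(events, (as.numeric(f[3]) - 1) / fs)
        labels <- c(labels, f[2])
      }
    }
  }
  eeg_recording(data, fs, channels, events = events,
                labels = if (all(labels %in% c("L", "R")) &&
                             length(labels) == length(events) &&
                             length(labels) > 0) labels else NULL)
}

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a recording as EDF
#'
#' Continuous European Data Format: 16-bit samples, one data record per
#' second, physical units microvolts. The physical range is chosen from the
#' data; the tail is zero-padded to a whole record. Events are not stored
#' (use [write_events_csv()] alongside).
#'
#' @param recording an [eeg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  nch <- nrow(data); fs <- recording$fs
  spr <- as.integer(round(fs))
  n_rec <- ceiling(ncol(data) / spr)
  if (ncol(data) < n_rec * spr) {
    data <- cbind(data, matrix(0, nch, n_rec * spr - ncol(data)))
  }
  pmin_ <- floor(min(data)); pmax_ <- ceiling(max(data))
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(paste(edf_pad(x, w), collapse = ""), con,
                                 nchars = w * length(x), eos = NULL)
  wr("0", 8); wr("premove synthetic", 80); wr("premove recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + nch)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(nch), 4)
  wr(substr(recording$channels, 1, 16), 16)
  wr(rep("EEG", nch), 80); wr(rep("uV", nch), 8)
  wr(rep(as.character(pmin_), nch), 8); wr(rep(as.character(pmax_), nch), 8)
  wr(rep(as.character(dmin), nch), 8); wr(rep(as.character(dmax), nch), 8)
  wr(rep("", nch), 80); wr(rep(as.character(spr), nch), 8); wr(rep("", nch), 32)
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((data[, idx, drop = FALSE] - pmin_) / scale_) + dmin
    writeBin(as.integer(t(dig)), con, size = 2)
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Minimal EDF reader: all signals must share the same sampling rate;
#' annotation channels are not supported. Physical scaling is applied, so
#' values come back in the header's physical units.
#'
#' @param path EDF file.
#' @return an [eeg_recording()] (without events; load those separately).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); nch <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  channels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80); spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1) stop("signals with mixed sampling rates not supported")
  fs <- spr[1] / dur
  out <- matrix(0, nch, n_rec * spr[1])
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (c in seq_len(nch)) {
      dig <- readBin(con, integer(), n = spr[c], size = 2, signed = TRUE)
      out[c, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[c]) * scale_[c] + pmin_[c]
    }
  }
  eeg_recording(out, fs, channels)
}
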