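#' Read and write BrainVision recordings
#'
#' Minimal BrainVision Core Data Format support: an INI-style `.vhdr`
#' header, a binary `.eeg` data file (`IEEE_FLOAT_32` or `INT_16` with
#' per-channel resolution, `MULTIPLEXED` or `VECTORIZED` orientation)
#' and an optional `.vmrk` marker file. Amplitudes are returned in
#' microvolts. The writer emits multiplexed IEEE float 32 and, when
#' `rpeaks` is given, a marker file with one `R Peak` marker per peak.
#'
#' @param vhdr_path path to the `.vhdr` header.
#' @return `read_brainvision`: list with `recording` (an
#'   [eeg_recording]) and `markers` (data frame with `type`,
#'   `description`, `position` in samples, or `NULL`).
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  ini <- parse_ini(lines)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chan <- ini[["Channel Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: no [Common Infos]")
  if (!identical(toupper(ci[["DataFormat"]]), "BINARY"))
    stop("only BINARY DataFormat is supported")
  nchan <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  fmt <- toupper(bi[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  chn <- t(vapply(paste0("Ch", seq_len(nchan)), function(k) {
    parts <- strsplit(chan[[k]], ",")[[1]]
    length(parts) <- 4L
    parts
  }, character(4)))
  labels <- chn[, 1]
  resolution <- suppressWarnings(as.numeric(chn[, 3]))
  resolution[is.na(resolution)] <- 1
  eeg_path <- file.path(dirname(vhdr_path), ci[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb"); on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    n_vals <- sz %/% 4
    raw_vals <- readBin(con, "numeric", n = n_vals, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    n_vals <- sz %/% 2
    raw_vals <- readBin(con, "integer", n = n_vals, size = 2, signed = TRUE,
                        endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  ns <- length(raw_vals) %/% nchan
  raw_vals <- raw_vals[seq_len(ns * nchan)]
  data <- if (orientation == "MULTIPLEXED") {
    matrix(raw_vals, nrow = nchan, ncol = ns)          # sample-major on disk
  } else t(matrix(raw_vals, nrow = ns, ncol = nchan))  # VECTORIZED
  data <- data * resolution
  markers <- NULL
  if (!is.null(ci[["MarkerFile"]])) {
    vmrk <- file.path(dirname(vhdr_path), ci[["MarkerFile"]])
    if (file.exists(vmrk)) markers <- read_vmrk(vmrk)
  }
  list(recording = eeg_recording(data, fs, labels), markers = markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && !is.null(section)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

read_vmrk <- function(path) {
  ini <- parse_ini(readLines(path, warn = FALSE))
  mk <- ini[["Marker Infos"]]
  if (is.null(mk) || !length(mk)) return(NULL)
  rows <- lapply(mk, function(v) strsplit(v, ",")[[1]])
  data.frame(type = vapply(rows, function(r) r[1], ""),
             description = vapply(rows, function(r) if (length(r) > 1) r[2] else "", ""),
             position = vapply(rows, function(r) as.integer(r[3]), 1L))
}

#' @rdname read_brainvision
#' @param rec an [eeg_recording] to write.
#' @param basename_path output path without extension; `.vhdr`, `.eeg`
#'   and (with peaks) `.vmrk` are created next to each other.
#' @param rpeaks optional [rpeak_series] written as `R Peak` markers.
#' @return `write_brainvision`: invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, basename_path, rpeaks = NULL) {
  base <- basename(basename_path)
  vhdr <- paste0(basename_path, ".vhdr")
  eegf <- paste0(basename_path, ".eeg")
  vmrk <- paste0(basename_path, ".vmrk")
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           if (!is.null(rpeaks)) paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", n_channels(rec)),
           paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(n_channels(rec)), rec$labels))
  writeLines(hdr, vhdr)
  con <- file(eegf, "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)
  if (!is.null(rpeaks)) {
    mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
            "[Common Infos]",
            paste0("DataFile=", base, ".eeg"),
            "[Marker Infos]",
            sprintf("Mk%d=Response,R Peak,%d,1,0", seq_along(rpeaks$indices),
                    rpeaks$indices))
    writeLines(mk, vmrk)
  }
  invisible(vhdr)
}

#' Read and write EDF recordings
#'
#' Plain continuous EDF (not EDF+): 16-bit samples with per-signal
#' physical scaling, fixed-duration data records. The writer uses 1 s
#' records and drops a trailing partial record (the reader cannot know
#' it was padding). All signals must share one sampling rate.
#'
#' @param path file path.
#' @return `read_edf`: an [eeg_recording] (microvolts assumed).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)          # version, patient, recording, date, time
  rd(8)                                        # header bytes
  rd(44)                                       # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)           # label, transducer, unit
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                      # prefiltering
  spr <- as.integer(fld(8))                    # samples per record
  fld(32)                                      # reserved
  if (length(unique(spr)) != 1L) stop("signals with mixed sampling rates are unsupported")
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                   endian = "little")
      data[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (v - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  eeg_recording(data, fs, labels)
}

#' @rdname read_edf
#' @param rec an [eeg_recording]; `rec$fs` must be a positive integer
#'   so 1 s records hold a whole number of samples.
#' @return `write_edf`: invisibly, the path.
#' @export
write_edf <- function(rec, path) {
  if (rec$fs != round(rec$fs)) stop("write_edf needs an integer sampling rate")
  ns <- n_channels(rec)
  spr <- as.integer(rec$fs)
  n_rec <- n_samples(rec) %/% spr
  if (n_rec < 1) stop("recording shorter than one 1 s data record")
  if (n_rec * spr < n_samples(rec))
    warning("dropping trailing partial data record (", n_samples(rec) - n_rec * spr,
            " samples)")
  phys_min <- apply(rec$data, 1, min); phys_max <- apply(rec$data, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeChar(paste0(substr(s, 1, w), collapse = ""), con, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("pacorrect", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 + 256 * ns, 8); pad("", 44)
  pad(n_rec, 8); pad("1", 8); pad(ns, 4)
  for (v in rec$labels) pad(v, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (v in phys_min) pad(formatC(v, digits = 6, format = "g"), 8)
  for (v in phys_max) pad(formatC(v, digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(spr, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- rec$data[s, ((r - 1) * spr + 1):(r * spr)]
      d <- round((seg - phys_min[s]) / gain[s]) + dig_min
      writeBin(as.integer(pmin(pmax(d, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EEG file by extension
#'
#' Dispatches on the file extension: `.vhdr` to [read_brainvision],
#' `.edf` to [read_edf].
#'
#' @param path input file.
#' @return an [eeg_recording].
#' @export
read_eeg <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vhdr = read_brainvision(path)$recording,
         edf = read_edf(path),
         stop("unsupported EEG format: .", ext))
}

#' Plain-text R-peak event files
#'
#' One 0-based sample index per line; lines starting with `#` are
#' comments. The on-disk convention is 0-based (interoperable with
#' array-offset tooling); in memory indices are 1-based.
#'
#' @param path file path.
#' @param fs sampling rate in Hz to attach to the series.
#' @return `read_rpeaks`: an [rpeak_series].
#' @export
read_rpeaks <- function(path, fs) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  idx <- suppressWarnings(as.integer(lines))
  if (any(is.na(idx))) stop("event file contains non-integer lines")
  rpeak_series(idx + 1L, fs)
}

#' @rdname read_rpeaks
#' @param rpeaks an [rpeak_series].
#' @return `write_rpeaks`: invisibly, the path.
#' @export
write_rpeaks <- function(rpeaks, path) {
  writeLines(c("# R-peak sample indices, 0-based",
               format(rpeaks$indices - 1L, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}
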