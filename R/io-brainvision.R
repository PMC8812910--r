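#' Write a recording in BrainVision core format
#'
#' Produces the `.vhdr` / `.vmrk` / `.eeg` triple: an INI-style text header,
#' a text marker file holding the stimulus events (marker descriptions
#' `S<category>` with the event's block/position encoded in the type field)
#' and button presses (`R  1`), and multiplexed IEEE float32 data in uV.
#'
#' @param rec An `eeg_recording`.
#' @param basepath Path without extension; the three files are written next
#'   to each other.
#' @return `basepath`, invisibly.
#' @export
write_raw_brainvision <- function(rec, basepath) {
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eeg <- paste0(basepath, ".eeg")
  n_chan <- nrow(rec$data)
  base <- basename(basepath)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_chan),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_chan), rec$channels)
  )
  writeLines(header, vhdr, useBytes = TRUE)
  ev <- rec$events
  markers <- c(
    sprintf("Mk%d=Stimulus,S%s|%s|b%d,%d,1,0", seq_len(nrow(ev)),
            ev$category, ev$position, ev$block, ev$sample),
    if (length(rec$press_samples) > 0) {
      sprintf("Mk%d=Response,R  1,%d,1,0",
              nrow(ev) + seq_along(rec$press_samples), rec$press_samples)
    }
  )
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    markers
  ), vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(basepath)
}

parse_ini_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (length(hit) == 0) abort(paste0("malformed BrainVision header: missing ", key))
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision core recording
#'
#' Minimal reader for the subset written by [write_raw_brainvision()]:
#' multiplexed IEEE float32 data with stimulus and response markers.
#'
#' @param basepath Path without extension, or the `.vhdr` path.
#' @param montage Montage attached to the returned recording.
#' @return An `eeg_recording` (the `events` tibble is reconstructed from the
#'   markers: columns `sample`, `category`, `position`, `block`,
#'   `is_target`, plus onset times implied by the sampling rate).
#' @export
read_raw_brainvision <- function(basepath, montage = montage_spec()) {
  basepath <- sub("\\.vhdr$", "", basepath)
  vhdr <- paste0(basepath, ".vhdr")
  if (!file.exists(vhdr)) abort(paste0("header not found: ", vhdr))
  lines <- readLines(vhdr, warn = FALSE)
  n_chan <- as.integer(parse_ini_value(lines, "NumberOfChannels"))
  samp_int <- as.numeric(parse_ini_value(lines, "SamplingInterval"))
  sfreq <- 1e6 / samp_int
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[`, character(1), 1)
  eeg <- paste0(basepath, ".eeg")
  n_bytes <- file.size(eeg)
  n_vals <- n_bytes / 4
  if (n_vals != floor(n_vals) || (n_vals %% n_chan) != 0) {
    abort(sprintf("truncated .eeg file: %d bytes is not a whole number of %d-channel float32 samples.",
                  n_bytes, n_chan))
  }
  con <- file(eeg, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n_vals, size = 4, endian = "little")
  data <- matrix(vals, nrow = n_chan)
  rownames(data) <- channels
  mk <- readLines(paste0(basepath, ".vmrk"), warn = FALSE)
  mk <- grep("^Mk[0-9]+=", mk, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  mtype <- vapply(parts, `[`, character(1), 1)
  desc <- vapply(parts, `[`, character(1), 2)
  sample <- as.integer(vapply(parts, `[`, character(1), 3))
  stim <- mtype == "Stimulus"
  fields <- strsplit(sub("^S", "", desc[stim]), "|", fixed = TRUE)
  events <- tibble::tibble(
    sample = sample[stim],
    category = vapply(fields, `[`, character(1), 1),
    position = vapply(fields, `[`, character(1), 2),
    block = as.integer(sub("^b", "", vapply(fields, `[`, character(1), 3)))
  )
  events$is_target <- events$category == "target"
  events$onset_ms <- (events$sample - 1) / sfreq * 1000
  structure(
    list(data = data, channels = channels, sfreq = sfreq, events = events,
         press_samples = sample[mtype == "Response"], montage = montage,
         reference_state = "as_recorded", soa_mode = NA_character_,
         subject = NA_integer_),
    class = "eeg_recording"
  )
}
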