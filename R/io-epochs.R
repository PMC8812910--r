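#' Write / read an epoch set as a binary array with JSON sidecar
#'
#' Stores the epoch array as little-endian float32 (`epochs.bin`) together
#' with `epochs.json` holding dimensions, channel names, the time grid, the
#' per-epoch condition table and the exclusion tallies.
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory (created if needed).
#' @return `write_epoch_set()` returns `dir` invisibly; `read_epoch_set()`
#'   returns the `epoch_set` (data at float32 precision).
#' @export
write_epoch_set <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "epochs.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 4, endian = "little")
  sidecar <- list(
    dim = dim(epochs$data),
    channels = dimnames(epochs$data)[[2]],
    times = epochs$times,
    info = epochs$info,
    tallies = as.list(epochs$tallies),
    soa_mode = epochs$soa_mode
  )
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "epochs.json"),
                                 simplifyVector = TRUE)
  dims <- as.integer(sidecar$dim)
  con <- file(file.path(dir, "epochs.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = prod(dims), size = 4, endian = "little")
  data <- array(vals, dim = dims,
                dimnames = list(NULL, sidecar$channels, NULL))
  structure(
    list(data = data, times = as.numeric(sidecar$times),
         info = tibble::as_tibble(sidecar$info),
         tallies = unlist(sidecar$tallies),
         montage = montage_spec(), soa_mode = sidecar$soa_mode),
    class = "epoch_set"
  )
}
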