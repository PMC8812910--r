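#' Write / read a stimulus event table as TSV
#'
#' The on-disk table has the columns `onset_ms, block, triplet_index,
#' position, sound, side, category, is_target` (UTF-8, header line).
#' Round-trips losslessly.
#'
#' @param events Event tibble (e.g. `generate_stream()$events`).
#' @param path File path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns the event tibble.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("onset_ms", "block", "triplet_index", "position", "sound",
            "side", "category", "is_target")
  readr::write_tsv(events[, intersect(cols, names(events))], path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    onset_ms = readr::col_double(),
    block = readr::col_integer(),
    triplet_index = readr::col_integer(),
    position = readr::col_character(),
    sound = readr::col_character(),
    side = readr::col_character(),
    category = readr::col_character(),
    is_target = readr::col_logical()
  ))
}

#' Serialise / restore a run configuration
#'
#' Flat key-value YAML round-trip of the pipeline configuration (see
#' [run_config()]).
#'
#' @param cfg A `run_config` list.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the configuration.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
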