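# CSV input/output for trajectories and summaries. Every file carries the
# fully resolved configuration as "# key: value" header comments so each
# number's provenance travels with it.

config_header <- function(config) {
  flat <- unclass(config)
  vals <- vapply(flat, function(v) paste(format(v, digits = 15), collapse = " "),
                 character(1))
  paste0("# ", names(flat), ": ", vals)
}

write_commented_csv <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config)) writeLines(config_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_commented_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write and read trajectory CSV files
#'
#' The trajectory schema is one row per replication and checkpoint with
#' columns `replication`, `time`, `mean_dominant_to_subordinate`,
#' `mean_subordinate_to_dominant`, `mean_alpha_dominant`,
#' `mean_alpha_subordinate`. When a configuration is supplied it is
#' embedded as `#`-prefixed header comments; `read_trajectory()` skips
#' them. Summary statistics are pure functions of trajectories, so a
#' round-trip through CSV reproduces them exactly at the written precision.
#'
#' @param trajectory A trajectory tibble (e.g. `tidy(sim)`).
#' @param path File path.
#' @param config Optional `trust_config` to embed as header comments.
#' @return `write_trajectory()`: `path`, invisibly. `read_trajectory()`:
#'   a tibble.
#' @export
write_trajectory <- function(trajectory, path, config = NULL) {
  write_commented_csv(trajectory, path, config)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read_commented_csv(path)
}

#' Write and read summary CSV files
#'
#' One row per replication plus a final aggregate row (`replication = NA`)
#' holding the mean of every statistic across replications.
#'
#' @param summaries The `summaries` tibble of a `trust_sim`.
#' @param path File path.
#' @param config Optional `trust_config` to embed as header comments.
#' @return `write_summary()`: `path`, invisibly. `read_summary()`: a tibble.
#' @export
write_summary <- function(summaries, path, config = NULL) {
  agg <- dplyr::summarise(summaries, dplyr::across(
    dplyr::where(is.numeric), function(v) mean(v, na.rm = TRUE)))
  agg$replication <- NA_integer_
  out <- dplyr::bind_rows(summaries, agg)
  write_commented_csv(out, path, config)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  read_commented_csv(path)
}
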