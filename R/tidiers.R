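# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a benchmark report
#'
#' @param x A `bench_report`.
#' @param ... Unused.
#' @return A tibble with one row per reported metric.
#' @export
tidy.bench_report <- function(x, ...) {
  tibble::tibble(
    metric = c("phase1_seconds", "records", "batches", "seeks",
               "peak_mem_bytes"),
    value = c(x$phase1_seconds, x$records, x$batches, x$seeks,
              x$peak_mem_bytes))
}

#' @rdname tidy.bench_report
#' @export
glance.bench_report <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode, format = x$config$format,
    records = x$records, batches = x$batches,
    phase1_seconds = x$phase1_seconds, seeks = x$seeks,
    peak_mem_bytes = x$peak_mem_bytes, checksum = x$checksum)
}

#' @rdname tidy.bench_report
#' @param object A `bench_report`.
#' @export
autoplot.bench_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$metric %in% c("phase1_seconds", "seeks"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("%s read of %s (%d records)", object$config$mode,
                      object$config$format, object$records),
      x = NULL, y = NULL) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}

#' Tidy a simulation report
#'
#' @param x A `sim_report`.
#' @param ... Unused.
#' @return The per-task latency tibble (pool, position, tick, seconds,
#'   deadline, warned).
#' @export
tidy.sim_report <- function(x, ...) x$latencies

#' @rdname tidy.sim_report
#' @export
glance.sim_report <- function(x, ...) {
  tibble::tibble(
    n_positions = x$config$n_positions,
    warnings = x$warnings,
    reads_completed = x$reads_completed,
    samples_written = x$samples_written,
    bytes_written = x$bytes_written,
    file_size_per_hour_gib = x$file_size_per_hour_gib,
    ram_peak_estimate_bytes = x$ram_peak_estimate_bytes,
    temp_files_remaining = x$temp_files_remaining)
}

#' @rdname tidy.sim_report
#' @param object A `sim_report`.
#' @export
#' @importFrom rlang .data
autoplot.sim_report <- function(object, ...) {
  ggplot2::ggplot(object$latencies,
                  ggplot2::aes(x = .data$tick, y = .data$seconds,
                               colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$latencies$deadline[1],
                        linetype = "dashed") +
    ggplot2::facet_wrap(~position, labeller = ggplot2::label_both) +
    ggplot2::labs(title = "Pool task latency per acquisition tick",
                  y = "task seconds (dashed = deadline)") +
    ggplot2::theme_minimal()
}

#' Tidy a capacity search
#'
#' @param x A `capacity_search`.
#' @param ... Unused.
#' @return The search trace tibble (n_positions, warnings).
#' @export
tidy.capacity_search <- function(x, ...) x$trace

#' @rdname tidy.capacity_search
#' @export
glance.capacity_search <- function(x, ...) {
  tibble::tibble(capacity = x$capacity, runs = nrow(x$trace))
}
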