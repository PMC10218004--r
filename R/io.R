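#' Read and write landmark events as CSV
#'
#' Events travel as plain CSV with columns `time_s`, `magnitude`, `kind`.
#'
#' @param events a [landmark_events()] object.
#' @param path file path.
#' @param duration total signal duration in seconds (stored nowhere in the
#'   CSV; supply on read when it matters, otherwise the last event time is
#'   used).
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a [landmark_events()] object.
#' @export
write_landmarks <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("time_s", "magnitude", "kind")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path, duration = NULL) {
  d <- utils::read.csv(path)
  landmark_events(d$time_s, d$magnitude, kind = d$kind, duration = duration)
}

#' Read and write a kernel as CSV
#'
#' Columns `lag_s`, `value`; the sampling rate is recovered from the lag
#' grid.
#'
#' @param kernel a [trf_kernel()].
#' @param path file path.
#' @return `write_kernel` returns `path` invisibly; `read_kernel` a
#'   [trf_kernel()].
#' @export
write_kernel <- function(kernel, path) {
  utils::write.csv(data.frame(lag_s = kernel_lags(kernel),
                              value = kernel$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  d <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(d$lag_s))
  trf_kernel(d$value, lag_window = range(d$lag_s), fs = round(fs, 6))
}
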