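# CSV round-tripping for traces and dwell series. The sampling interval
# travels in a `# dt <seconds>` comment line ahead of the header.

#' Write / read a gating trace as CSV
#'
#' Columns `step,state` plus any recorded side-channels (`rc`, `b2`,
#' `drift`); the sampling interval is stored in a `# dt` comment line.
#' Round-trips are lossless for the integer state series.
#'
#' @param gt A [gating_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [gating_trace()].
#' @export
write_trace <- function(gt, path) {
  stopifnot(inherits(gt, "gating_trace"))
  df <- data.frame(step = seq_along(gt$states), state = gt$states)
  for (side in c("rc", "b2", "drift"))
    if (!is.null(gt[[side]])) df[[side]] <- gt[[side]]
  writeLines(sprintf("# dt %.17g", gt$dt), path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  dt <- parse_dt_header(path)
  df <- data.table::fread(path, skip = 1, header = TRUE, data.table = FALSE)
  if (!all(c("step", "state") %in% names(df)))
    stop("malformed trace file (need `step,state` header after the `# dt` line): ", path)
  gating_trace(df$state, dt = dt, rc = df$rc, b2 = df$b2, drift = df$drift)
}

#' Write / read a dwell series as CSV
#'
#' Columns `state,duration` (durations in samples), with the sampling
#' interval in a `# dt` comment line.
#'
#' @param ds A `dwell_series` from [extract_dwells()].
#' @param path File path.
#' @return `write_dwells` returns `path` invisibly; `read_dwells` returns
#'   a `dwell_series`.
#' @export
write_dwells <- function(ds, path) {
  stopifnot(inherits(ds, "dwell_series"))
  writeLines(sprintf("# dt %.17g", attr(ds, "dt")), path)
  data.table::fwrite(data.frame(state = ds$state, duration = ds$duration),
                     path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  dt <- parse_dt_header(path)
  df <- data.table::fread(path, skip = 1, header = TRUE, data.table = FALSE)
  if (!all(c("state", "duration") %in% names(df)))
    stop("malformed dwell file (need `state,duration` header after the `# dt` line): ", path)
  if (any(df$duration < 1)) stop("durations must be >= 1 sample: ", path)
  if (nrow(df) > 1 && any(diff(df$state) == 0))
    stop("dwell states must strictly alternate: ", path)
  structure(data.frame(state = as.integer(df$state),
                       duration = as.integer(df$duration)),
            dt = dt, class = c("dwell_series", "data.frame"))
}

parse_dt_header <- function(path) {
  l1 <- readLines(path, n = 1)
  m <- regmatches(l1, regexec("^# dt ([0-9.eE+-]+)$", l1))[[1]]
  if (length(m) < 2)
    stop("line 1: missing `# dt <seconds>` header in ", path)
  as.numeric(m[2])
}
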