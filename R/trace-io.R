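#' Construct a sampled physiological trace
#'
#' A uniformly sampled single-channel recording, e.g. left-ventricular
#' pressure (mmHg) or coronary flow (mL/min) exported from a chart
#' recorder.
#'
#' @param times Sample times in seconds, strictly increasing and
#'   uniformly spaced.
#' @param values Sample values (mmHg or mL/min); must be finite.
#' @param channel Channel label, e.g. `"LVP"` or `"flow"`.
#' @return An object of class `sampled_trace`.
#' @export
sampled_trace <- function(times, values, channel = "LVP") {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 2L)
  if (!all(is.finite(values))) stop("trace values must be finite")
  dt <- diff(times)
  if (any(dt <= 0)) stop("trace times must be strictly increasing")
  if (diff(range(dt)) > 1e-6)
    stop("trace times must be uniformly spaced (to within 1e-6 s)")
  structure(list(channel = channel,
                 times = as.numeric(times),
                 values = as.numeric(values),
                 rate_hz = 1 / mean(dt)),
            class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace '%s': %d samples @ %.4g Hz, %.4g-%.4g s>\n",
              x$channel, length(x$times), x$rate_hz,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Parse a chart-recorder text export
#'
#' Reads tab- or comma-delimited text exports of the form
#' `time <tab> channel1 <tab> channel2 ...`. Text header and comment
#' lines are skipped, decimal commas are accepted (for tab- or
#' semicolon-delimited files), and a column map assigns channel names.
#'
#' @param path Path to the export file.
#' @param channels Character vector naming the data columns after the
#'   time column. When `NULL`, names are taken from the last header line
#'   if one exists, else `"ch1"`, `"ch2"`, ...
#' @param max_bad_frac Maximum tolerated fraction of unparseable data
#'   rows before a format error is raised (default 0, i.e. any bad row
#'   within the data block is an error; the error names the offending
#'   line numbers).
#' @return A named list of [sampled_trace()] objects, one per channel.
#' @export
parse_chart_export <- function(path, channels = NULL, max_bad_frac = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty export file: ", path)

  split_row <- function(line) {
    line <- trimws(line)
    if (grepl("\t", line)) {
      fields <- strsplit(line, "\t")[[1]]
      fields <- gsub(",", ".", fields, fixed = TRUE)  # decimal comma
    } else if (grepl(";", line)) {
      fields <- strsplit(line, ";")[[1]]
      fields <- gsub(",", ".", fields, fixed = TRUE)
    } else if (grepl(",", line)) {
      fields <- strsplit(line, ",")[[1]]
    } else {
      fields <- strsplit(line, "[[:space:]]+")[[1]]
    }
    trimws(fields)
  }

  parsed <- lapply(lines, split_row)
  numeric_row <- vapply(parsed, function(f)
    length(f) >= 2L && !anyNA(suppressWarnings(as.numeric(f))), logical(1))

  first_data <- match(TRUE, numeric_row)
  if (is.na(first_data)) stop("no numeric data rows found in ", path)

  # bad rows inside the data block (past the header)
  bad <- which(!numeric_row & seq_along(lines) > first_data)
  n_data <- sum(numeric_row)
  if (length(bad) > max_bad_frac * (n_data + length(bad))) {
    stop("unparseable data rows at line(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", " in ", path)
  }

  data_rows <- parsed[numeric_row]
  ncols <- length(data_rows[[1]])
  if (any(vapply(data_rows, length, integer(1)) != ncols))
    stop("inconsistent column counts among data rows in ", path)
  mat <- matrix(as.numeric(unlist(data_rows)), ncol = ncols, byrow = TRUE)

  if (is.null(channels)) {
    header_idx <- if (first_data > 1L) first_data - 1L else NA_integer_
    hdr <- if (!is.na(header_idx)) parsed[[header_idx]] else NULL
    channels <- if (!is.null(hdr) && length(hdr) == ncols) {
      hdr[-1]
    } else {
      paste0("ch", seq_len(ncols - 1L))
    }
  }
  if (length(channels) != ncols - 1L)
    stop("expected ", length(channels), " data columns, found ", ncols - 1L)

  times <- mat[, 1]
  out <- lapply(seq_along(channels), function(j)
    sampled_trace(times, mat[, j + 1L], channel = channels[j]))
  names(out) <- channels
  out
}

#' Write traces as a chart-recorder-style text export
#'
#' Writes a tab-delimited file with a `time` column and one column per
#' trace, preceded by a channel-name header line. The output round-trips
#' through [parse_chart_export()].
#'
#' @param traces A named list of [sampled_trace()] objects sharing one
#'   time base.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chart_export <- function(traces, path) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "sampled_trace")))
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(t0) || max(abs(tr$times - t0)) > 1e-9)
      stop("all traces must share one time base")
  }
  labels <- vapply(traces, `[[`, character(1), "channel")
  mat <- cbind(t0, do.call(cbind, lapply(traces, `[[`, "values")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", labels), collapse = "\t"), con)
  utils::write.table(format(mat, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
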