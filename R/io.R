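## Plain-text trace/curve files: a `#`-prefixed `key: value` header block
## followed by tab-separated data columns.  Output is deterministic (fixed
## key order, %.10g float formatting) so identical objects give
## byte-identical files.

trace_columns <- list(
  current_trace = c("time", "current"),
  ecs_trace = c("time", "signal"),
  fluor_trace = c("time", "fluorescence"),
  sans_curve = c("q", "intensity", "sigma"),
  cd_spectrum = c("wavelength", "cd_signal")
)

header_line <- function(key, value) {
  if (is.null(value) || !length(value)) return(NULL)
  sprintf("# %s: %s", key, paste(vapply(value, function(v) {
    if (is.numeric(v)) fmt_num(v) else as.character(v)
  }, character(1)), collapse = " "))
}

truth_lines <- function(metadata) {
  tr <- metadata$truth
  if (is.null(tr)) return(NULL)
  keep <- vapply(tr, function(v) is.atomic(v) && length(v) >= 1L, logical(1))
  unlist(lapply(names(tr)[keep], function(k) {
    header_line(paste0("truth_", k), tr[[k]])
  }))
}

#' Write a trace or curve to a plain-text file
#'
#' @param object A [current_trace()], [ecs_trace()], [fluor_trace()],
#'   [sans_curve()] or [cd_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(object, path) {
  UseMethod("write_trace")
}

write_data_block <- function(path, header, columns) {
  cols <- columns[!vapply(columns, is.null, logical(1))]
  lines <- c(header,
             paste(names(cols), collapse = "\t"),
             do.call(paste, c(lapply(cols, function(x) {
               vapply(x, fmt_num, character(1))
             }), sep = "\t")))
  con <- file(path, open = "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @export
write_trace.current_trace <- function(object, path) {
  header <- c(
    header_line("kind", "current_trace"),
    header_line("sampling_rate", object$sampling_rate),
    header_line("holding_potential_mv", object$holding_potential),
    header_line("temperature_k", object$ionic$temperature_k),
    header_line("ionic_cis", paste0(names(object$ionic$cis), "=",
                                    vapply(object$ionic$cis, fmt_num,
                                           character(1)),
                                    collapse = ",")),
    header_line("ionic_trans", paste0(names(object$ionic$trans), "=",
                                      vapply(object$ionic$trans, fmt_num,
                                             character(1)),
                                      collapse = ",")),
    header_line("seed", object$metadata$seed),
    truth_lines(object$metadata)
  )
  write_data_block(path, header,
                   list(time = object$time, current = object$current))
}

#' @export
write_trace.ecs_trace <- function(object, path) {
  pr <- object$protocol
  header <- c(
    header_line("kind", "ecs_trace"),
    header_line("sampling_rate", object$sampling_rate),
    header_line("baseline", pr$baseline),
    header_line("flashes", pr$flashes),
    header_line("light_on", pr$light_on),
    header_line("dark_intervals", pr$dark_intervals),
    header_line("interval_s", pr$interval_s),
    header_line("tail", pr$tail),
    header_line("seed", object$metadata$truth$seed),
    truth_lines(object$metadata)
  )
  write_data_block(path, header,
                   list(time = object$time, signal = object$signal))
}

#' @export
write_trace.fluor_trace <- function(object, path) {
  header <- c(
    header_line("kind", "fluor_trace"),
    header_line("sampling_rate", object$sampling_rate),
    header_line("f_m", object$f_m),
    header_line("pulse_times", object$pulse_times),
    truth_lines(object$metadata)
  )
  write_data_block(path, header,
                   list(time = object$time,
                        fluorescence = object$fluorescence))
}

#' @export
write_trace.sans_curve <- function(object, path) {
  header <- c(header_line("kind", "sans_curve"), truth_lines(object$metadata))
  write_data_block(path, header,
                   list(q = object$q, intensity = object$intensity,
                        sigma = object$sigma))
}

#' @export
write_trace.cd_spectrum <- function(object, path) {
  header <- c(
    header_line("kind", "cd_spectrum"),
    header_line("normalization", object$normalization),
    truth_lines(object$metadata)
  )
  write_data_block(path, header,
                   list(wavelength = object$wavelength,
                        cd_signal = object$cd_signal))
}

parse_header <- function(lines) {
  hdr_idx <- grep("^#", lines)
  kv <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

num_field <- function(kv, key) {
  if (is.null(kv[[key]])) return(NULL)
  as.numeric(strsplit(kv[[key]], "\\s+")[[1]])
}

parse_ionic_side <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1]], "=")
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[[`, character(1), 1))
}

read_truth <- function(kv) {
  keys <- grep("^truth_", names(kv), value = TRUE)
  if (!length(keys)) return(NULL)
  tr <- lapply(keys, function(k) {
    v <- suppressWarnings(num_field(kv, k))
    if (any(is.na(v))) kv[[k]] else v
  })
  stats::setNames(tr, sub("^truth_", "", keys))
}

#' Read a trace or curve from a plain-text file
#'
#' Dispatches on the mandatory `kind` header key and returns the matching
#' typed object; the time column is checked for monotonicity and the data
#' for missing values, and the declared sampling rate must agree with the
#' time grid.
#'
#' @param path File written by [write_trace()] (or conforming to its
#'   format).
#' @return A [current_trace()], [ecs_trace()], [fluor_trace()],
#'   [sans_curve()] or [cd_spectrum()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- parse_header(lines)
  if (is.null(kv$kind)) {
    stop_thylakoidr("missing mandatory `kind` header", "missing_metadata")
  }
  kind <- kv$kind
  if (!kind %in% names(trace_columns)) {
    stop_thylakoidr(sprintf("unknown trace kind '%s'", kind), "unknown_kind")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- strsplit(body[1], "\t")[[1]]
  dat <- utils::read.table(text = body[-1], sep = "\t", col.names = cols,
                           colClasses = "numeric")
  if (any(!stats::complete.cases(dat)) ||
      any(!vapply(dat, function(x) all(is.finite(x)), logical(1)))) {
    stop_thylakoidr("missing or non-finite values in data block",
                    "bad_values")
  }
  if ("time" %in% cols && any(diff(dat$time) <= 0)) {
    stop_thylakoidr("time column has a backward or repeated step",
                    "nonmonotone_time")
  }
  truth <- read_truth(kv)
  meta <- if (is.null(truth)) list() else list(truth = truth)
  switch(kind,
    current_trace = {
      for (k in c("sampling_rate", "holding_potential_mv", "ionic_cis",
                  "ionic_trans")) {
        if (is.null(kv[[k]])) {
          stop_thylakoidr(sprintf("missing mandatory header key `%s`", k),
                          "missing_metadata")
        }
      }
      if (!is.null(kv$seed)) meta$seed <- as.integer(kv$seed)
      current_trace(
        dat$time, dat$current,
        holding_potential = num_field(kv, "holding_potential_mv"),
        ionic = ionic_condition(
          parse_ionic_side(kv$ionic_cis), parse_ionic_side(kv$ionic_trans),
          temperature_k = if (is.null(kv$temperature_k)) 298.15
                          else as.numeric(kv$temperature_k)),
        sampling_rate = num_field(kv, "sampling_rate"),
        metadata = meta)
    },
    ecs_trace = {
      for (k in c("sampling_rate", "baseline", "light_on")) {
        if (is.null(kv[[k]])) {
          stop_thylakoidr(sprintf("missing mandatory header key `%s`", k),
                          "missing_metadata")
        }
      }
      pr <- ecs_protocol(
        baseline = num_field(kv, "baseline"),
        flashes = if (is.null(kv$flashes)) numeric(0)
                  else num_field(kv, "flashes"),
        light_on = num_field(kv, "light_on"),
        dark_intervals = if (is.null(kv$dark_intervals)) numeric(0)
                         else num_field(kv, "dark_intervals"),
        interval_s = if (is.null(kv$interval_s)) 0.6
                     else num_field(kv, "interval_s"),
        tail = if (is.null(kv$tail)) 0 else num_field(kv, "tail"))
      ecs_trace(dat$time, dat$signal, pr, num_field(kv, "sampling_rate"),
                metadata = meta)
    },
    fluor_trace = {
      for (k in c("sampling_rate", "f_m")) {
        if (is.null(kv[[k]])) {
          stop_thylakoidr(sprintf("missing mandatory header key `%s`", k),
                          "missing_metadata")
        }
      }
      fluor_trace(dat$time, dat$fluorescence,
                  pulse_times = if (is.null(kv$pulse_times)) numeric(0)
                                else num_field(kv, "pulse_times"),
                  f_m = num_field(kv, "f_m"),
                  sampling_rate = num_field(kv, "sampling_rate"),
                  metadata = meta)
    },
    sans_curve = sans_curve(dat$q, dat$intensity,
                            sigma = if ("sigma" %in% cols) dat$sigma,
                            metadata = meta),
    cd_spectrum = cd_spectrum(dat$wavelength, dat$cd_signal,
                              normalization = if (!is.null(kv$normalization))
                                as.numeric(kv$normalization),
                              metadata = meta)
  )
}

#' Read a protocol sidecar file
#'
#' Two-column tab-separated `event` / `time` file as an alternative to the
#' embedded protocol header; recognised events are `baseline_start`,
#' `baseline_end`, `flash`, `light_on`, `light_off` and `light_resume`.
#'
#' @param path Sidecar file path.
#' @return An [ecs_protocol()].
#' @export
read_protocol <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           col.names = c("event", "time"),
                           colClasses = c("character", "numeric"))
  offs <- sort(dat$time[dat$event == "light_off"])
  resumes <- sort(dat$time[dat$event == "light_resume"])
  interval_s <- if (length(offs) && length(resumes) == length(offs)) {
    unique(round(resumes - offs, 9))[1]
  } else 0.6
  ecs_protocol(
    baseline = c(dat$time[dat$event == "baseline_start"][1],
                 dat$time[dat$event == "baseline_end"][1]),
    flashes = sort(dat$time[dat$event == "flash"]),
    light_on = dat$time[dat$event == "light_on"][1],
    dark_intervals = offs,
    interval_s = interval_s)
}

#' Write a protocol sidecar file
#'
#' @param protocol An [ecs_protocol()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "ecs_protocol"))
  ev <- protocol$events
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("event\ttime",
               sprintf("%s\t%s", ev$event,
                       vapply(ev$time, fmt_num, character(1)))),
             con, sep = "\n")
  invisible(path)
}
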