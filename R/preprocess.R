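# Sensor pipeline: long records -> deduplicated wide table -> forward fill
# -> sliding-window summary -> window-aligned annotation labels.

#' Read raw sensor records
#'
#' Accepts JSON-lines records \code{{"t_ms": ..., "sensor": ..., "value": ...}}
#' or a CSV with columns \code{t_ms, sensor, value}.
#'
#' @param path Input file.
#' @param format \code{"auto"} (by extension), \code{"jsonl"} or \code{"csv"}.
#' @return Data.frame with t_ms, sensor, value.
#' @export
read_sensor_records <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path)) "jsonl" else "csv"
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
    data.frame(t_ms = vapply(recs, function(r) as.numeric(r$t_ms), numeric(1)),
               sensor = vapply(recs, function(r) as.character(r$sensor), character(1)),
               value = vapply(recs, function(r) as.numeric(r$value), numeric(1)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Deduplicate raw records into a column-per-sensor table
#'
#' Combines all records sharing a timestamp into one row.  When the same
#' (timestamp, sensor) pair carries several distinct values, the last record
#' wins and a warning is emitted; identical duplicates merge silently.
#'
#' @param records Data.frame with columns t_ms, sensor, value.
#' @param sensors Optional character vector fixing the column schema (and
#'   order); defaults to the sorted sensors present.
#' @return Data.frame with strictly increasing \code{t_ms} and one numeric
#'   column per sensor (NA where unmeasured).
#' @export
deduplicate <- function(records, sensors = NULL) {
  stopifnot(all(c("t_ms", "sensor", "value") %in% names(records)))
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (is.null(sensors)) sensors <- sort(unique(records$sensor))
  bad <- setdiff(unique(records$sensor), sensors)
  if (length(bad))
    stop(sprintf("undeclared sensor(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  ts <- sort(unique(records$t_ms))
  out <- as.data.frame(matrix(NA_real_, length(ts), length(sensors),
                              dimnames = list(NULL, sensors)))
  out <- cbind(data.frame(t_ms = ts), out)
  conflict <- FALSE
  for (i in seq_len(nrow(records))) {
    r <- row.names <- records[i, ]
    ri <- match(r$t_ms, ts)
    cur <- out[ri, r$sensor]
    if (!is.na(cur) && cur != r$value) conflict <- TRUE
    out[ri, r$sensor] <- r$value  # last write wins
  }
  if (conflict)
    warning("conflicting duplicate values at a shared timestamp; last record kept",
            call. = FALSE)
  out
}

#' Forward-fill undefined sensor values
#'
#' Each NA cell is replaced with the nearest previous value of the same
#' sensor.  Leading NAs (before a sensor's first measurement) are filled
#' with the sensor's declared default.  Measured cells are never changed;
#' the returned table carries a \code{"filled"} attribute marking
#' provenance.
#'
#' @param table Wide sensor table from [deduplicate()].
#' @param defaults Named list/vector of per-sensor leading defaults.
#' @param default_value Fallback default for sensors not in \code{defaults}.
#' @return The filled table.
#' @export
forward_fill <- function(table, defaults = list(), default_value = 0) {
  sensors <- setdiff(names(table), "t_ms")
  filled <- matrix(FALSE, nrow(table), length(sensors), dimnames = list(NULL, sensors))
  for (sn in sensors) {
    v <- table[[sn]]
    if (all(is.na(v)) && is.null(defaults[[sn]]) && is.null(default_value))
      stop(sprintf("sensor '%s' has no values and no default", sn), call. = FALSE)
    filled[, sn] <- is.na(v)
    # carry forward
    for (i in seq_along(v)) {
      if (is.na(v[i])) v[i] <- if (i > 1L) v[i - 1L] else NA
    }
    lead <- is.na(v)
    if (any(lead)) {
      d <- defaults[[sn]]
      if (is.null(d)) d <- default_value
      v[lead] <- d
    }
    table[[sn]] <- v
  }
  attr(table, "filled") <- filled
  table
}

#' Sliding-window summarisation
#'
#' Splits each sensor series into windows of \code{w} rows advancing by
#' \code{step = max(1, floor(w * (1 - overlap)))} rows (2 for the default
#' w = 5 with 50\% overlap) and summarises each window per sensor with the
#' aggregate (default max).  Only full windows are emitted; a table shorter
#' than \code{w} yields a single truncated window with a warning.
#'
#' @param table Filled sensor table (with \code{t_ms}).
#' @param w Window size in rows (default 5).
#' @param overlap Overlap fraction in [0, 1) (default 0.5).
#' @param agg \code{"max"} (default) or \code{"mean"}.
#' @return Data.frame with \code{window}, \code{t_start_ms} and one column
#'   per sensor; attributes \code{w}, \code{step} and \code{spans} (raw row
#'   ranges per window).
#' @export
window_table <- function(table, w = 5L, overlap = 0.5, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  stopifnot(w >= 1L, overlap >= 0, overlap < 1)
  sensors <- setdiff(names(table), "t_ms")
  n <- nrow(table)
  step <- max(1L, as.integer(floor(w * (1 - overlap))))
  if (n < w) {
    warning(sprintf("table shorter than window (%d < %d): single truncated window", n, w),
            call. = FALSE)
    starts <- 1L; ends <- n
  } else {
    starts <- seq.int(1L, n - w + 1L, by = step)
    ends <- starts + w - 1L
  }
  fn <- if (agg == "max") max else mean
  out <- data.frame(window = seq_along(starts), t_start_ms = table$t_ms[starts])
  for (sn in sensors) {
    out[[sn]] <- vapply(seq_along(starts), function(i)
      fn(table[[sn]][starts[i]:ends[i]]), numeric(1))
  }
  attr(out, "w") <- w
  attr(out, "step") <- step
  attr(out, "spans") <- data.frame(start = starts, end = ends)
  out
}

#' Align an annotation track to windows
#'
#' Each raw row is labelled with the annotation active at its timestamp
#' (the most recent label whose start time is <= the row's time; rows
#' before the first label get \code{"(unknown)"}).  Each window receives
#' the label occupying the majority of its raw span by dwell time; ties go
#' to the label that starts earliest within the window.
#'
#' @param track Data.frame with columns \code{t_ms} (non-decreasing label
#'   start times) and \code{label}.
#' @param windows Windowed table from [window_table()].
#' @param table The raw sensor table the windows were computed from.
#' @return Character vector of labels, one per window.
#' @export
align_annotation <- function(track, windows, table) {
  stopifnot(all(c("t_ms", "label") %in% names(track)))
  if (is.unsorted(track$t_ms)) stop("annotation times must be non-decreasing", call. = FALSE)
  ts <- table$t_ms
  # active label per raw row
  idx <- findInterval(ts, track$t_ms)
  row_label <- ifelse(idx == 0L, "(unknown)", track$label[pmax(idx, 1L)])
  # dwell time per raw row (gap to the next row; last row gets the median gap)
  gaps <- diff(ts)
  dwell <- c(gaps, if (length(gaps)) stats::median(gaps) else 1)
  spans <- attr(windows, "spans")
  vapply(seq_len(nrow(spans)), function(i) {
    rows <- spans$start[i]:spans$end[i]
    lab <- row_label[rows]
    tot <- tapply(dwell[rows], lab, sum)
    best <- max(tot)
    cand <- names(tot)[tot >= best - 1e-12]
    if (length(cand) == 1L) return(cand)
    # earliest-starting label within the window wins ties
    firsts <- vapply(cand, function(l) min(which(lab == l)), numeric(1))
    cand[which.min(firsts)]
  }, character(1))
}
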