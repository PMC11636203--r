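#' Field of view of the entrance camera
#'
#' Describes the camera-visible region of the entrance tunnel and which image
#' edge adjoins the hive interior. The default 800 x 320 px frame matches the
#' tunnel window used in the field deployments this package targets; the hive
#' is taken to lie beyond the left image edge unless stated otherwise.
#'
#' @param width Frame width in pixels (positive integer).
#' @param height Frame height in pixels (positive integer).
#' @param hive_side Which image edge adjoins the hive interior: one of
#'   `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @return An object of class `fov`: a list with `width`, `height`,
#'   `hive_side`.
#' @examples
#' fov()
#' fov(640, 480, hive_side = "top")
#' @export
fov <- function(width = 800, height = 320, hive_side = "left") {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || width <= 0L) abort("`width` must be a positive integer.")
  if (is.na(height) || height <= 0L) abort("`height` must be a positive integer.")
  hive_side <- match.arg(hive_side, c("left", "right", "top", "bottom"))
  structure(list(width = width, height = height, hive_side = hive_side),
            class = "fov")
}

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov> %d x %d px, hive side: %s\n", x$width, x$height,
              x$hive_side))
  invisible(x)
}

# ---- timestamps --------------------------------------------------------
# Timestamps are naive local time (the field rig has no timezone handling);
# internally they are POSIXct pinned to UTC so arithmetic is unambiguous,
# and they are carried at millisecond resolution so that log round-trips
# are lossless.

ts_round_ms <- function(t) {
  .POSIXct(round(as.numeric(t) * 1000) / 1000, tz = "UTC")
}

format_ts <- function(t) {
  n <- round(as.numeric(t) * 1000)
  sec <- n %/% 1000
  ms <- n %% 1000
  base <- format(.POSIXct(sec, tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
  frac <- ifelse(ms > 0, paste0(".", sub("0+$", "", sprintf("%03d", ms))), "")
  paste0(base, frac)
}

parse_ts <- function(x) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  ts_round_ms(t)
}

# numeric fields are written in full precision so parse(write(x)) == x
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- ""
  out
}

log_header <- "timestamp,tag_id,x,y,theta,cpu_temp"

#' Construct a detection table
#'
#' A detection is one sighting of a tag in one camera frame: tag ID,
#' timestamp, image position, forward-orientation angle, and (optionally) the
#' CPU temperature the logging computer recorded alongside it.
#'
#' @param timestamp POSIXct (or ISO-8601 strings) of each sighting.
#' @param tag_id Non-negative integer tag IDs.
#' @param x,y Image position in pixels, inside the field of view.
#' @param theta Tag forward-orientation angle, degrees in `[0, 360)`.
#' @param cpu_temp Optional device temperature, degrees Celsius (`NA` if not
#'   recorded).
#' @return A tibble with columns `timestamp`, `tag_id`, `x`, `y`, `theta`,
#'   `cpu_temp`, sorted chronologically (stable in input order at ties).
#' @seealso [validate_detections()], [read_detection_log()]
#' @export
detections <- function(timestamp, tag_id, x, y, theta, cpu_temp = NA_real_) {
  if (is.character(timestamp)) timestamp <- parse_ts(timestamp)
  d <- tibble(
    timestamp = ts_round_ms(timestamp),
    tag_id = as.integer(tag_id),
    x = as.numeric(x),
    y = as.numeric(y),
    theta = as.numeric(theta),
    cpu_temp = as.numeric(cpu_temp)
  )
  d[order(d$timestamp), , drop = FALSE]
}

empty_detections <- function() {
  tibble(timestamp = .POSIXct(numeric(0), tz = "UTC"),
         tag_id = integer(0), x = numeric(0), y = numeric(0),
         theta = numeric(0), cpu_temp = numeric(0))
}

#' Validate a detection table against a field of view
#'
#' Checks column presence and the per-field invariants: timestamps present,
#' IDs non-negative integers, positions inside the field of view, angles in
#' `[0, 360)`.
#'
#' @param d A detection tibble (see [detections()]).
#' @param fov A [fov()] object.
#' @return `d`, invisibly, if valid; otherwise an error naming the offending
#'   field.
#' @export
validate_detections <- function(d, fov = beegate::fov()) {
  needed <- c("timestamp", "tag_id", "x", "y", "theta", "cpu_temp")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    abort(paste0("detection table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(d$timestamp)) abort("invalid field `timestamp`: missing values")
  if (anyNA(d$tag_id) || any(d$tag_id < 0L)) {
    abort("invalid field `tag_id`: must be non-negative integers")
  }
  if (anyNA(d$x) || any(d$x < 0 | d$x > fov$width)) {
    abort(sprintf("invalid field `x`: must lie in [0, %d]", fov$width))
  }
  if (anyNA(d$y) || any(d$y < 0 | d$y > fov$height)) {
    abort(sprintf("invalid field `y`: must lie in [0, %d]", fov$height))
  }
  if (anyNA(d$theta) || any(d$theta < 0 | d$theta >= 360)) {
    abort("invalid field `theta`: must lie in [0, 360)")
  }
  invisible(d)
}

default_line_parser <- function(fov) {
  force(fov)
  function(line) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) == 5L) parts <- c(parts, "")
    if (length(parts) != 6L) return("expected 5 or 6 comma-separated fields")
    ts <- parse_ts(parts[1])
    if (is.na(ts)) return("unparseable timestamp")
    id <- suppressWarnings(as.integer(parts[2]))
    if (is.na(id) || id < 0L) return("tag_id must be a non-negative integer")
    x <- suppressWarnings(as.numeric(parts[3]))
    y <- suppressWarnings(as.numeric(parts[4]))
    th <- suppressWarnings(as.numeric(parts[5]))
    if (is.na(x) || x < 0 || x > fov$width) {
      return(sprintf("x outside field of view [0, %d]", fov$width))
    }
    if (is.na(y) || y < 0 || y > fov$height) {
      return(sprintf("y outside field of view [0, %d]", fov$height))
    }
    if (is.na(th) || th < 0 || th >= 360) return("theta outside [0, 360)")
    temp <- if (nzchar(trimws(parts[6]))) {
      suppressWarnings(as.numeric(parts[6]))
    } else NA_real_
    list(timestamp = ts, tag_id = id, x = x, y = y, theta = th,
         cpu_temp = temp)
  }
}

#' Parse a detection log
#'
#' Reads the canonical detection-log dialect: UTF-8 CSV with header
#' `timestamp,tag_id,x,y,theta,cpu_temp`, one detection per line, timestamps
#' ISO-8601 with optional fractional seconds. Output is chronologically
#' ordered (stable sort; ties keep input order). Malformed lines are never
#' silently dropped: in lenient mode (the default, appropriate for field data
#' with glitches) they are skipped and collected in the `problems` attribute;
#' in strict mode the first malformed line aborts the parse.
#'
#' @param lines Character vector of log lines (including the header), or use
#'   [read_detection_log()] for files.
#' @param fov Field of view used to validate positions.
#' @param strict If `TRUE`, abort on the first malformed line.
#' @param parser Optional pluggable line parser for other dialects: a
#'   `function(line)` returning either a named list of fields or a character
#'   string describing the problem.
#' @return A detection tibble, chronologically ordered, with attribute
#'   `problems`: a tibble of `line` (number), `raw` (text), `reason`.
#' @seealso [detection_problems()], [write_detection_log()]
#' @export
parse_detection_lines <- function(lines, fov = beegate::fov(),
                                  strict = FALSE, parser = NULL) {
  parser <- parser %||% default_line_parser(fov)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  problems <- list()
  if (length(lines) == 0L) {
    out <- empty_detections()
    attr(out, "problems") <- tibble(line = integer(0), raw = character(0),
                                    reason = character(0))
    return(out)
  }
  body <- lines
  offset <- 0L
  if (trimws(lines[1]) == log_header) {
    body <- lines[-1]
    offset <- 1L
  }
  recs <- vector("list", length(body))
  ok <- logical(length(body))
  for (i in seq_along(body)) {
    if (!nzchar(trimws(body[i]))) next
    res <- parser(body[i])
    if (is.character(res)) {
      if (strict) {
        abort(sprintf("line %d: %s [%s]", i + offset, res, body[i]))
      }
      problems[[length(problems) + 1L]] <-
        tibble(line = i + offset, raw = body[i], reason = res)
    } else {
      recs[[i]] <- res
      ok[i] <- TRUE
    }
  }
  recs <- recs[ok]
  out <- if (length(recs)) {
    d <- tibble(
      timestamp = ts_round_ms(.POSIXct(
        vapply(recs, function(r) as.numeric(r$timestamp), 0), tz = "UTC")),
      tag_id = vapply(recs, function(r) r$tag_id, 0L),
      x = vapply(recs, function(r) r$x, 0),
      y = vapply(recs, function(r) r$y, 0),
      theta = vapply(recs, function(r) r$theta, 0),
      cpu_temp = vapply(recs, function(r) r$cpu_temp, 0)
    )
    d[order(d$timestamp), , drop = FALSE]  # order() is a stable sort
  } else {
    empty_detections()
  }
  attr(out, "problems") <- if (length(problems)) {
    bind_rows(problems)
  } else {
    tibble(line = integer(0), raw = character(0), reason = character(0))
  }
  out
}

#' @rdname parse_detection_lines
#' @param path Path to a detection-log file.
#' @export
read_detection_log <- function(path, fov = beegate::fov(), strict = FALSE,
                               parser = NULL) {
  parse_detection_lines(readLines(path, warn = FALSE), fov = fov,
                        strict = strict, parser = parser)
}

#' Malformed lines recorded by a lenient parse
#'
#' @param d A detection tibble returned by [parse_detection_lines()].
#' @return A tibble with columns `line`, `raw`, `reason` (zero rows if the
#'   parse was clean).
#' @export
detection_problems <- function(d) {
  attr(d, "problems") %||%
    tibble(line = integer(0), raw = character(0), reason = character(0))
}

#' Write a detection log in the canonical dialect
#'
#' Inverse of [parse_detection_lines()]: emits the header and one CSV line
#' per detection, chronologically ordered, LF line endings. Writing then
#' re-parsing reproduces the input exactly.
#'
#' @param d A detection tibble.
#' @param path Optional output path; if `NULL`, the lines are returned as a
#'   character vector.
#' @param fov Field of view used to validate before writing.
#' @return The log lines, invisibly when `path` is given.
#' @export
write_detection_log <- function(d, path = NULL, fov = beegate::fov()) {
  validate_detections(d, fov)
  d <- d[order(d$timestamp), , drop = FALSE]
  lines <- c(log_header,
             if (nrow(d)) paste(format_ts(d$timestamp), d$tag_id,
                                fmt_num(d$x), fmt_num(d$y), fmt_num(d$theta),
                                fmt_num(d$cpu_temp), sep = ","))
  if (is.null(path)) return(lines)
  con <- file(path, open = "wb")  # binary mode: LF endings everywhere
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(lines)
}

# ---- colony allocation -------------------------------------------------

#' Colony allocation scheme for tag IDs
#'
#' Tag IDs are allocated to colonies in blocks of one thousand by the
#' thousands digit: 1000-1999 to `worker01`, 2000-2999 to `worker02`, ...,
#' 5000-5999 to `worker05`, and 6000-6999 to the colony monitored by the
#' `queen` computer. IDs outside every range (for example the 0-999 block
#' used during system testing) map to the sentinel `"unallocated"`.
#'
#' @param labels Colony labels.
#' @param id_low,id_high Inclusive ID range per colony.
#' @return A tibble with columns `colony`, `id_low`, `id_high`.
#' @examples
#' colony_scheme()
#' colony_of(c(1500, 2000, 6999, 500))
#' @export
colony_scheme <- function(labels = c(paste0("worker0", 1:5), "queen"),
                          id_low = seq(1000L, 6000L, by = 1000L),
                          id_high = id_low + 999L) {
  if (length(labels) != length(id_low) || length(labels) != length(id_high)) {
    abort("`labels`, `id_low` and `id_high` must have equal length.")
  }
  s <- tibble(colony = as.character(labels),
              id_low = as.integer(id_low), id_high = as.integer(id_high))
  if (any(s$id_high < s$id_low)) abort("each `id_high` must be >= `id_low`.")
  s <- s[order(s$id_low), , drop = FALSE]
  if (nrow(s) > 1L && any(s$id_low[-1] <= s$id_high[-nrow(s)])) {
    abort("colony ID ranges must be disjoint.")
  }
  s
}

#' @rdname colony_scheme
#' @param tag_id Integer vector of tag IDs.
#' @param scheme A colony scheme tibble.
#' @return For `colony_of()`: a character vector of colony labels, with
#'   `"unallocated"` for IDs outside every range.
#' @export
colony_of <- function(tag_id, scheme = colony_scheme()) {
  out <- rep("unallocated", length(tag_id))
  for (i in seq_len(nrow(scheme))) {
    hit <- tag_id >= scheme$id_low[i] & tag_id <= scheme$id_high[i]
    out[hit] <- scheme$colony[i]
  }
  out
}
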