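# Domain types for sensor streams and subjects, cohort file I/O, and the
# stream-sufficiency (missing data) accounting.

.parse_iso8601 <- function(x, file = NULL) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable ISO-8601 timestamp %s at row %d%s",
                 x[bad[1]], bad[1],
                 if (is.null(file)) "" else paste0(" of ", file)),
         call. = FALSE)
  }
  out
}

.format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.check_sorted <- function(ts, what, file = NULL) {
  if (is.unsorted(ts, strictly = FALSE)) {
    warning(sprintf("%s timestamps not sorted%s; sorting", what,
                    if (is.null(file)) "" else paste0(" in ", file)),
            call. = FALSE)
    return(order(ts))
  }
  seq_along(ts)
}

#' Self-report scale scores
#'
#' Validated container for exit scores on the three screening instruments:
#' LSAS (0-144), GAD-7 (0-21), PHQ-8 (0-24).
#'
#' @param lsas,gad7,phq8 Integer scores within the instrument ranges.
#' @return A `scale_scores` list.
#' @export
scale_scores <- function(lsas, gad7, phq8) {
  s <- list(lsas = as.integer(lsas), gad7 = as.integer(gad7),
            phq8 = as.integer(phq8))
  for (nm in names(s)) {
    rng <- .SCALE_RANGES[[nm]]
    if (is.na(s[[nm]]) || s[[nm]] < rng[1] || s[[nm]] > rng[2]) {
      stop(sprintf("%s score %s outside instrument range [%d, %d]",
                   toupper(nm), s[[nm]], rng[1], rng[2]), call. = FALSE)
    }
  }
  structure(s, class = "scale_scores")
}

.check_stream <- function(df, cols, subject_id, what, window = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("subject %s: %s stream lacks column(s) %s", subject_id,
                 what, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df)[cols]
  if (nrow(df)) {
    ord <- .check_sorted(df$timestamp, paste("subject", subject_id, what))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    if (anyDuplicated(as.numeric(df$timestamp))) {
      stop(sprintf("subject %s: duplicate %s timestamps", subject_id, what),
           call. = FALSE)
    }
    if (!is.null(window)) {
      if (any(df$timestamp < window[1]) || any(df$timestamp > window[2])) {
        stop(sprintf("subject %s: %s timestamps outside observation window",
                     subject_id, what), call. = FALSE)
      }
    }
  }
  df
}

#' Construct a validated subject record
#'
#' Bundles one subject's five passive data streams, word bag, observation
#' window, local-time offset, and exit self-report scores. Streams are
#' sorted by timestamp (with a warning if they arrive unsorted); range and
#' window invariants are enforced.
#'
#' @param subject_id Opaque identifier string.
#' @param window_start,window_end `POSIXct` UTC bounds of the observation
#'   window (nominally 14 days).
#' @param utc_offset_min Signed minutes to add to UTC to obtain local time;
#'   fixed per subject (night and weeknight windows are local-time).
#' @param audio Data frame `timestamp`, `volume` (non-negative,
#'   device-relative units), `has_speech` (logical).
#' @param gps Data frame `timestamp`, `latitude`, `longitude` (degrees).
#' @param screen Data frame `timestamp`, `state` (`"on"`/`"off"`).
#' @param light Data frame `timestamp`, `lux` (non-negative).
#' @param words Character vector of word tokens, order-free; lowercased at
#'   ingest.
#' @param scores A [scale_scores()] object.
#' @return A `subject_record` list.
#' @export
subject_record <- function(subject_id, window_start, window_end,
                           utc_offset_min, audio, gps, screen, light,
                           words, scores) {
  stopifnot(inherits(window_start, "POSIXct"), inherits(window_end, "POSIXct"))
  if (!(window_start < window_end)) {
    stop("observation window start must precede end", call. = FALSE)
  }
  window <- c(window_start, window_end)

  audio <- .check_stream(audio, c("timestamp", "volume", "has_speech"),
                         subject_id, "audio", window)
  if (nrow(audio) && (any(!is.finite(audio$volume)) || any(audio$volume < 0))) {
    stop(sprintf("subject %s: audio volume must be finite and non-negative",
                 subject_id), call. = FALSE)
  }
  audio$has_speech <- as.logical(audio$has_speech)

  gps <- .check_stream(gps, c("timestamp", "latitude", "longitude"),
                       subject_id, "gps", window)
  if (nrow(gps)) {
    bad <- which(abs(gps$latitude) > 90 | abs(gps$longitude) > 180)
    if (length(bad)) {
      stop(sprintf("subject %s: GPS coordinate out of range at row %d (lat %s, lon %s)",
                   subject_id, bad[1], gps$latitude[bad[1]],
                   gps$longitude[bad[1]]), call. = FALSE)
    }
  }

  screen <- .check_stream(screen, c("timestamp", "state"),
                          subject_id, "screen", window)
  if (nrow(screen) && !all(screen$state %in% c("on", "off"))) {
    stop(sprintf("subject %s: screen state must be 'on' or 'off'", subject_id),
         call. = FALSE)
  }

  light <- .check_stream(light, c("timestamp", "lux"),
                         subject_id, "light", window)
  if (nrow(light) && (any(!is.finite(light$lux)) || any(light$lux < 0))) {
    stop(sprintf("subject %s: illuminance must be finite and non-negative",
                 subject_id), call. = FALSE)
  }

  if (!inherits(scores, "scale_scores")) {
    scores <- do.call(scale_scores, as.list(scores)[c("lsas", "gad7", "phq8")])
  }

  structure(list(
    subject_id = as.character(subject_id),
    window_start = window_start, window_end = window_end,
    utc_offset_min = as.numeric(utc_offset_min),
    audio = audio, gps = gps, screen = screen, light = light,
    words = tolower(as.character(words)),
    scores = scores
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s>\n", x$subject_id))
  cat(sprintf("  window: %s .. %s (UTC%+d min)\n",
              .format_iso8601(x$window_start), .format_iso8601(x$window_end),
              x$utc_offset_min))
  cat(sprintf("  audio %d | gps %d | screen %d | light %d | words %d\n",
              nrow(x$audio), nrow(x$gps), nrow(x$screen), nrow(x$light),
              length(x$words)))
  cat(sprintf("  scores: LSAS %d, GAD-7 %d, PHQ-8 %d\n",
              x$scores$lsas, x$scores$gad7, x$scores$phq8))
  invisible(x)
}

#' Expected sample count for a periodically sampled stream
#'
#' Under perfect periodic sampling at the nominal rate (audio and GPS every
#' 5 minutes, light every 10 minutes) the expected count over a window is
#' `floor(window_minutes / period)`. The screen stream is event-driven and
#' has no nominal rate, so asking for it is an error.
#'
#' @param stream One of `"audio"`, `"gps"`, `"light"`.
#' @param window_start,window_end Window bounds (`POSIXct`).
#' @return Integer expected sample count.
#' @export
#' @examples
#' t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
#' expected_samples("audio", t0, t0 + 14 * 86400)  # 4032
expected_samples <- function(stream, window_start, window_end) {
  stream <- match.arg(stream, c("audio", "gps", "light", "screen"))
  if (stream == "screen") {
    stop("screen is event-driven and has no nominal sampling rate",
         call. = FALSE)
  }
  mins <- as.numeric(difftime(window_end, window_start, units = "mins"))
  if (!(mins > 0)) stop("window length must be positive", call. = FALSE)
  as.integer(floor(mins / .STREAM_PERIOD_MIN[[stream]]))
}

#' Stream-sufficiency accounting for one subject
#'
#' A stream contributes features only if it holds at least half of the
#' samples expected under perfect periodic sampling ("less than half"
#' is strict, so exactly half counts as sufficient). Applies to the
#' audio, GPS, and light streams; screen events are exempt.
#'
#' @param record A [subject_record()].
#' @return Data frame with one row per stream: `stream`, `observed`,
#'   `expected`, `sufficient`.
#' @export
assess_sufficiency <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  streams <- c("audio", "gps", "light")
  observed <- vapply(streams, function(s) nrow(record[[s]]), integer(1))
  expected <- vapply(streams, function(s) {
    expected_samples(s, record$window_start, record$window_end)
  }, integer(1))
  data.frame(stream = streams, observed = unname(observed),
             expected = unname(expected),
             sufficient = unname(observed >= expected / 2),
             stringsAsFactors = FALSE)
}

#' Collapse repeated screen states
#'
#' Consecutive events with the same state carry no transition information;
#' the first of each run is kept so that on/off events alternate.
#'
#' @param screen Screen-event data frame (`timestamp`, `state`), sorted.
#' @return Data frame with alternating states.
#' @export
normalize_screen_events <- function(screen) {
  if (nrow(screen) < 2) return(screen)
  keep <- c(TRUE, screen$state[-1] != screen$state[-nrow(screen)])
  out <- screen[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- cohort file layout ----------------------------------------------------
# <path>/manifest.csv                subject_id, dir
# <path>/<id>/audio.csv              timestamp_iso8601,volume,has_speech
# <path>/<id>/gps.csv                timestamp_iso8601,lat,lon
# <path>/<id>/screen.csv             timestamp_iso8601,state
# <path>/<id>/light.csv              timestamp_iso8601,lux
# <path>/<id>/words.txt              one lowercase token per line, unordered
# <path>/<id>/subject.json           ids, window, utc offset, scale scores

#' Write a cohort to the on-disk layout
#'
#' One directory per subject (CSV streams + `words.txt` + `subject.json`)
#' plus a `manifest.csv`. [read_cohort()] of the result reproduces the
#' cohort exactly (timestamps to the second, numeric fields to written
#' precision).
#'
#' @param cohort List of [subject_record()]s.
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create cohort directory ", path)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  data.table::fwrite(
    data.table::data.table(subject_id = ids, dir = ids),
    file.path(path, "manifest.csv"))
  for (rec in cohort) write_subject(rec, file.path(path, rec$subject_id))
  invisible(path)
}

#' @rdname write_cohort
#' @param record A single [subject_record()].
#' @param dir Directory for that subject.
#' @export
write_subject <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::data.table(
    timestamp_iso8601 = .format_iso8601(record$audio$timestamp),
    volume = record$audio$volume,
    has_speech = as.integer(record$audio$has_speech)
  ), file.path(dir, "audio.csv"))
  data.table::fwrite(data.table::data.table(
    timestamp_iso8601 = .format_iso8601(record$gps$timestamp),
    lat = record$gps$latitude, lon = record$gps$longitude
  ), file.path(dir, "gps.csv"))
  data.table::fwrite(data.table::data.table(
    timestamp_iso8601 = .format_iso8601(record$screen$timestamp),
    state = record$screen$state
  ), file.path(dir, "screen.csv"))
  data.table::fwrite(data.table::data.table(
    timestamp_iso8601 = .format_iso8601(record$light$timestamp),
    lux = record$light$lux
  ), file.path(dir, "light.csv"))
  writeLines(record$words, file.path(dir, "words.txt"))
  jsonlite::write_json(list(
    subject_id = record$subject_id,
    window_start = .format_iso8601(record$window_start),
    window_end = .format_iso8601(record$window_end),
    utc_offset_minutes = record$utc_offset_min,
    lsas = record$scores$lsas, gad7 = record$scores$gad7,
    phq8 = record$scores$phq8
  ), file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.read_stream_csv <- function(file, subject_id) {
  if (!file.exists(file)) {
    stop(sprintf("subject %s: missing required file %s", subject_id, file),
         call. = FALSE)
  }
  df <- as.data.frame(data.table::fread(file, colClasses = list(
    character = "timestamp_iso8601")))
  df$timestamp <- .parse_iso8601(df$timestamp_iso8601, file)
  df
}

#' Read one subject directory
#'
#' @param dir Subject directory in the documented layout.
#' @param subject_id Identifier used in error messages (defaults to the
#'   directory basename until `subject.json` is read).
#' @return A validated [subject_record()].
#' @export
read_subject <- function(dir, subject_id = basename(dir)) {
  meta_file <- file.path(dir, "subject.json")
  if (!file.exists(meta_file)) {
    stop(sprintf("subject %s: missing required file %s", subject_id,
                 meta_file), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)

  audio <- .read_stream_csv(file.path(dir, "audio.csv"), subject_id)
  gps <- .read_stream_csv(file.path(dir, "gps.csv"), subject_id)
  screen <- .read_stream_csv(file.path(dir, "screen.csv"), subject_id)
  light <- .read_stream_csv(file.path(dir, "light.csv"), subject_id)

  bad <- which(abs(gps$lat) > 90 | abs(gps$lon) > 180)
  if (length(bad)) {
    stop(sprintf("parse error in %s row %d: coordinate out of range (lat %s, lon %s)",
                 file.path(dir, "gps.csv"), bad[1], gps$lat[bad[1]],
                 gps$lon[bad[1]]), call. = FALSE)
  }
  bad <- which(light$lux < 0)
  if (length(bad)) {
    stop(sprintf("parse error in %s row %d: negative illuminance %s",
                 file.path(dir, "light.csv"), bad[1], light$lux[bad[1]]),
         call. = FALSE)
  }

  words_file <- file.path(dir, "words.txt")
  if (!file.exists(words_file)) {
    stop(sprintf("subject %s: missing required file %s", subject_id,
                 words_file), call. = FALSE)
  }
  words <- readLines(words_file)
  words <- words[nzchar(words)]

  subject_record(
    subject_id = meta$subject_id,
    window_start = .parse_iso8601(meta$window_start, meta_file),
    window_end = .parse_iso8601(meta$window_end, meta_file),
    utc_offset_min = meta$utc_offset_minutes,
    audio = data.frame(timestamp = audio$timestamp, volume = audio$volume,
                       has_speech = as.logical(audio$has_speech)),
    gps = data.frame(timestamp = gps$timestamp, latitude = gps$lat,
                     longitude = gps$lon),
    screen = data.frame(timestamp = screen$timestamp, state = screen$state,
                        stringsAsFactors = FALSE),
    light = data.frame(timestamp = light$timestamp, lux = light$lux),
    words = words,
    scores = scale_scores(meta$lsas, meta$gad7, meta$phq8)
  )
}

#' Read a cohort from the on-disk layout
#'
#' @param path Cohort directory containing `manifest.csv` and one
#'   subdirectory per subject.
#' @return List of [subject_record()]s in manifest order.
#' @export
read_cohort <- function(path) {
  manifest_file <- file.path(path, "manifest.csv")
  if (!file.exists(manifest_file)) {
    stop("no cohort manifest at ", manifest_file, call. = FALSE)
  }
  manifest <- as.data.frame(data.table::fread(manifest_file,
                                              colClasses = "character"))
  lapply(seq_len(nrow(manifest)), function(i) {
    read_subject(file.path(path, manifest$dir[i]), manifest$subject_id[i])
  })
}
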