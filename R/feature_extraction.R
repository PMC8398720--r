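# Per-subject computation of the eight behavioral features, honoring the
# stream-sufficiency rule. Missingness is data here, not failure: every
# feature function returns NA when its input does not support a value.

#' Regularize the audio volume series onto a fixed grid
#'
#' Bins the irregular volume samples onto a `bin_width_min`-minute grid
#' anchored at the window start: bin value = mean volume of samples in the
#' bin, `NA` for empty bins. The 24-hour autocorrelation needs a regular
#' grid; the default bin width mirrors the nominal 5-minute sampling
#' period.
#'
#' @param audio Audio data frame (`timestamp`, `volume`), sorted.
#' @param window_start,window_end Observation window (`POSIXct`).
#' @param bin_width_min Bin width in minutes.
#' @return Numeric vector of length `floor(window_minutes / bin_width)`.
#' @export
bin_volume <- function(audio, window_start, window_end, bin_width_min = 5) {
  mins <- as.numeric(difftime(window_end, window_start, units = "mins"))
  n_bins <- floor(mins / bin_width_min)
  v <- rep(NA_real_, n_bins)
  if (nrow(audio) == 0 || n_bins == 0) return(v)
  idx <- floor(as.numeric(difftime(audio$timestamp, window_start,
                                   units = "mins")) / bin_width_min) + 1
  keep <- idx >= 1 & idx <= n_bins
  if (!any(keep)) return(v)
  m <- tapply(audio$volume[keep], idx[keep], mean)
  v[as.integer(names(m))] <- as.numeric(m)
  v
}

#' Daily similarity: 24-hour autocorrelation of ambient volume
#'
#' Pearson correlation between the binned volume series and itself shifted
#' by 24 hours, computed over all bin pairs where both values are present.
#' High values indicate that the daily peaks and troughs of ambient volume
#' (daytime activity, nighttime quiet) recur at the same clock time across
#' days. Lag-paired Pearson (rather than the full-series autocovariance
#' ratio) is robust to missing bins.
#'
#' @param series Binned volume vector from [bin_volume()].
#' @param bin_width_min Bin width used to build `series`, minutes; the lag
#'   is `24 * 60 / bin_width_min` bins and must be a whole number.
#' @return Correlation in `[-1, 1]`, or `NA` when fewer than 2 complete
#'   pairs exist or either lagged slice has zero variance.
#' @export
daily_similarity <- function(series, bin_width_min = 5) {
  lag <- 24 * 60 / bin_width_min
  if (lag != round(lag)) stop("bin width must divide 24 hours evenly")
  lag <- as.integer(lag)
  n <- length(series)
  if (n <= lag + 1) return(NA_real_)
  x <- series[seq_len(n - lag)]
  y <- series[(lag + 1):n]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Speech presence
#'
#' Fraction of audio recordings labeled as containing speech.
#'
#' @param audio Audio data frame with logical `has_speech`.
#' @return Proportion in `[0, 1]`, `NA` for an empty stream.
#' @export
speech_presence <- function(audio) {
  if (nrow(audio) == 0) return(NA_real_)
  mean(audio$has_speech)
}

#' Weeknight sleep disturbance
#'
#' Sample standard deviation (n-1 denominator) of ambient volume during
#' weeknights between local midnight and 6 AM, a proxy for how noisy the
#' environment is during common sleeping hours. Weekend nights are
#' excluded; by default the qualifying morning blocks are Tuesday through
#' Saturday (the nights following Monday-Friday evenings), switchable to
#' Monday-Friday mornings via `weeknight_wdays`.
#'
#' Volume units are device-relative; this feature is only ever used as a
#' within-subject statistic.
#'
#' @param audio Audio data frame (`timestamp`, `volume`).
#' @param utc_offset_min Local-time offset, minutes.
#' @param weeknight_wdays Local weekdays (0 = Sunday) whose morning block
#'   qualifies.
#' @param night_start_h,night_end_h Local night window, hours.
#' @return Standard deviation, or `NA` with fewer than 2 qualifying
#'   samples.
#' @export
weeknight_sleep_disturbance <- function(audio, utc_offset_min,
                                        weeknight_wdays = 2:6,
                                        night_start_h = 0, night_end_h = 6) {
  if (nrow(audio) == 0) return(NA_real_)
  loc <- as.numeric(audio$timestamp) + utc_offset_min * 60
  hour <- (loc %% 86400) / 3600
  # 1970-01-01 was a Thursday (wday 4)
  wday <- (floor(loc / 86400) + 4) %% 7
  qual <- hour >= night_start_h & hour < night_end_h & wday %in% weeknight_wdays
  if (sum(qual) < 2) return(NA_real_)
  sd(audio$volume[qual])
}

#' Read a lexicon file
#'
#' One lowercase entry per line; a trailing `*` marks a prefix wildcard.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the lexicon file.
#' @param name Category name attached to the lexicon.
#' @return A `lexicon` list with `exact` and `prefix` entry sets.
#' @export
read_lexicon <- function(path, name = basename(path)) {
  entries <- trimws(readLines(path))
  entries <- tolower(entries[nzchar(entries) & !startsWith(entries, "#")])
  entries <- unique(entries)
  if (!length(entries)) stop("lexicon is empty: ", path, call. = FALSE)
  wild <- endsWith(entries, "*")
  structure(list(name = name,
                 exact = entries[!wild],
                 prefix = sub("\\*$", "", entries[wild])),
            class = "lexicon")
}

#' Bundled open death-related-words lexicon
#'
#' An open word list covering the death semantic category (die, death,
#' funeral, grave, mourn, ...). It stands in for the proprietary LIWC
#' death dictionary, which cannot be redistributed: category semantics are
#' preserved but exact counts will differ from LIWC's.
#'
#' @return A `lexicon` (see [read_lexicon()]).
#' @export
death_lexicon <- function() {
  read_lexicon(system.file("extdata", "death_lexicon.txt",
                           package = "phenoscreen"), name = "death")
}

.match_lexicon <- function(words, lexicon) {
  hit <- words %in% lexicon$exact
  for (p in lexicon$prefix) hit <- hit | startsWith(words, p)
  hit
}

#' Percentage of death-related words
#'
#' Share (in percent) of all collected word tokens matching the death
#' lexicon; wildcard entries match by prefix.
#'
#' @param words Character vector of lowercase tokens (order-free bag).
#' @param lexicon A `lexicon`; defaults to the bundled death list.
#' @return Percent in `[0, 100]`, `NA` for an empty bag.
#' @export
death_related_words <- function(words, lexicon = death_lexicon()) {
  if (length(words) == 0) return(NA_real_)
  100 * mean(.match_lexicon(tolower(words), lexicon))
}

#' Screen use
#'
#' Proportion of the observation window during which the screen is on.
#' The state before the first event is taken as the complement of that
#' event's state, and the last state persists to the window end.
#'
#' @param screen Screen events (`timestamp`, `state`), sorted; repeated
#'   states are collapsed internally.
#' @param window_start,window_end Observation window.
#' @return Proportion in `[0, 1]`, `NA` with no events.
#' @export
screen_use <- function(screen, window_start, window_end) {
  screen <- normalize_screen_events(screen)
  if (nrow(screen) == 0) return(NA_real_)
  t <- as.numeric(screen$timestamp)
  t0 <- as.numeric(window_start)
  t1 <- as.numeric(window_end)
  bounds <- c(t0, pmin(pmax(t, t0), t1), t1)
  states <- c(ifelse(screen$state[1] == "on", "off", "on"), screen$state)
  on_s <- sum(diff(bounds)[states == "on"])
  on_s / (t1 - t0)
}

#' Time in darkness
#'
#' Fraction of light-sensor readings measuring an illuminance strictly
#' below `dark_lux` (default 5 lux, a very dark environment).
#'
#' @param light Light samples data frame with `lux`.
#' @param dark_lux Darkness threshold, lux (strict `<`).
#' @return Proportion in `[0, 1]`, `NA` for an empty stream.
#' @export
time_in_darkness <- function(light, dark_lux = 5) {
  if (nrow(light) == 0) return(NA_real_)
  mean(light$lux < dark_lux)
}

#' Extract the eight-feature vector for one subject
#'
#' Applies the stream-sufficiency rule: the four audio-derived features
#' (daily similarity, speech presence, weeknight sleep disturbance,
#' death-related words) are missing when the audio stream is insufficient;
#' the two location features are missing when the GPS stream is
#' insufficient or the home cluster is undefined; time in darkness is
#' missing when the light stream is insufficient; screen use is missing
#' only when there are no screen events (the screen stream is event-driven
#' and exempt from the rule). Individual features can additionally be
#' missing on their own degenerate inputs (empty word bag, constant
#' volume, ...).
#'
#' @param record A [subject_record()].
#' @param sufficiency Optional precomputed [assess_sufficiency()] result.
#' @param config Analysis configuration, see [default_config()].
#' @param lexicon Death lexicon (defaults to the bundled list).
#' @return Named numeric vector of the eight features (`NA` = missing).
#' @export
extract_features <- function(record, sufficiency = NULL,
                             config = default_config(),
                             lexicon = death_lexicon()) {
  if (is.null(sufficiency)) sufficiency <- assess_sufficiency(record)
  suff <- stats::setNames(sufficiency$sufficient, sufficiency$stream)
  out <- stats::setNames(rep(NA_real_, length(.PHENO_FEATURES)),
                         .PHENO_FEATURES)

  if (isTRUE(suff[["audio"]]) && nrow(record$audio) > 0) {
    series <- bin_volume(record$audio, record$window_start,
                         record$window_end,
                         config$features$bin_width_min)
    out["daily_similarity"] <- daily_similarity(
      series, config$features$bin_width_min)
    out["speech_presence"] <- speech_presence(record$audio)
    out["weeknight_sleep_disturbance"] <- weeknight_sleep_disturbance(
      record$audio, record$utc_offset_min, config$weeknight_wdays,
      config$night$start_hour, config$night$end_hour)
    out["death_related_words"] <- death_related_words(record$words, lexicon)
  }

  if (isTRUE(suff[["gps"]]) && nrow(record$gps) > 0) {
    pts <- stationary_points(record$gps, record$window_end,
                             config$stationary$speed_kmh,
                             config$stationary$dwell_cap_min)
    if (nrow(pts) > 0) {
      labels <- dbscan_geo(pts, config$dbscan$eps_m, config$dbscan$min_pts)
      home <- infer_home(pts, labels, record$utc_offset_min,
                         config$night$start_hour, config$night$end_hour)
      if (!is.na(home)) {
        out["locations_visited"] <- count_locations(labels)
        out["exits_from_home"] <- count_exits(labels, home)
      }
    }
  }

  out["screen_use"] <- screen_use(record$screen, record$window_start,
                                  record$window_end)

  if (isTRUE(suff[["light"]])) {
    out["time_in_darkness"] <- time_in_darkness(record$light,
                                                config$features$dark_lux)
  }
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort List of [subject_record()]s.
#' @param config Analysis configuration.
#' @param lexicon Death lexicon.
#' @return Data frame `subject_id` + the eight feature columns, with the
#'   per-subject sufficiency table attached as attribute `"sufficiency"`.
#' @export
extract_cohort_features <- function(cohort, config = default_config(),
                                    lexicon = death_lexicon()) {
  suff_list <- lapply(cohort, assess_sufficiency)
  feats <- t(vapply(seq_along(cohort), function(i) {
    extract_features(cohort[[i]], suff_list[[i]], config, lexicon)
  }, numeric(length(.PHENO_FEATURES))))
  out <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    feats, stringsAsFactors = FALSE)
  suff <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    cbind(subject_id = cohort[[i]]$subject_id, suff_list[[i]])
  }))
  attr(out, "sufficiency") <- suff
  out
}
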