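t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")  # a Monday

test_that("volume binning averages within bins and marks empty bins missing", {
  audio <- data.frame(
    timestamp = t0 + c(60, 400, 430, 2000),
    volume = c(0.5, 1, 3, 0.2), has_speech = FALSE)
  v <- bin_volume(audio, t0, t0 + 3000, bin_width_min = 5)
  expect_length(v, 10)
  expect_equal(v[1], 0.5)
  expect_equal(v[2], 2)        # mean of 1 and 3
  expect_true(all(is.na(v[3:6])))
  expect_equal(v[7], 0.2)
  expect_true(all(is.na(v[8:10])))
})

test_that("daily similarity is 1 for an exactly 24h-periodic series", {
  n <- 14 * 288
  v <- sin(2 * pi * seq_len(n) / 288)
  expect_equal(daily_similarity(v, 5), 1.0, tolerance = 1e-9)
  expect_true(is.na(daily_similarity(rep(3, n), 5)))     # zero variance
  expect_true(is.na(daily_similarity(numeric(10), 5)))   # too short
})

test_that("daily similarity equals the brute-force lagged Pearson oracle", {
  set.seed(601)
  n <- 2 * 288
  v <- sin(2 * pi * seq_len(n) / 288) + rnorm(n, 0, 0.3)
  v[sample.int(n, 60)] <- NA  # missing bins are tolerated
  expect_equal(daily_similarity(v, 5), oracle_pearson_lag(v, 288),
               tolerance = 1e-12)
})

test_that("daily similarity is invariant to affine volume rescaling", {
  set.seed(602)
  v <- sin(2 * pi * seq_len(3 * 288) / 288) + rnorm(3 * 288, 0, 0.2)
  expect_equal(daily_similarity(2.5 * v + 7, 5), daily_similarity(v, 5),
               tolerance = 1e-12)
})

test_that("speech presence is the labeled fraction of recordings", {
  mk <- function(flags) data.frame(timestamp = t0 + 300 * seq_along(flags),
                                   volume = 1, has_speech = flags)
  expect_equal(speech_presence(mk(rep(c(TRUE, rep(FALSE, 19)), 3))), 3 / 60)
  expect_equal(speech_presence(mk(rep(FALSE, 10))), 0)
  expect_equal(speech_presence(mk(rep(TRUE, 10))), 1)
  empty <- data.frame(timestamp = t0[0], volume = numeric(0),
                      has_speech = logical(0))
  expect_true(is.na(speech_presence(empty)))
})

test_that("weeknight sleep disturbance filters by local weeknight window", {
  # window starts Monday; Tuesday 00:00-06:00 local is a weeknight block
  tue_night <- t0 + 86400 + c(1, 2, 3) * 3600   # Tue 01:00-03:00 UTC
  audio <- data.frame(timestamp = tue_night, volume = c(0.1, 0.1, 0.1),
                      has_speech = FALSE)
  expect_equal(weeknight_sleep_disturbance(audio, 0), 0)

  audio2 <- data.frame(timestamp = tue_night[1:2], volume = c(0, 2),
                       has_speech = FALSE)
  expect_equal(weeknight_sleep_disturbance(audio2, 0), sqrt(2))

  # fewer than 2 qualifying samples -> missing
  expect_true(is.na(weeknight_sleep_disturbance(audio[1, ], 0)))

  # samples outside the window never change the value
  day_noise <- data.frame(timestamp = t0 + c(12, 36, 60) * 3600 + 1,
                          volume = c(9, 9, 9), has_speech = FALSE)
  expect_equal(weeknight_sleep_disturbance(rbind(audio, day_noise), 0),
               weeknight_sleep_disturbance(audio, 0))

  # Monday morning qualifies only under the Mon-Fri variant
  mon_night <- t0 + c(1, 2) * 3600  # Mon 01:00, 02:00
  audio3 <- data.frame(timestamp = mon_night, volume = c(0, 2),
                       has_speech = FALSE)
  expect_true(is.na(weeknight_sleep_disturbance(audio3, 0)))
  expect_equal(weeknight_sleep_disturbance(audio3, 0,
                                           weeknight_wdays = 1:5), sqrt(2))
})

test_that("weeknight filter agrees with an independent calendar oracle", {
  g <- generate_cohort(no_dropout_config(n_subjects = 1, seed = 603))
  rec <- g$cohort[[1]]
  got <- weeknight_sleep_disturbance(rec$audio, rec$utc_offset_min)
  # oracle: POSIXlt local calendar, weekday names
  lt <- as.POSIXlt(rec$audio$timestamp + rec$utc_offset_min * 60, tz = "UTC")
  qual <- lt$hour < 6 &
    weekdays(as.Date(lt)) %in% c("Tuesday", "Wednesday", "Thursday",
                                 "Friday", "Saturday")
  expect_equal(got, sd(rec$audio$volume[qual]), tolerance = 1e-12)
})

test_that("death-related word percentage uses exact and prefix matching", {
  lex <- structure(list(name = "death", exact = character(0), prefix = "die"),
                   class = "lexicon")
  bag <- c(rep("walk", 98), "died", "dies")
  expect_equal(death_related_words(bag, lex), 2.0)
  expect_equal(death_related_words(rep("walk", 50), lex), 0)
  # prefix semantics: "died" matches die*, "day" and "dying" do not
  expect_equal(death_related_words(c("died", "dying", "day"), lex),
               100 / 3, tolerance = 0.01)
  expect_true(is.na(death_related_words(character(0), lex)))
  # bundled lexicon covers the generator's death vocabulary
  expect_equal(death_related_words(c("funeral", "mourning", "suicide",
                                     "graveyard", "deaths"),
                                   death_lexicon()), 100)
  expect_equal(death_related_words(c("daytime", "dinner", "grateful",
                                     "diet", "gravel"), death_lexicon()), 0)
})

test_that("screen use integrates on-time over the window", {
  scr <- function(h, s) data.frame(timestamp = t0 + h * 60, state = s,
                                   stringsAsFactors = FALSE)
  # on at t0, off at t0+6min, 60-min window
  ev <- rbind(scr(0, "on"), scr(6, "off"))
  expect_equal(screen_use(ev, t0, t0 + 3600), 0.1)
  # single off at window start: screen was on before... complement rule
  expect_equal(screen_use(scr(0, "off"), t0, t0 + 3600), 0)
  # single on at start -> on for the whole window
  expect_equal(screen_use(scr(0, "on"), t0, t0 + 3600), 1)
  expect_true(is.na(screen_use(scr(0, "on")[0, ], t0, t0 + 3600)))
})

test_that("screen use matches the interval-accumulation oracle", {
  set.seed(604)
  for (i in 1:5) {
    n_ev <- sample(10:60, 1)
    times <- sort(sample.int(14 * 86400 - 10, n_ev))
    first <- sample(c("on", "off"), 1)
    states <- rep(c(first, setdiff(c("on", "off"), first)),
                  length.out = n_ev)
    ev <- data.frame(timestamp = t0 + times, state = states,
                     stringsAsFactors = FALSE)
    expect_equal(screen_use(ev, t0, t0 + 14 * 86400),
                 oracle_screen_on(ev, t0, t0 + 14 * 86400),
                 tolerance = 1e-12)
  }
})

test_that("time in darkness uses a strict 5-lux threshold", {
  mk <- function(lux) data.frame(timestamp = t0 + 600 * seq_along(lux),
                                 lux = lux)
  expect_equal(time_in_darkness(mk(c(1, 10, 3, 200))), 0.5)
  expect_equal(time_in_darkness(mk(5)), 0)      # boundary excluded
  expect_equal(time_in_darkness(mk(c(0, 1, 4.9))), 1)
  expect_true(is.na(time_in_darkness(mk(numeric(0)))))
})

test_that("feature extraction honors the stream-to-feature missingness map", {
  g <- generate_cohort(no_dropout_config(n_subjects = 1, seed = 605))
  rec <- g$cohort[[1]]
  f <- extract_features(rec)
  expect_named(f, pheno_features())
  expect_false(anyNA(f))
  expect_true(f[["daily_similarity"]] >= -1 && f[["daily_similarity"]] <= 1)
  expect_true(all(f[c("speech_presence", "screen_use",
                      "time_in_darkness")] >= 0 &
                  f[c("speech_presence", "screen_use",
                      "time_in_darkness")] <= 1))

  # audio below half expected -> exactly the 4 audio features missing
  rec2 <- rec
  rec2$audio <- rec$audio[seq_len(2000), ]
  f2 <- extract_features(rec2)
  expect_true(all(is.na(f2[c("daily_similarity", "speech_presence",
                             "weeknight_sleep_disturbance",
                             "death_related_words")])))
  expect_equal(sum(is.na(f2)), 4)

  # empty word bag with sufficient audio: only death words missing
  rec3 <- rec
  rec3$words <- character(0)
  f3 <- extract_features(rec3)
  expect_true(is.na(f3[["death_related_words"]]))
  expect_equal(sum(is.na(f3)), 1)

  # gps gone -> location features missing
  rec4 <- rec
  rec4$gps <- rec$gps[0, ]
  f4 <- extract_features(rec4)
  expect_true(all(is.na(f4[c("locations_visited", "exits_from_home")])))
  expect_equal(sum(is.na(f4)), 2)

  # no screen events -> screen use missing (screen exempt from sufficiency)
  rec5 <- rec
  rec5$screen <- rec$screen[0, ]
  f5 <- extract_features(rec5)
  expect_true(is.na(f5[["screen_use"]]))
  expect_equal(sum(is.na(f5)), 1)
})
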