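# Synthetic cohort generator. Latent per-subject severities (SAD, GAD,
# MDD; correlated, emulating comorbidity) drive both the self-report
# scale scores and the generative parameters of every sensor stream, so
# the whole pipeline can be validated against known ground truth.
#
# Two arms share the same latent machinery:
#   * generate_cohort()        - full raw sensor streams (subject_record)
#   * simulate_feature_cohort()- feature-level draws, for experiments that
#                                need hundreds of cohorts (calibration,
#                                power) where raw-stream synthesis would
#                                be wasteful.

#' Default severity-to-behavior effect map
#'
#' Signed effect sizes (per SD of latent severity, on each feature's
#' generative parameter scale) linking the three latent severities to the
#' eight features. The default sign pattern encodes the directions the
#' screening models are expected to recover: for both SAD and MDD the
#' regularity, mobility, and darkness features are protective while
#' death-related words and screen use are risk factors; speech presence
#' is strongly protective for MDD but mildly risk-increasing for SAD, and
#' weeknight sleep disturbance is a risk factor for MDD but protective
#' for SAD. GAD effects default to zero (behavioral features carry little
#' GAD signal). Magnitudes are free modeling parameters.
#'
#' @return 8 x 3 numeric matrix, features x disorders.
#' @export
default_effects <- function() {
  m <- matrix(0, nrow = length(.PHENO_FEATURES), ncol = 3,
              dimnames = list(.PHENO_FEATURES, names(.PHENO_DISORDERS)))
  m[, "SAD"] <- c(-0.5, 0.1, -0.3, 0.5, -0.5, -0.3, 0.3, -0.2)
  m[, "MDD"] <- c(-0.3, -0.6, 0.5, 0.5, -0.3, -0.6, 0.3, -0.2)
  m
}

#' Zero effect map (null cohorts)
#'
#' @return 8 x 3 zero matrix; with it, features are independent of the
#'   screening labels by construction.
#' @export
null_effects <- function() {
  matrix(0, nrow = length(.PHENO_FEATURES), ncol = 3,
         dimnames = list(.PHENO_FEATURES, names(.PHENO_DISORDERS)))
}

#' Generator configuration
#'
#' Defaults mirror the study conditions: 112 recruited subjects observed
#' for 14 days, screening prevalences near 38% (SAD), 26% (GAD), and 37%
#' (MDD), and roughly a quarter of subjects with enough data loss to be
#' excluded. Baseline behavioral levels sit at the observed cohort means
#' (speech 0.15, death words 0.16%, ~12 locations, ~15 exits, screen use
#' 0.23, darkness 0.63).
#'
#' @param n_subjects Cohort size.
#' @param window_days Observation window length, days.
#' @param seed Master seed; the cohort is a pure function of the config.
#' @param effects Severity-to-behavior effect map (features x disorders).
#' @param prevalence Target positive-screen fractions per disorder.
#' @param comorbidity Pairwise correlation of the latent severities.
#' @param dropout List: `p_lossy` = probability a subject is a lossy
#'   recorder, `good`/`lossy` = per-stream retention ranges for the two
#'   groups (lossy retention sits below the one-half sufficiency cut),
#'   `block` = if TRUE drop one contiguous block instead of i.i.d.
#'   thinning.
#' @param baselines Baseline generative levels, see Details in the
#'   package vignette.
#' @param scales Per-instrument `slope` (points per severity SD) and
#'   `noise` (residual SD, points).
#' @param words_mean Mean word-bag size.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 112L, window_days = 14L,
                             seed = 1L,
                             effects = default_effects(),
                             prevalence = c(SAD = 0.38, GAD = 0.26,
                                            MDD = 0.37),
                             comorbidity = 0.5,
                             dropout = list(p_lossy = 0.25,
                                            good = c(0.80, 0.98),
                                            lossy = c(0.20, 0.45),
                                            block = FALSE),
                             baselines = list(
                               speech = 0.15, death_rate = 0.0016,
                               sites = 12, exits = 15,
                               screen_on = 0.23, dark = 0.63,
                               sigma_night = 0.14, phase_jitter_min = 25,
                               amp_jitter = 0.15,
                               vol_base = 0.5, vol_amp = 0.3,
                               vol_noise = 0.10),
                             scales = list(
                               lsas = c(slope = 20, noise = 6),
                               gad7 = c(slope = 4, noise = 1.5),
                               phq8 = c(slope = 4.5, noise = 1.5)),
                             words_mean = 1500) {
  stopifnot(n_subjects >= 1, window_days >= 2,
            all(prevalence > 0 & prevalence < 1),
            comorbidity >= 0, comorbidity < 1,
            is.matrix(effects),
            nrow(effects) == length(.PHENO_FEATURES), ncol(effects) == 3,
            dropout$p_lossy >= 0, dropout$p_lossy <= 1)
  rownames(effects) <- .PHENO_FEATURES
  colnames(effects) <- names(.PHENO_DISORDERS)
  structure(list(n_subjects = as.integer(n_subjects),
                 window_days = as.integer(window_days),
                 seed = as.integer(seed), effects = effects,
                 prevalence = prevalence, comorbidity = comorbidity,
                 dropout = dropout, baselines = baselines, scales = scales,
                 words_mean = words_mean),
            class = "generator_config")
}

.draw_severities <- function(n, rho) {
  sigma <- matrix(rho, 3, 3)
  diag(sigma) <- 1
  z <- matrix(rnorm(n * 3), n, 3)
  sev <- z %*% chol(sigma)
  colnames(sev) <- names(.PHENO_DISORDERS)
  sev
}

# Scale scores as monotone maps of severity plus noise, clipped to the
# instrument range and rounded. The intercept is calibrated in closed
# form so that P(round(score) >= threshold) equals the target prevalence
# for a standard-normal severity: mean = (thr - 0.5) - z_{1-p} * sd_total.
.draw_scale_scores <- function(sev, config,
                               thresholds = default_config()$screening) {
  n <- nrow(sev)
  out <- data.frame(row.names = seq_len(n))
  for (d in names(.PHENO_DISORDERS)) {
    instr <- .PHENO_DISORDERS[[d]]
    sl <- config$scales[[instr]][["slope"]]
    no <- config$scales[[instr]][["noise"]]
    sd_tot <- sqrt(sl^2 + no^2)
    mu <- (thresholds[[instr]] - 0.5) - qnorm(1 - config$prevalence[[d]]) * sd_tot
    raw <- mu + sl * sev[, d] + rnorm(n, 0, no)
    rng <- .SCALE_RANGES[[instr]]
    out[[instr]] <- pmin(pmax(as.integer(round(raw)), rng[1]), rng[2])
  }
  out
}

# Per-subject generative parameters from the latent severities: for each
# feature, a target level t = sum_d effects[f, d] * severity_d plus
# subject-level noise, mapped through a link keeping the parameter in its
# natural range.
.subject_params <- function(sev_row, config) {
  b <- config$baselines
  t <- drop(config$effects %*% sev_row)  # named by feature
  list(
    phase_jitter_min = min(240, exp(log(b$phase_jitter_min) -
                                      1.2 * t[["daily_similarity"]] +
                                      rnorm(1, 0, 0.25))),
    p_speech = plogis(qlogis(b$speech) + t[["speech_presence"]] +
                        rnorm(1, 0, 0.25)),
    sigma_night = min(0.35, max(0.02,
      exp(log(b$sigma_night) + 0.5 * t[["weeknight_sleep_disturbance"]] +
            rnorm(1, 0, 0.25)))),
    death_rate = min(0.02, exp(log(b$death_rate) +
                                 t[["death_related_words"]] +
                                 rnorm(1, 0, 0.4))),
    n_sites = max(1L, min(40L, as.integer(round(
      b$sites * exp(0.35 * t[["locations_visited"]] + rnorm(1, 0, 0.25)))))),
    n_exits = max(0L, min(48L, as.integer(round(
      b$exits * exp(0.35 * t[["exits_from_home"]] + rnorm(1, 0, 0.25)))))),
    screen_on = min(0.9, max(0.02,
      plogis(qlogis(b$screen_on) + 0.6 * t[["screen_use"]] +
               rnorm(1, 0, 0.25)))),
    dark = min(0.95, max(0.25,
      plogis(qlogis(b$dark) + 0.6 * t[["time_in_darkness"]] +
               rnorm(1, 0, 0.25))))
  )
}

# Fillers deliberately include near-miss tokens (day, dine, deed, graveltruck
# is out of vocabulary) so prefix matching is actually exercised.
.FILLER_WORDS <- c(
  "the", "and", "you", "that", "have", "with", "this", "just", "like",
  "time", "good", "going", "really", "today", "tomorrow", "work", "home",
  "dinner", "coffee", "weather", "morning", "night", "day", "week",
  "phone", "watch", "music", "friend", "family", "maybe", "thanks",
  "okay", "right", "sure", "dine", "deed", "dear", "door", "great")

.DEATH_WORDS <- c("death", "died", "dying", "dead", "funeral", "grave",
                  "kill", "killed", "buried", "coffin", "mourning",
                  "suicide", "fatal")

#' Generate one subject's audio stream and word bag
#'
#' Volume is a diurnal sinusoid (peak mid-afternoon local time, trough at
#' night) with per-day phase and amplitude jitter plus observation noise;
#' the phase jitter drives the daily-similarity feature down as it grows.
#' Night samples get their own noise SD (`sigma_night`), which drives
#' weeknight sleep disturbance. Speech labels are Bernoulli with the
#' subject's speech rate; the word bag mixes death-lexicon tokens at the
#' subject's death-word rate into filler vocabulary and is shuffled.
#'
#' @param params Subject parameter list (see `generator_config()`
#'   baselines for the knobs).
#' @param window_start `POSIXct` window start (local midnight).
#' @param window_days Window length.
#' @param utc_offset_min Local-time offset, minutes.
#' @param config Generator configuration.
#' @return List `audio` (data frame), `words` (character).
#' @export
generate_audio_stream <- function(params, window_start, window_days,
                                  utc_offset_min, config) {
  b <- config$baselines
  n <- window_days * 24 * 12  # every 5 minutes
  ts <- window_start + 300 * (seq_len(n) - 1)
  loc <- as.numeric(ts) + utc_offset_min * 60
  day <- floor(loc / 86400)
  di <- day - min(day) + 1
  hour_min <- (loc %% 86400) / 60
  n_days <- max(di)
  phase <- rnorm(n_days, 0, params$phase_jitter_min)
  amp <- b$vol_amp * exp(rnorm(n_days, 0, b$amp_jitter))
  v <- b$vol_base +
    amp[di] * sin(2 * pi * (hour_min - 14 * 60 - phase[di]) / 1440)
  night <- hour_min < 6 * 60
  noise_sd <- ifelse(night, params$sigma_night, b$vol_noise)
  if (any(noise_sd > 0)) v <- v + rnorm(n, 0, noise_sd)
  v <- round(pmax(v, 0), 6)
  audio <- data.frame(timestamp = ts, volume = v,
                      has_speech = runif(n) < params$p_speech)
  nw <- rpois(1, config$words_mean)
  nd <- rbinom(1, nw, params$death_rate)
  words <- c(sample(.DEATH_WORDS, nd, replace = TRUE),
             sample(.FILLER_WORDS, nw - nd, replace = TRUE))
  list(audio = audio, words = sample(words))
}

#' Generate one subject's GPS trajectory
#'
#' The trajectory alternates dwell at a home site (always occupied between
#' local midnight and 6 AM) with excursions to `n_sites - 1` distinct
#' visit sites laid out 500 m apart (greater than 3 x the 150 m
#' clustering radius). Each excursion occupies a daytime slot: ~10 min
#' travel out (fixes move fast enough to be non-stationary), 45 min dwell
#' at the site, ~10 min travel back. Within-site jitter is ~10 m. Ground
#' truth: the pipeline should recover `n_sites` locations and `n_exits`
#' exits whenever no samples are dropped.
#'
#' @inheritParams generate_audio_stream
#' @return Data frame `timestamp`, `latitude`, `longitude`.
#' @export
generate_gps_stream <- function(params, window_start, window_days,
                                utc_offset_min, config) {
  n <- window_days * 24 * 12
  ts <- window_start + 300 * (seq_len(n) - 1)
  loc <- as.numeric(ts) + utc_offset_min * 60
  day0 <- min(floor(loc / 86400))

  home_lat <- runif(1, 43, 54)
  home_lon <- runif(1, -123, -63)
  # candidate excursion slots: local 9/12/15/18 h starts whose ~65-minute
  # excursion lies fully inside the observed window
  cand <- expand.grid(day = 0:window_days, hour = c(9, 12, 15, 18))
  slot_start <- (day0 + cand$day) * 86400 + cand$hour * 3600
  cand <- cand[slot_start >= min(loc) & slot_start + 3900 <= max(loc) + 300, ,
               drop = FALSE]
  n_slots <- nrow(cand)
  k <- min(params$n_sites, n_slots + 1L)
  e <- if (k <= 1) 0L else min(max(params$n_exits, k - 1L), n_slots)
  # visit sites on an east-west line, 500 m spacing
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(home_lat * pi / 180)
  site_lat <- rep(home_lat, max(k - 1, 0))
  site_lon <- home_lon + (seq_len(max(k - 1, 0)) * 500) / m_per_deg_lon

  lat <- rep(home_lat, n)
  lon <- rep(home_lon, n)
  if (e > 0) {
    pick <- cand[sample.int(n_slots, e), , drop = FALSE]
    site_of <- sample(rep(seq_len(k - 1), length.out = e))
    for (j in seq_len(e)) {
      s0 <- (day0 + pick$day[j]) * 86400 + pick$hour[j] * 3600
      travel_out <- loc >= s0 & loc < s0 + 600
      at_site <- loc >= s0 + 600 & loc < s0 + 3300
      travel_back <- loc >= s0 + 3300 & loc < s0 + 3900
      sj <- site_of[j]
      lat[at_site] <- site_lat[sj]
      lon[at_site] <- site_lon[sj]
      # travel fixes advance along the path so consecutive fixes stay
      # fast (non-stationary) and never pile up at one spot
      io <- which(travel_out)
      lon[io] <- home_lon + (c(1, 2) / 3)[seq_along(io)] *
        (site_lon[sj] - home_lon)
      ib <- which(travel_back)
      lon[ib] <- home_lon + (c(2, 1) / 3)[seq_along(ib)] *
        (site_lon[sj] - home_lon)
      lat[c(io, ib)] <- home_lat
    }
  }
  jit <- 10  # meters
  lat <- lat + rnorm(n, 0, jit / m_per_deg_lat)
  lon <- lon + rnorm(n, 0, jit / m_per_deg_lon)
  out <- data.frame(timestamp = ts, latitude = round(lat, 7),
                    longitude = round(lon, 7))
  attr(out, "truth") <- list(n_sites = k, n_exits = e,
                             home = c(home_lat, home_lon))
  out
}

#' Generate one subject's screen events and light samples
#'
#' Screen state is an alternating renewal process with exponential on/off
#' durations whose means give the target on-fraction (13-minute mean
#' cycle). Light samples arrive every 10 minutes; each is dark (< 5 lux)
#' with a probability of 0.95 during local night (00:00-07:00) and a
#' daytime probability solved so that the overall expected dark fraction
#' equals the subject's target.
#'
#' @inheritParams generate_audio_stream
#' @return List `screen`, `light` (data frames) and `dark_target`
#'   (realized expected dark fraction).
#' @export
generate_screen_and_light <- function(params, window_start, window_days,
                                      utc_offset_min, config) {
  total_s <- window_days * 86400
  cycle <- 13 * 60
  mu_on <- max(30, params$screen_on * cycle)
  mu_off <- max(30, (1 - params$screen_on) * cycle)
  n_draw <- ceiling(total_s / (mu_on + mu_off) * 2) + 20
  durs <- numeric(2 * n_draw)
  durs[seq(1, 2 * n_draw, by = 2)] <- pmax(1, round(rexp(n_draw, 1 / mu_off)))
  durs[seq(2, 2 * n_draw, by = 2)] <- pmax(1, round(rexp(n_draw, 1 / mu_on)))
  at <- cumsum(durs)
  keep <- at < total_s
  states <- rep(c("on", "off"), n_draw)[keep]  # starts off, first event "on"
  screen <- data.frame(timestamp = window_start + at[keep], state = states,
                       stringsAsFactors = FALSE)

  n_l <- window_days * 24 * 6  # every 10 minutes
  ts <- window_start + 600 * (seq_len(n_l) - 1)
  hour <- ((as.numeric(ts) + utc_offset_min * 60) %% 86400) / 3600
  is_night <- hour < 7
  p_night <- 0.95
  p_day <- (params$dark * n_l - p_night * sum(is_night)) /
    max(1, n_l - sum(is_night))
  p_day <- min(1, max(0, p_day))
  p <- ifelse(is_night, p_night, p_day)
  dark <- runif(n_l) < p
  lux <- ifelse(dark, runif(n_l, 0.01, 4.9),
                5.5 + rlnorm(n_l, log(120), 1))
  light <- data.frame(timestamp = ts, lux = round(lux, 3))
  list(screen = screen, light = light, dark_target = mean(p))
}

.thin_stream <- function(df, retention, block = FALSE) {
  n <- nrow(df)
  if (n == 0 || retention >= 1) return(df)
  if (block) {
    drop_n <- round((1 - retention) * n)
    if (drop_n == 0) return(df)
    start <- sample.int(n - drop_n + 1, 1)
    keep <- setdiff(seq_len(n), seq(start, start + drop_n - 1))
  } else {
    keep <- which(runif(n) < retention)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws correlated latent severities, maps them to scale scores
#' (calibrated to the target screening prevalences) and to per-subject
#' behavioral parameters via the effect map, synthesizes all five sensor
#' streams, and applies per-stream dropout (a `p_lossy` fraction of
#' subjects retain well under half their samples and are expected to be
#' excluded downstream). Deterministic given the config, including its
#' seed; each subject is generated from an independently derived seed.
#'
#' @param config A [generator_config()].
#' @return List: `cohort` (list of [subject_record()]s) and `truth`
#'   (data frame of per-subject latent severities, generative parameters,
#'   ground-truth location counts, and retention rates).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  sev <- .draw_severities(n, config$comorbidity)
  scores <- .draw_scale_scores(sev, config)
  subject_seeds <- sample.int(2^31 - 2, n)
  offsets <- sample(c(-480, -420, -360, -300, -240, -210), n, replace = TRUE,
                    prob = c(0.14, 0.10, 0.12, 0.50, 0.10, 0.04))
  base_local <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

  cohort <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    id <- sprintf("S%03d", i)
    w0 <- base_local - offsets[i] * 60  # local midnight in UTC
    w1 <- w0 + config$window_days * 86400
    params <- .subject_params(sev[i, ], config)

    aud <- generate_audio_stream(params, w0, config$window_days,
                                 offsets[i], config)
    gps <- generate_gps_stream(params, w0, config$window_days,
                               offsets[i], config)
    gps_truth <- attr(gps, "truth")
    sl <- generate_screen_and_light(params, w0, config$window_days,
                                    offsets[i], config)

    lossy <- runif(1) < config$dropout$p_lossy
    rng <- if (lossy) config$dropout$lossy else config$dropout$good
    ret <- runif(3, rng[1], rng[2])  # audio, gps, light
    blk <- isTRUE(config$dropout$block)
    audio_thin <- .thin_stream(aud$audio, ret[1], blk)
    gps_thin <- .thin_stream(gps, ret[2], blk)
    light_thin <- .thin_stream(sl$light, ret[3], blk)

    cohort[[i]] <- subject_record(
      subject_id = id, window_start = w0, window_end = w1,
      utc_offset_min = offsets[i],
      audio = audio_thin, gps = gps_thin, screen = sl$screen,
      light = light_thin, words = aud$words,
      scores = scale_scores(scores$lsas[i], scores$gad7[i], scores$phq8[i]))

    truth[[i]] <- data.frame(
      subject_id = id,
      severity_sad = sev[i, "SAD"], severity_gad = sev[i, "GAD"],
      severity_mdd = sev[i, "MDD"],
      p_speech = params$p_speech, death_rate = params$death_rate,
      sigma_night = params$sigma_night,
      phase_jitter_min = params$phase_jitter_min,
      n_sites = gps_truth$n_sites, n_exits = gps_truth$n_exits,
      screen_on = params$screen_on, dark_target = sl$dark_target,
      lossy = lossy, ret_audio = ret[1], ret_gps = ret[2],
      ret_light = ret[3], stringsAsFactors = FALSE)
  }
  list(cohort = cohort, truth = do.call(rbind, truth))
}

#' Feature-level synthetic cohorts
#'
#' The fast arm of the generator: draws the same latent severities and
#' calibrated scale scores as [generate_cohort()], but emits each
#' subject's feature vector directly as
#' `x_f = sum_d effects[f, d] * severity_d + N(0, 1)` instead of
#' synthesizing raw streams and extracting. With `effects = NULL`
#' (zeros), features are independent of the screening labels by
#' construction - the null case for type-I-error calibration. Intended
#' for experiments needing many cohorts (calibration curves, power over
#' seeds).
#'
#' @param n Number of subjects (default 84, the analyzed sample size).
#' @param effects Effect map (features x disorders); `NULL` for the null.
#' @param seed Integer seed.
#' @param prevalence,comorbidity,scales As in [generator_config()].
#' @return List: `features` (data frame, `subject_id` + 8 columns),
#'   `labels` (logical `SAD`/`GAD`/`MDD` + scale scores), `severities`.
#' @export
simulate_feature_cohort <- function(n = 84L, effects = NULL, seed = NULL,
                                    prevalence = c(SAD = 0.38, GAD = 0.26,
                                                   MDD = 0.37),
                                    comorbidity = 0.5,
                                    scales = generator_config()$scales) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effects)) effects <- null_effects()
  cfg <- list(prevalence = prevalence, scales = scales)
  sev <- .draw_severities(n, comorbidity)
  scores <- .draw_scale_scores(sev, cfg)
  thr <- default_config()$screening
  labels <- data.frame(
    SAD = scores$lsas >= thr$lsas,
    GAD = scores$gad7 >= thr$gad7,
    MDD = scores$phq8 >= thr$phq8)
  X <- sev %*% t(effects) + matrix(rnorm(n * length(.PHENO_FEATURES)), n)
  features <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), X,
                         stringsAsFactors = FALSE)
  names(features) <- c("subject_id", .PHENO_FEATURES)
  list(features = features, labels = cbind(labels, scores),
       severities = sev)
}
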