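# Independent reference implementations (oracles) and small fixture
# builders. Each oracle is deliberately written with a different method
# than the package code it checks.

# Spherical law of cosines distance (meters) - independent of haversine.
oracle_dist_m <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  la1 <- lat1 * pi / 180; la2 <- lat2 * pi / 180
  dlo <- (lon2 - lon1) * pi / 180
  c <- sin(la1) * sin(la2) + cos(la1) * cos(la2) * cos(dlo)
  R * acos(pmin(pmax(c, -1), 1))
}

# Degrees of latitude/longitude giving a displacement of `m` meters.
deg_for_m_lat <- function(m, R = 6371000) m / (pi * R / 180)
deg_for_m_lon <- function(m, lat, R = 6371000) {
  m / (pi * R / 180 * cos(lat * pi / 180))
}

# Two-pass Pearson correlation of a series with its lag-shifted self,
# complete pairs only.
oracle_pearson_lag <- function(v, lag) {
  n <- length(v)
  x <- v[1:(n - lag)]
  y <- v[(lag + 1):n]
  ok <- which(!is.na(x) & !is.na(y))
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive pair-counting AUROC.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force DBSCAN by transitive closure over the eps-graph of core
# points; same label semantics as the package (ids by earliest core
# timestamp, border joins the lowest reachable id).
oracle_dbscan <- function(points, eps_m, min_pts) {
  n <- nrow(points)
  D <- outer(seq_len(n), seq_len(n), function(i, j) {
    oracle_dist_m(points$latitude[i], points$longitude[i],
                  points$latitude[j], points$longitude[j])
  })
  A <- D <= eps_m
  core <- rowSums(A) >= min_pts
  # transitive closure over core-core adjacency
  reach <- A & outer(core, core, `&`)
  diag(reach) <- core
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- rep(NA_integer_, n)
  cid <- 0L
  for (i in order(as.numeric(points$timestamp))) {
    if (!core[i] || !is.na(labels[i])) next
    cid <- cid + 1L
    labels[which(reach[i, ])] <- cid
  }
  for (i in which(!core)) {
    cl <- labels[which(A[i, ] & core)]
    if (length(cl)) labels[i] <- min(cl)
  }
  labels
}

# Direct interval accumulation of screen on-time.
oracle_screen_on <- function(events, window_start, window_end) {
  t0 <- as.numeric(window_start); t1 <- as.numeric(window_end)
  state <- if (events$state[1] == "on") "off" else "on"
  cur <- t0
  on_time <- 0
  for (i in seq_len(nrow(events))) {
    ti <- as.numeric(events$timestamp[i])
    if (state == "on") on_time <- on_time + (ti - cur)
    if (events$state[i] != state) state <- events$state[i]
    cur <- ti
  }
  if (state == "on") on_time <- on_time + (t1 - cur)
  on_time / (t1 - t0)
}

# Plain Newton/IRLS logistic fit (unpenalized), independent of glm.
oracle_irls_logistic <- function(x, y, maxit = 50) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    W <- diag(as.numeric(mu * (1 - mu)))
    beta <- beta + solve(t(X) %*% W %*% X, t(X) %*% (y - mu))
  }
  as.numeric(beta)
}

# Small hand-built subject record; streams are regular grids so expected
# counts are easy to reason about.
make_test_record <- function(id = "T01", days = 14, utc_offset_min = 0,
                             n_audio = NULL, n_gps = NULL, n_light = NULL,
                             window_start = as.POSIXct("2021-03-01 00:00:00",
                                                       tz = "UTC")) {
  w0 <- window_start
  w1 <- w0 + days * 86400
  na <- if (is.null(n_audio)) days * 288 else n_audio
  ng <- if (is.null(n_gps)) days * 288 else n_gps
  nl <- if (is.null(n_light)) days * 144 else n_light
  audio <- data.frame(timestamp = w0 + 300 * (seq_len(na) - 1),
                      volume = 0.5 + 0.1 * sin(seq_len(na)),
                      has_speech = seq_len(na) %% 7 == 0)
  gps <- data.frame(timestamp = w0 + 300 * (seq_len(ng) - 1),
                    latitude = 45, longitude = -75)
  screen <- data.frame(timestamp = c(w0 + 3600, w0 + 5400),
                       state = c("on", "off"), stringsAsFactors = FALSE)
  light <- data.frame(timestamp = w0 + 600 * (seq_len(nl) - 1),
                      lux = rep(c(1, 50), length.out = nl))
  subject_record(id, w0, w1, utc_offset_min, audio, gps, screen, light,
                 words = c("hello", "world"),
                 scores = scale_scores(30, 5, 5))
}

# No-dropout generator config for ground-truth recovery checks.
no_dropout_config <- function(...) {
  generator_config(..., dropout = list(p_lossy = 0, good = c(1, 1),
                                       lossy = c(0.2, 0.45), block = FALSE))
}
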