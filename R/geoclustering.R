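# GPS trajectory processing: stationary-point detection, density-based
# clustering (DBSCAN with haversine distances), home-cluster inference,
# and the two location feature counts.

.EARTH_RADIUS_M <- 6371000

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m. At the 150 m
#' scale of the location clustering, ellipsoidal corrections are
#' irrelevant. Vectorized over coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distances in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_M)
}

# Points on the sphere as 3-D Cartesian coordinates (meters). A haversine
# distance threshold eps is equivalent to a chord-length threshold
# 2 R sin(eps / 2R), which makes DBSCAN region queries cheap vector ops.
.geo_to_xyz <- function(lat, lon) {
  la <- lat * pi / 180
  lo <- lon * pi / 180
  .EARTH_RADIUS_M * cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

.chord2_for_eps <- function(eps_m) {
  (2 * .EARTH_RADIUS_M * sin(pmin(eps_m / (2 * .EARTH_RADIUS_M), pi / 2)))^2
}

#' Stationary points of a GPS trajectory
#'
#' A fix is stationary when the direct-line speed from the previous fix is
#' below `speed_kmh` (default 1 km/h); the first fix, having no
#' predecessor, is stationary by convention. Each stationary point carries
#' a dwell time: the gap to the next recorded fix (to the window end for
#' the last fix, when given), capped at `dwell_cap_min` so data gaps do
#' not inflate dwell.
#'
#' Fixes that duplicate the previous timestamp are dropped with a warning
#' (speed would be undefined).
#'
#' @param gps Data frame `timestamp`, `latitude`, `longitude`, sorted.
#' @param window_end Optional `POSIXct` window end for the last dwell.
#' @param speed_kmh Stationary speed threshold, km/h.
#' @param dwell_cap_min Dwell cap, minutes.
#' @return Data frame `timestamp`, `latitude`, `longitude`, `dwell`
#'   (seconds), a subset of the input fixes.
#' @export
stationary_points <- function(gps, window_end = NULL, speed_kmh = 1.0,
                              dwell_cap_min = 30) {
  stopifnot(nrow(gps) >= 1)
  ts <- as.numeric(gps$timestamp)
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sprintf("dropping %d GPS fix(es) with duplicated timestamps",
                    sum(dup)), call. = FALSE)
    gps <- gps[!dup, , drop = FALSE]
    ts <- ts[!dup]
  }
  n <- nrow(gps)
  if (n == 1) {
    stationary <- TRUE
  } else {
    dt_h <- diff(ts) / 3600
    d_km <- haversine_m(gps$latitude[-n], gps$longitude[-n],
                        gps$latitude[-1], gps$longitude[-1]) / 1000
    stationary <- c(TRUE, d_km / dt_h < speed_kmh)
  }
  tail_gap <- if (is.null(window_end)) 0 else {
    max(0, as.numeric(window_end) - ts[n])
  }
  dwell <- pmin(c(diff(ts), tail_gap), dwell_cap_min * 60)
  out <- data.frame(timestamp = gps$timestamp, latitude = gps$latitude,
                    longitude = gps$longitude, dwell = dwell)[stationary, ,
                                                              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DBSCAN over geographic points
#'
#' Standard DBSCAN semantics with haversine distances: a core point has at
#' least `min_pts` neighbors (itself included) within `eps_m`; clusters
#' are the density-connected components of core points; a non-core point
#' within `eps_m` of one or more core points is a border point and joins
#' the reachable cluster with the lowest id; remaining points are noise.
#' Cluster ids are assigned in order of each cluster's earliest core-point
#' timestamp, which makes the labeling invariant to input permutation.
#'
#' @param points Data frame with `latitude`, `longitude`, `timestamp`.
#' @param eps_m Neighborhood radius, meters (default 150).
#' @param min_pts Core-point threshold (default 5).
#' @return Integer vector of cluster ids (1-based) aligned with the input
#'   rows; `NA` marks noise.
#' @export
dbscan_geo <- function(points, eps_m = 150, min_pts = 5L) {
  stopifnot(eps_m > 0, min_pts >= 1)
  n <- nrow(points)
  if (n == 0) return(integer(0))

  ord <- order(as.numeric(points$timestamp))
  X <- .geo_to_xyz(points$latitude[ord], points$longitude[ord])
  thr2 <- .chord2_for_eps(eps_m)
  nbr <- function(i) {
    which((X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2 +
            (X[, 3] - X[i, 3])^2 <= thr2)
  }

  core <- logical(n)
  for (i in seq_len(n)) core[i] <- length(nbr(i)) >= min_pts

  labels <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    cid <- cid + 1L
    labels[i] <- cid
    queue <- i
    qhead <- 1L
    while (qhead <= length(queue)) {
      j <- queue[qhead]
      qhead <- qhead + 1L
      nb <- nbr(j)
      grow <- nb[core[nb] & is.na(labels[nb])]
      if (length(grow)) {
        labels[grow] <- cid
        queue <- c(queue, grow)
      }
    }
  }
  for (i in which(!core)) {
    nb <- nbr(i)
    cl <- labels[nb[core[nb]]]
    if (length(cl)) labels[i] <- min(cl)
  }

  out <- rep(NA_integer_, n)
  out[ord] <- labels
  out
}

# Seconds of overlap between intervals [s, e] (numeric local-time seconds
# since epoch) and the nightly window [night_start, night_end) hours.
.night_overlap <- function(s, e, night_start_h = 0, night_end_h = 6) {
  ov <- numeric(length(s))
  d0 <- floor(s / 86400)
  d1 <- floor(e / 86400)
  for (k in 0:max(d1 - d0)) {
    day <- d0 + k
    active <- day <= d1
    ns <- day * 86400 + night_start_h * 3600
    ne <- day * 86400 + night_end_h * 3600
    ov <- ov + ifelse(active, pmax(0, pmin(e, ne) - pmax(s, ns)), 0)
  }
  ov
}

#' Infer the home cluster
#'
#' Home is the cluster in which the subject accumulates the most dwell
#' time between local midnight and 6 AM across all nights of the window.
#' Ties go to the cluster with the larger total dwell over the whole
#' window, then to the lowest cluster id.
#'
#' @param points Stationary points ([stationary_points()] output).
#' @param labels Cluster labels from [dbscan_geo()], aligned with `points`.
#' @param utc_offset_min Local-time offset, minutes.
#' @param night_start_h,night_end_h Local night window, hours.
#' @return Home cluster id, or `NA` when no clustered point overlaps the
#'   night window (home undefined).
#' @export
infer_home <- function(points, labels, utc_offset_min,
                       night_start_h = 0, night_end_h = 6) {
  ok <- !is.na(labels)
  if (!any(ok)) return(NA_integer_)
  s <- as.numeric(points$timestamp[ok]) + utc_offset_min * 60
  e <- s + points$dwell[ok]
  night <- .night_overlap(s, e, night_start_h, night_end_h)
  lab <- labels[ok]
  night_by <- tapply(night, lab, sum)
  if (all(night_by == 0)) return(NA_integer_)
  total_by <- tapply(points$dwell[ok], lab, sum)
  ids <- as.integer(names(night_by))
  o <- order(-night_by, -total_by, ids)
  ids[o[1]]
}

#' Number of distinct locations visited
#'
#' @param labels Cluster labels (`NA` = noise).
#' @return Count of distinct non-noise clusters.
#' @export
count_locations <- function(labels) {
  length(unique(labels[!is.na(labels)]))
}

#' Number of exits from the home cluster
#'
#' With stationary points in time order and noise points removed (noise is
#' unassigned, not evidence of a distinct location), counts transitions
#' from the home cluster to any non-home cluster.
#'
#' @param labels Cluster labels in time order (`NA` = noise).
#' @param home Home cluster id.
#' @return Integer exit count; `NA` if `home` is undefined.
#' @export
count_exits <- function(labels, home) {
  if (is.na(home)) return(NA_integer_)
  lab <- labels[!is.na(labels)]
  if (length(lab) < 2) return(0L)
  sum(lab[-length(lab)] == home & lab[-1] != home)
}
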