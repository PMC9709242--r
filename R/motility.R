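# Uterine-zone sperm localization and track-velocity statistics.
#
# The uterus axis is the straight vulva -> spermatheca segment, divided
# into thirds: zone 1 is the vulval third, zone 2 the central third, zone 3
# the spermathecal third. Zone boundaries are half-open, [0, 1/3), [1/3,
# 2/3), [2/3, 1], so an axis fraction of exactly 1/3 falls in zone 2.

#' Construct a uterus scene
#'
#' @param vulva_point,spermatheca_point numeric (row, col) landmarks; must
#'   differ.
#' @param sperm_points two-column matrix of sperm (row, col) positions.
#' @return a `UterusScene` list.
#' @export
uterus_scene <- function(vulva_point, spermatheca_point, sperm_points) {
  if (all(vulva_point == spermatheca_point))
    stop("vulva and spermatheca must be distinct points")
  sperm_points <- matrix(as.numeric(sperm_points), ncol = 2)
  structure(list(vulva = as.numeric(vulva_point),
                 spermatheca = as.numeric(spermatheca_point),
                 sperm = sperm_points),
            class = "UterusScene")
}

#' Assign sperm to uterine zones
#'
#' Each sperm is orthogonally projected onto the vulva->spermatheca axis;
#' its axis fraction in [0, 1] determines the zone. Fractions projecting
#' outside [0, 1] are clamped with a warning.
#'
#' @param scene a [uterus_scene()].
#' @return list with `fraction` (per sperm), `zone` (1, 2 or 3),
#'   `zone_fractions` (proportion of sperm per zone, summing to 1) and
#'   `clamped` (logical per sperm).
#' @export
assign_zones <- function(scene) {
  stopifnot(inherits(scene, "UterusScene"))
  a <- scene$spermatheca - scene$vulva
  d <- cbind(scene$sperm[, 1] - scene$vulva[1],
             scene$sperm[, 2] - scene$vulva[2])
  f <- (d[, 1] * a[1] + d[, 2] * a[2]) / sum(a^2)
  clamped <- f < 0 | f > 1
  if (any(clamped))
    warning(sum(clamped), " sperm project outside the uterus axis; clamped")
  f <- pmin(pmax(f, 0), 1)
  zone <- ifelse(f < 1 / 3, 1L, ifelse(f < 2 / 3, 2L, 3L))
  zf <- tabulate(zone, nbins = 3) / length(zone)
  list(fraction = f, zone = zone,
       zone_fractions = setNames(zf, paste0("zone", 1:3)), clamped = clamped)
}

#' Construct a track
#'
#' @param track_id identifier.
#' @param t_seconds strictly increasing time stamps (s).
#' @param row,col positions at each time stamp.
#' @param arm optional gonad-arm identifier.
#' @param zone optional uterine zone of the track.
#' @return a `Track` list.
#' @export
track <- function(track_id, t_seconds, row, col, arm = NA, zone = NA) {
  if (length(t_seconds) != length(row) || length(row) != length(col))
    stop("t, row, col must have equal length")
  if (any(duplicated(t_seconds))) stop("duplicate timestamps in track")
  if (is.unsorted(t_seconds, strictly = TRUE)) stop("timestamps must increase")
  structure(list(track_id = track_id, t = as.numeric(t_seconds),
                 row = as.numeric(row), col = as.numeric(col),
                 arm = arm, zone = zone),
            class = "Track")
}

#' Path-length speed of a track
#'
#' Speed is the total path length (sum of segment lengths) divided by the
#' elapsed time, the tracking-literature convention; net displacement over
#' time ("progressivity") is returned alongside as a secondary metric.
#'
#' @param trk a [track()] with at least two samples.
#' @return list with `speed` and `progressive_speed` (same units as the
#'   coordinates per second).
#' @export
track_speed <- function(trk) {
  stopifnot(inherits(trk, "Track"))
  m <- length(trk$t)
  if (m < 2) stop("a speed needs at least 2 samples")
  seg <- sqrt(diff(trk$row)^2 + diff(trk$col)^2)
  dt <- trk$t[m] - trk$t[1]
  net <- sqrt((trk$row[m] - trk$row[1])^2 + (trk$col[m] - trk$col[1])^2)
  list(speed = sum(seg) / dt, progressive_speed = net / dt)
}

#' Read tracks from a CSV table
#'
#' Expects columns `track`, `frame`, `x`, `y` (x = col, y = row; the
#' common tracking-export layout) or `track`, `t`, `row`, `col`. When only
#' frames are given, `t = (frame - min(frame)) * interval`.
#'
#' @param path CSV path.
#' @param interval frame interval in seconds (default 30).
#' @param arm optional arm id recorded on every track.
#' @param zone optional zone recorded on every track.
#' @return list of [track()] objects.
#' @export
read_tracks <- function(path, interval = 30, arm = NA, zone = NA) {
  df <- read.csv(path)
  if (!"t" %in% names(df)) {
    if (!"frame" %in% names(df)) stop("need a frame or t column")
    df$t <- (df$frame - min(df$frame)) * interval
  }
  if (!"row" %in% names(df)) { df$row <- df$y; df$col <- df$x }
  lapply(split(df, df$track), function(d) {
    d <- d[order(d$t), ]
    track(d$track[1], d$t, d$row, d$col, arm = arm, zone = zone)
  })
}

#' Mean sperm velocity per gonad arm
#'
#' Averages per-track path speeds over the tracks in the selected zone
#' (zone 2, the central uterus, by convention) for each arm. Arms with no
#' qualifying track are reported as `NA`, never as zero.
#'
#' @param tracks list of [track()] objects carrying `arm` and `zone`.
#' @param zone_filter the uterine zone whose tracks enter the average.
#' @return data.frame with `arm`, `mean_speed`, `n_tracks`.
#' @export
gonad_arm_velocity <- function(tracks, zone_filter = 2L) {
  arms <- vapply(tracks, function(t) as.character(t$arm), character(1))
  zones <- vapply(tracks, function(t) as.numeric(t$zone), numeric(1))
  speeds <- vapply(tracks, function(t) track_speed(t)$speed, numeric(1))
  out <- lapply(unique(arms), function(a) {
    sel <- arms == a & !is.na(zones) & zones == zone_filter
    data.frame(arm = a,
               mean_speed = if (any(sel)) mean(speeds[sel]) else NA_real_,
               n_tracks = sum(sel))
  })
  do.call(rbind, out)
}
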