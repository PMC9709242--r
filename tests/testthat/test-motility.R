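make_scene <- function(fracs, v = c(0, 0), s = c(0, 90), perp = 0) {
  axis <- s - v
  pu <- c(-axis[2], axis[1]) / sqrt(sum(axis^2))
  pts <- cbind(v[1] + fracs * axis[1] + perp * pu[1],
               v[2] + fracs * axis[2] + perp * pu[2])
  uterus_scene(v, s, pts)
}

test_that("zone assignment divides the uterus axis into thirds", {
  z <- assign_zones(make_scene(c(0.1, 0.5, 0.9)))
  expect_equal(z$zone, c(1L, 2L, 3L))
  # half-open boundaries: exactly 1/3 falls in zone 2, exactly 2/3 in zone 3
  zb <- assign_zones(make_scene(c(1 / 3, 2 / 3)))
  expect_equal(zb$zone, c(2L, 3L))
  expect_equal(sum(z$zone_fractions), 1)
  expect_error(uterus_scene(c(1, 1), c(1, 1), cbind(1, 1)), "distinct")
})

test_that("sperm projecting outside the axis are clamped with a warning", {
  expect_warning(z <- assign_zones(make_scene(c(-0.2, 0.5, 1.4))), "clamped")
  expect_equal(z$zone, c(1L, 2L, 3L))
  expect_equal(z$fraction[c(1, 3)], c(0, 1))
})

test_that("zone assignment is invariant to rigid motions of the scene", {
  set.seed(5)
  fracs <- runif(25); perp <- rnorm(25, 0, 4)
  base <- assign_zones(make_scene(fracs, perp = perp))
  for (ang in c(0.4, 1.9)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    tr <- c(13, -7)
    sc <- make_scene(fracs, perp = perp)
    rot <- uterus_scene(as.vector(R %*% sc$vulva) + tr,
                        as.vector(R %*% sc$spermatheca) + tr,
                        t(R %*% t(sc$sperm)) + rep(tr, each = 25))
    expect_equal(assign_zones(rot)$zone, base$zone)
  }
})

test_that("track speed is path length over elapsed time", {
  t1 <- track(1, c(0, 30), row = c(0, 3), col = c(0, 4))
  expect_equal(track_speed(t1)$speed, 5 / 30)
  still <- track(2, c(0, 30, 60), row = c(5, 5, 5), col = c(2, 2, 2))
  expect_equal(track_speed(still)$speed, 0)
  # zig-zag: segment-sum oracle
  zz <- track(3, c(0, 10, 20, 30), row = c(0, 3, 0, 3), col = c(0, 4, 8, 12))
  seg <- sqrt(c(9 + 16, 9 + 16, 9 + 16))
  expect_equal(track_speed(zz)$speed, sum(seg) / 30)
  expect_equal(track_speed(zz)$progressive_speed, sqrt(9 + 144) / 30)
  expect_error(track(4, c(0, 0, 30), 1:3, 1:3), "duplicate")
  expect_error(track_speed(track(5, 0, 1, 1)), "2 samples")
})

test_that("speed is origin-shift invariant and scale equivariant", {
  t0 <- track(1, c(0, 30, 60), row = c(0, 4, 2), col = c(0, 1, 7))
  shifted <- track(1, c(100, 130, 160), row = c(0, 4, 2), col = c(0, 1, 7))
  expect_equal(track_speed(shifted)$speed, track_speed(t0)$speed)
  scaled <- track(1, c(0, 30, 60), row = 3 * c(0, 4, 2), col = 3 * c(0, 1, 7))
  expect_equal(track_speed(scaled)$speed, 3 * track_speed(t0)$speed)
})

test_that("per-arm velocity averages zone-2 tracks and reports missing arms", {
  trks <- list(
    track(1, c(0, 30), c(0, 3), c(0, 0), arm = "L", zone = 2),  # 0.1 px/s
    track(2, c(0, 30), c(0, 9), c(0, 0), arm = "L", zone = 2),  # 0.3 px/s
    track(3, c(0, 30), c(0, 9), c(0, 0), arm = "R", zone = 1))
  out <- gonad_arm_velocity(trks, zone_filter = 2)
  expect_equal(out$mean_speed[out$arm == "L"], 0.2)
  expect_true(is.na(out$mean_speed[out$arm == "R"]))
  expect_equal(out$n_tracks[out$arm == "R"], 0L)
})

test_that("track CSVs round-trip through the common export layout", {
  df <- data.frame(track = rep(1:2, each = 3), frame = rep(1:3, 2),
                   x = c(0, 4, 8, 1, 1, 1), y = c(0, 3, 6, 2, 2, 2))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  trks <- read_tracks(f, interval = 30, arm = "L", zone = 2)
  expect_length(trks, 2L)
  expect_equal(track_speed(trks[[1]])$speed, 5 / 30)
  expect_equal(track_speed(trks[[2]])$speed, 0)
})

test_that("synthetic scenes reproduce the localisation and velocity truths", {
  wt <- synth_uterus_timelapse(preset_config("uterus", 8))
  zf_wt <- assign_zones(wt$scene)$zone_fractions
  expect_gt(zf_wt["zone3"], zf_wt["zone1"])   # wild-type: spermathecal side
  mut <- synth_uterus_timelapse(preset_config("uterus-mut", 8))
  zf_mut <- assign_zones(mut$scene)$zone_fractions
  expect_gt(zf_mut["zone1"], zf_mut["zone3"]) # mutant: stuck near the vulva

  # configured mean speed recovered within 2 SEM from the track table
  trks <- lapply(split(wt$tracks, wt$tracks$track), function(d)
    track(d$track[1], d$t, d$row, d$col, arm = "a", zone = 2))
  speeds <- vapply(trks, function(t) track_speed(t)$speed, numeric(1))
  arm <- gonad_arm_velocity(trks, zone_filter = 2)
  sem <- sd(speeds) / sqrt(length(speeds))
  expect_lt(abs(arm$mean_speed - 0.15), 2 * sem + 1e-9)

  # per-track path speed equals the configured speed exactly by design
  expect_equal(unname(speeds), wt$truth$speed_px_s, tolerance = 1e-9)

  frozen <- synth_uterus_timelapse(preset_config("uterus", 9,
    speed = c(mean = 0, sd = 0)))
  expect_true(all(tapply(frozen$tracks$row, frozen$tracks$track,
                         function(v) diff(range(v))) == 0))
  expect_error(synth_uterus_timelapse(preset_config("uterus", 9,
    frame_interval_s = 0)), "interval")
})
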