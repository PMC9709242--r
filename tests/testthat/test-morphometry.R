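test_that("metric limits hold on a rasterized disc", {
  labs <- label_map(draw_disk(60, 60, 30, 30, 20))
  m <- measure_cell(labs, 1L)
  expect_gte(m$circularity, 0.95)
  expect_lte(m$circularity, 1.0)
  expect_gte(m$solidity, 0.98)
  expect_lte(m$aspect_ratio, 1.05)
  expect_gte(m$feret_px, sqrt(4 * m$area_px / pi) - 1)
})

test_that("rectangle metrics match their analytic values", {
  m <- measure_cell(label_map(draw_rect(50, 60, 10, 39, 10, 49)), 1L)
  expect_equal(m$feret_px, 50, tolerance = 1.5 / 50)  # 30x40 diagonal
  m2 <- measure_cell(label_map(draw_rect(50, 50, 6, 45, 20, 29)), 1L)
  expect_equal(m2$aspect_ratio, 4.0, tolerance = 0.05)  # 40x10 moments
  expect_equal(m2$solidity, 1.0, tolerance = 0.02)
})

test_that("convex rasterized shapes have solidity 1 within 2%", {
  for (seed in 1:5) {
    poly <- draw_convex(60, 60, n_sides = 5 + seed, radius = 22, seed = seed)
    m <- measure_cell(label_map(poly), 1L)
    expect_equal(m$solidity, 1.0, tolerance = 0.02)
  }
})

test_that("rotating-calipers Feret equals the all-pairs brute force", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- draw_disk(50, 50, 25, 25, 6 + 2 * (seed %% 3))
    extra <- cbind(sample(10:40, 15), sample(10:40, 15))
    m[extra] <- 1L
    m <- fill_holes(binary_closing(m, 1))
    idx <- which(m, arr.ind = TRUE)
    labs <- label_components(m)
    main <- which.max(tabulate(labs[labs > 0]))
    idx <- which(unclass(labs) == main, arr.ind = TRUE)
    corners <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
                     cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
                     cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
                     cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
    expect_equal(feret_diameter(corners), brute_feret(corners),
                 tolerance = 1e-9)
  }
})

test_that("metrics are scale-stable: doubling size doubles Feret only", {
  small <- measure_cell(label_map(draw_disk(50, 50, 25, 25, 11)), 1L)
  big <- measure_cell(label_map(draw_disk(100, 100, 50, 50, 22)), 1L)
  expect_equal(big$circularity / small$circularity, 1, tolerance = 0.02)
  expect_equal(big$solidity / small$solidity, 1, tolerance = 0.02)
  expect_equal(big$aspect_ratio / small$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(big$feret_px / small$feret_px, 2, tolerance = 0.02)
})

test_that("a single-pixel object measures without division by zero", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  row <- measure_cell(label_map(m), 1L)
  expect_true(is.finite(row$circularity))
  expect_true(is.finite(row$perimeter_px))
  expect_gt(row$perimeter_px, 0)
})

test_that("the decision tree recovers the synthetic classes", {
  # perfect disc metrics classify as an unactivated spermatid
  disc <- measure_cell(label_map(draw_disk(40, 40, 20, 20, 9)), 1L)
  rec <- classify_activation(disc, activation_rules(reference_area = disc$area_px))
  expect_equal(rec$activation_class, "spermatid")
  expect_error(classify_activation(disc[, setdiff(names(disc), "extension")]),
               "missing metric")

  # zero-noise field: per-class confusion <= 5%
  cfg <- synthesis_config("spermatid_field", seed = 21, n_cells = 60,
    image_size = c(560L, 560L), touching_cell_fraction = 0,
    class_mixture = c(spermatid = 0.4, small_protrusion = 0.2,
                      spermatozoon = 0.3, abnormal = 0.1),
    noise = list(gaussian_sd = 0, poisson = FALSE),
    background = list(level = 20, gradient = 0))
  field <- synth_spermatid_field(cfg)
  morphs <- measure_cells(field$instances, field$image)
  recs <- classify_cells(morphs)
  truth <- field$truth$class[morphs$label]
  agree <- mean(recs$activation_class == truth)
  expect_gte(agree, 0.95)
  # directional fidelity: deformed (mutant-mixture) fields score lower
  # circularity and solidity than almost-all-round fields
  wt_like <- synth_spermatid_field(synthesis_config("spermatid_field",
    seed = 22, n_cells = 40, image_size = c(480L, 480L),
    class_mixture = c(spermatid = 0.05, small_protrusion = 0.05,
                      spermatozoon = 0.9, abnormal = 0)))
  td_like <- synth_spermatid_field(synthesis_config("spermatid_field",
    seed = 22, n_cells = 40, image_size = c(480L, 480L),
    class_mixture = c(spermatid = 0.9, small_protrusion = 0.05,
                      spermatozoon = 0.05, abnormal = 0)))
  m_wt <- measure_cells(wt_like$instances)
  m_td <- measure_cells(td_like$instances)
  expect_lt(mean(m_wt$circularity), mean(m_td$circularity))
  expect_lt(mean(m_wt$solidity), mean(m_td$solidity))
})

test_that("population summaries compute fractions and flag degeneracies", {
  recs <- data.frame(activation_class = rep(
    c("spermatozoon", "spermatid", "small_protrusion", "abnormal"),
    c(170, 20, 6, 4)))
  s <- summarize_activation(recs)
  expect_equal(s$n_total, 200L)
  expect_equal(unname(s$class_fractions["spermatozoon"]), 0.85)
  expect_equal(sum(s$class_fractions), 1, tolerance = 1e-9)
  one <- summarize_activation(data.frame(activation_class = rep("spermatid", 7)))
  expect_equal(unname(one$class_fractions["spermatid"]), 1)
  expect_error(summarize_activation(data.frame()), "no activation")
})

test_that("group mean/SEM agree with a two-pass variance oracle", {
  g <- group_mean_sem(c(2, 4, 6), rep("a", 3))
  expect_equal(g$mean, 4)
  expect_equal(g$sem, 2 / sqrt(3), tolerance = 1e-12)
  single <- group_mean_sem(5, "a")
  expect_true(single$degenerate)
  expect_true(is.na(single$sem))
  set.seed(9)
  v <- rnorm(40); grp <- rep(c("x", "y"), 20)
  out <- group_mean_sem(v, grp)
  for (k in c("x", "y")) {
    vv <- v[grp == k]
    mu <- sum(vv) / length(vv)
    var2 <- sum((vv - mu)^2) / (length(vv) - 1)   # explicit two-pass
    expect_equal(out$sem[out$group == k], sqrt(var2 / length(vv)),
                 tolerance = 1e-12)
  }
})

test_that("reversion frequency is exact arithmetic with integer display", {
  r <- reversion_frequency(7, 162)
  expect_equal(r$percent, 700 / 162)
  expect_equal(r$display, 4L)
  expect_equal(reversion_frequency(0, 100)$percent, 0)
  expect_equal(reversion_frequency(1, 3)$percent, 100 / 3, tolerance = 1e-9)
  expect_error(reversion_frequency(3, 0), "positive")
  expect_error(reversion_frequency(5, 4), "n_revertant")
})
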