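test_that("preprocessing flattens background and preserves blob signal", {
  # pure linear gradient: residual slope under 10% of input slope
  nr <- 128; nc <- 128
  grad <- outer(rep(1, nr), seq(0, 40, length.out = nc))
  pre <- preprocess_mito(image2d(grad + 5), clahe = FALSE)
  # fit the residual plane over the filter-valid interior
  inner <- 30:(nc - 30)
  slope <- function(m) coef(lm(as.vector(m[, inner]) ~
                                 as.vector(col(m)[, inner])))[2]
  expect_lt(abs(slope(unclass(pre))), 0.1 * abs(slope(grad)))

  # blob on zero background: integrated signal preserved within 15%
  blob <- matrix(0, 96, 96)
  dr <- outer(1:96 - 48, rep(1, 96)); dc <- t(dr)
  blob <- 100 * exp(-(dr^2 + dc^2) / (2 * 2.5^2))
  mask <- blob > 1
  pre2 <- preprocess_mito(image2d(blob), ball_radius_px = 15L)
  expect_equal(sum(unclass(pre2)[mask]) / sum(blob[mask]), 1,
               tolerance = 0.15)
  # output is finite and non-negative (no idempotence claim: CLAHE is nonlinear)
  expect_true(all(is.finite(unclass(pre2))) && all(unclass(pre2) >= 0))
  expect_error(preprocess_mito(image2d(matrix(1, 3, 3)), clahe_tiles = 10L),
               "larger than image")
})

test_that("the >=7 px size-filter stage is exact and detection handles blanks", {
  m <- matrix(0L, 20, 30)
  m[2, 2:4] <- 1L                       # 3 px
  m[6:7, 10:12] <- 1L; m[6, 13] <- 1L   # 7 px
  m[12:14, 20:23] <- 1L                 # 12 px
  expect_equal(attr(size_filter(m, 7L), "n_objects"), 2L)
  blank <- detect_mitochondria(image2d(matrix(3, 64, 64)))
  expect_equal(attr(blank, "n_objects"), 0L)
})

test_that("detection recovers blob geometry from noiseless renders", {
  render_blob <- function(ar, sy = 1.4) {
    m <- matrix(0, 80, 80)
    dr <- outer(1:80 - 40, rep(1, 80)); dc <- t(dr)
    m + 150 * exp(-((dc / (ar * sy))^2 + (dr / sy)^2) / 2)
  }
  round_lab <- detect_mitochondria(image2d(render_blob(1)))
  expect_equal(attr(round_lab, "n_objects"), 1L)
  expect_lte(measure_mitochondria(round_lab)$aspect_ratio[1], 1.1)
  elong_lab <- detect_mitochondria(image2d(render_blob(3)))
  ar <- measure_mitochondria(elong_lab)$aspect_ratio[1]
  expect_gte(ar, 2.5); expect_lte(ar, 3.5)
})

test_that("find-maxima merges plateaus but splits prominent twin peaks", {
  img <- matrix(0, 10, 14); img[4:6, 4:10] <- 5; img[5, 6:8] <- 9
  labs <- label_components(img > 0)
  expect_equal(nrow(find_blob_maxima(img, labs, 0.10)), 1L)
  img2 <- matrix(0, 10, 20)
  img2[4:6, 3:17] <- 3; img2[5, 5] <- 10; img2[5, 15] <- 8
  expect_equal(nrow(find_blob_maxima(img2, label_components(img2 > 0), 0.10)), 2L)
})

test_that("per-cell counts are exact on constructed scenes and conserved", {
  cells <- matrix(0L, 60, 100)
  cells[6:55, 6:45] <- 1L; cells[6:55, 55:95] <- 2L
  cells <- label_map(cells)
  mito <- matrix(0, 60, 100)
  at <- rbind(c(15, 15), c(30, 25), c(45, 35),                 # 3 in cell 1
              c(15, 65), c(25, 80), c(40, 70), c(50, 88))     # 4 in cell 2
  for (k in seq_len(nrow(at))) {
    dr <- outer(1:60 - at[k, 1], rep(1, 100)); dc <- outer(rep(1, 60), 1:100 - at[k, 2])
    mito <- mito + 200 * exp(-(dr^2 + dc^2) / (2 * 1.5^2))
  }
  labs <- detect_mitochondria(image2d(mito))
  cnt <- count_mitochondria_per_cell(labs, cells, image = image2d(mito))
  expect_equal(as.integer(cnt), c(3L, 4L))
  expect_equal(sum(cnt) + attr(cnt, "orphans"), attr(cnt, "n_points"))
})

test_that("count conservation holds on a full synthetic field", {
  f <- synth_jc1_field(preset_config("wt-jc1", 3))
  pre <- preprocess_mito(f$stack$red)
  labs <- detect_mitochondria(pre)
  cnt <- count_mitochondria_per_cell(labs, f$cells, image = pre)
  expect_equal(sum(cnt) + attr(cnt, "orphans"), attr(cnt, "n_points"))
  expect_true(all(cnt >= 0))
})

test_that("red:green ratios are computed per cell with safe degeneracies", {
  cells <- label_map(matrix(rep(c(0L, 1L), c(20, 80)), 10, 10))
  red <- image2d(matrix(2.5, 10, 10))     # total over 80 px = 200
  green <- image2d(matrix(1.25, 10, 10))  # total = 100
  r <- jc1_ratio(channel_stack(red = red, green = green), cells)
  expect_equal(r$red_green_ratio, 2.0)
  r0 <- jc1_ratio(channel_stack(red = image2d(matrix(0, 10, 10)),
                                green = green), cells)
  expect_equal(r0$red_green_ratio, 0)
  rg0 <- jc1_ratio(channel_stack(red = red,
                                 green = image2d(matrix(0, 10, 10))), cells)
  expect_true(is.na(rg0$red_green_ratio))
})

test_that("the ratio estimator is unbiased on noiseless renders", {
  f <- synth_jc1_field(synthesis_config("jc1_field", 7, n_cells = 4,
    image_size = c(220L, 220L),
    background = list(level = 0, gradient = 0),
    noise = list(gaussian_sd = 0, poisson = FALSE)))
  r <- jc1_ratio(f$noiseless, f$cells)
  expect_equal(r$red_green_ratio, f$truth$ratio, tolerance = 1e-6)
})

test_that("a depolarised fraction shows up as a green-channel detection excess", {
  # two replicate fields per condition, as the assay pools males
  pts <- function(preset, seed) {
    f <- synth_jc1_field(preset_config(preset, seed))
    sapply(c("red", "green"), function(ch) {
      pre <- preprocess_mito(f$stack[[ch]])
      nrow(find_blob_maxima(pre, detect_mitochondria(pre), 0.10))
    })
  }
  excess <- 0; configured <- 0
  for (seed in 1:2) {
    f <- synth_jc1_field(preset_config("mut-jc1", seed))
    configured <- configured + sum(f$mito_truth$low_mmp)
    p <- pts("mut-jc1", seed)
    excess <- excess + (p["green"] - p["red"])
  }
  expect_equal(unname(excess) / configured, 1, tolerance = 0.20)
})
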