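test_that("largest-remainder rounding gives exact stratified counts", {
  mix <- c(spermatid = 0.63, small_protrusion = 0.09,
           spermatozoon = 0.23, abnormal = 0.05)
  expect_equal(unname(largest_remainder(mix, 200)), c(126L, 18L, 46L, 10L))
  expect_equal(unname(largest_remainder(c(a = 1, b = 0, c = 0, d = 0), 50)),
               c(50L, 0L, 0L, 0L))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(4); p <- p / sum(p)
    n <- sample(50:400, 1)
    cnt <- largest_remainder(p, n)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - p * n) < 1))
  }
  expect_error(largest_remainder(c(0.5, 0.4), 10), "sum to 1")
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- synthesis_config("spermatid_field", seed = 13, n_cells = 12,
                          image_size = c(220L, 220L))
  set.seed(123); before <- runif(1)
  a <- synth_spermatid_field(cfg)
  b <- synth_spermatid_field(cfg)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth, b$truth)
  set.seed(123)
  expect_identical(runif(1), before)   # global stream untouched by position
})

test_that("truth masks measured on noiseless renders recover amplitudes", {
  cfg <- synthesis_config("spermatid_field", seed = 17, n_cells = 8,
    image_size = c(200L, 200L), touching_cell_fraction = 0,
    noise = list(gaussian_sd = 0, poisson = FALSE),
    background = list(level = 20, gradient = 0))
  f <- synth_spermatid_field(cfg)
  inst <- unclass(f$instances)
  for (l in f$truth$label) {
    got <- mean(unclass(f$noiseless)[inst == l]) - 20
    expect_equal(got, f$truth$amplitude[l], tolerance = 1e-9)
  }
})

test_that("class mixtures render the demanded composition", {
  f <- synth_spermatid_field(synthesis_config("spermatid_field", 3,
    n_cells = 50, image_size = c(460L, 460L)))
  expect_equal(sum(f$truth$class == "spermatid"), 50L)
  g <- synth_spermatid_field(preset_config("mut-pronase", 3, n_cells = 200))
  expect_equal(unname(table(factor(g$truth$class,
    c("spermatid", "small_protrusion", "spermatozoon", "abnormal")))),
    c(126L, 18L, 46L, 10L), ignore_attr = TRUE)
  expect_error(synth_spermatid_field(synthesis_config("spermatid_field", 3,
    n_cells = 80, image_size = c(120L, 120L))), "overlap budget")
})

test_that("JC-1 truth encodes the configured membrane-potential structure", {
  all_high <- synth_jc1_field(synthesis_config("jc1_field", 19, n_cells = 6,
    image_size = c(300L, 300L), low_mmp_fraction = 0))
  expect_true(all(all_high$mito_truth$red_amp > all_high$mito_truth$green_amp))
  round_only <- synth_jc1_field(synthesis_config("jc1_field", 19, n_cells = 6,
    image_size = c(300L, 300L), mito_elongation = c(mean = 1, sd = 0)))
  expect_true(all(round_only$mito_truth$aspect_ratio == 1))
  wt <- synth_jc1_field(preset_config("wt-jc1", 19))
  mut <- synth_jc1_field(preset_config("mut-jc1", 19))
  expect_gt(mean(mut$mito_truth$aspect_ratio), mean(wt$mito_truth$aspect_ratio))
  frac_low <- mean(mut$mito_truth$low_mmp)
  expect_equal(frac_low, 0.30, tolerance = 0.01)  # stratified count
})

test_that("reporter scenes expose exact truth means and brightness ratios", {
  sc <- synth_reporter_animal(preset_config("reporter", 23,
    noise = list(gaussian_sd = 0, poisson = FALSE)))
  expect_equal(mean(unclass(sc$image)[sc$mask]), sc$truth$animal_mean)
  expect_equal(mean(unclass(sc$image)[!sc$mask]), sc$truth$background_mean)
  bright <- synth_reporter_animal(preset_config("reporter", 23,
    brightness_factor = 1.3, noise = list(gaussian_sd = 0, poisson = FALSE)))
  adj <- bright$truth$animal_mean - bright$truth$background_mean
  adj0 <- sc$truth$animal_mean - sc$truth$background_mean
  expect_equal(adj / adj0, 1.3, tolerance = 1e-9)
})

test_that("uterus scenes place sperm at the demanded axis fractions", {
  # bypass randomness: direct scene at fractions 0.1/0.5/0.9
  sc <- uterus_scene(c(128, 60), c(128, 450),
                     cbind(128, 60 + c(0.1, 0.5, 0.9) * 390))
  expect_equal(assign_zones(sc)$zone, c(1L, 2L, 3L))
  tl <- synth_uterus_timelapse(preset_config("uterus", 29, n_sperm = 10L,
                                             n_frames = 4L))
  expect_length(tl$frames, 4L)
  expect_equal(nrow(tl$tracks), 40L)
  expect_equal(tl$truth$zone, assign_zones(tl$scene)$zone)
})
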