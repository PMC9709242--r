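# Ground-truthed synthetic microscopy generator.
#
# Every downstream stage is validated against fields rendered here: round
# spermatids with optional protrusions and abnormal morphs, two-channel
# JC-1 fields with per-mitochondrion red/green amplitudes, worm-shaped
# reporter scenes, and uterus timelapses with moving sperm puncta.
#
# Determinism contract: all draws flow from one generator seeded from the
# config; the caller's RNG state is untouched; identical config + seed
# yields identical output.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Exact stratified class counts (largest-remainder rounding)
#'
#' Class counts are deterministic rounds of `mixture * n`, not binomial
#' draws, so fraction-recovery tests see classifier error only, never
#' sampling error.
#'
#' @param mixture named non-negative fractions summing to 1.
#' @param n total count.
#' @return integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(mixture, n) {
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture must sum to 1")
  if (any(mixture < 0 | mixture > 1)) stop("fractions must be in [0, 1]")
  exact <- mixture * n
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  setNames(as.integer(counts), names(mixture))
}

#' Synthesis configuration
#'
#' One constructor covers all scene kinds; kind-specific fields are nested.
#' Defaults encode the study conditions each preset emulates; geometry that
#' no real calibration pins down (absolute spermatid radius in pixels) is a
#' documented plausible placeholder.
#'
#' @param kind one of `"spermatid_field"`, `"jc1_field"`, `"reporter"`,
#'   `"uterus"`.
#' @param seed integer RNG seed.
#' @param ... overrides of the kind's defaults (nested lists merged).
#' @return a `SynthesisConfig` list.
#' @export
synthesis_config <- function(kind = c("spermatid_field", "jc1_field",
                                      "reporter", "uterus"),
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    spermatid_field = list(
      image_size = c(900L, 900L),
      n_cells = 200L,
      class_mixture = c(spermatid = 1, small_protrusion = 0,
                        spermatozoon = 0, abnormal = 0),
      cell_radius_px = c(mean = 9, sd = 0.35),
      cell_amplitude = c(mean = 120, sd = 5),
      # pseudopod length/width as fractions of the cell diameter
      pseudopod = list(length = c(0.6, 0.9), width = 0.45, tip_width = 0.3),
      small_protrusion = list(length = c(0.2, 0.3), width = 0.3),
      spike = list(length = c(0.55, 0.8), width_px = 2),
      swollen_area_factor = 1.5,
      vacuole_radius_frac = 0.45,
      touching_cell_fraction = 0.05,
      noise = list(gaussian_sd = 2, poisson = FALSE),
      background = list(level = 20, gradient = 10)),
    jc1_field = list(
      image_size = c(512L, 512L),
      n_cells = 24L,
      cell_radius_px = c(mean = 18, sd = 0.8),
      body_green_amplitude = 35,
      mito_per_cell = c(mean = 8, sd = 1.2),
      mito_sigma_px = c(mean = 1.3, sd = 0.08),
      mito_elongation = c(mean = 1.2, sd = 0.10),   # log-normal on aspect ratio
      mmp_profile = list(red_mean = 120, green_mean = 60, mito_log_sd = 0.08,
                         cell_log_sd = 0.08,
                         low_red = 4, low_green = 140),
      low_mmp_fraction = 0.05,
      noise = list(gaussian_sd = 2, poisson = FALSE),
      background = list(level = 8, gradient = 0)),
    reporter = list(
      image_size = c(300L, 400L),
      worm_radius_px = 12,
      worm_amplitude = 40,
      brightness_factor = 1.0,
      background = list(level = 10, gradient = 0),
      noise = list(gaussian_sd = 1.5, poisson = FALSE)),
    uterus = list(
      image_size = c(256L, 512L),
      vulva = c(128, 60),
      spermatheca = c(128, 450),
      n_sperm = 30L,
      axis_beta = c(5, 1.5),     # Beta(a, b) over the vulva->spermatheca axis
      perp_sd_px = 12,
      speed = c(mean = 0.15, sd = 0.03),   # px/s
      frame_interval_s = 30,
      n_frames = 10L,
      spot = list(sigma = 1.5, amplitude = 150),
      noise = list(gaussian_sd = 2, poisson = FALSE),
      background = list(level = 10, gradient = 0)))
  cfg <- modifyList(base, list(...), keep.null = TRUE)
  cfg$kind <- kind
  cfg$seed <- as.integer(seed)
  validate_synthesis_config(cfg)
  structure(cfg, class = c("SynthesisConfig", "list"))
}

validate_synthesis_config <- function(cfg) {
  if (cfg$kind == "spermatid_field") {
    if (abs(sum(cfg$class_mixture) - 1) > 1e-9)
      stop("class_mixture must sum to 1")
    if (any(cfg$class_mixture < 0 | cfg$class_mixture > 1))
      stop("class fractions must be in [0, 1]")
    if (cfg$touching_cell_fraction < 0 || cfg$touching_cell_fraction > 1)
      stop("touching_cell_fraction must be in [0, 1]")
  }
  if (cfg$kind == "jc1_field") {
    if (cfg$low_mmp_fraction < 0 || cfg$low_mmp_fraction > 1)
      stop("low_mmp_fraction must be in [0, 1]")
  }
  if (cfg$kind == "uterus" && cfg$frame_interval_s <= 0)
    stop("frame interval must be positive")
  invisible(cfg)
}

#' Named synthesis presets
#'
#' `wt-pronase`, `mut-pronase` and `aka36-pronase` encode the published
#' four-class activation mixtures (wild-type 85% activated; mutant
#' 63/9/23/5; AKA36 62/12/21/5 as spermatid / small protrusion /
#' spermatozoon / abnormal). `wt-jc1` and `mut-jc1` encode the
#' mitochondrial contrasts (elongated, larger, more often low-MMP
#' mitochondria and more variable per-cell membrane potential in the
#' mutant, with equal expected red:green ratio). `reporter` and `uterus`
#' cover the whole-animal reporter and sperm-motility scenes.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param ... further overrides passed to [synthesis_config()].
#' @return a `SynthesisConfig`.
#' @export
preset_config <- function(name, seed = 1L, ...) {
  presets <- list(
    "wt-pronase" = list(kind = "spermatid_field",
      class_mixture = c(spermatid = 0.09, small_protrusion = 0.04,
                        spermatozoon = 0.85, abnormal = 0.02)),
    "mut-pronase" = list(kind = "spermatid_field",
      class_mixture = c(spermatid = 0.63, small_protrusion = 0.09,
                        spermatozoon = 0.23, abnormal = 0.05)),
    "aka36-pronase" = list(kind = "spermatid_field",
      class_mixture = c(spermatid = 0.62, small_protrusion = 0.12,
                        spermatozoon = 0.21, abnormal = 0.05)),
    "wt-jc1" = list(kind = "jc1_field"),
    # mutant mitochondria are fewer, larger and elongated (hyperfusion),
    # with a 30% depolarised (green-dominant) fraction and a wider
    # per-cell membrane-potential spread; red_mean is set so the expected
    # per-cell red:green ratio equals the wild-type preset (the published
    # contrast is greater dispersion at an unchanged mean)
    "mut-jc1" = list(kind = "jc1_field",
      cell_radius_px = c(mean = 22, sd = 0.8),
      mito_elongation = c(mean = 3.0, sd = 0.12),
      mito_sigma_px = c(mean = 1.5, sd = 0.08),
      mito_per_cell = c(mean = 5, sd = 0.8),
      low_mmp_fraction = 0.30,
      mmp_profile = list(red_mean = 98, green_mean = 60, mito_log_sd = 0.25,
                         cell_log_sd = 0.35, low_red = 4, low_green = 140)),
    "reporter" = list(kind = "reporter"),
    "uterus" = list(kind = "uterus"),
    "uterus-mut" = list(kind = "uterus",
      axis_beta = c(1.5, 5), speed = c(mean = 0.05, sd = 0.01)))
  if (!name %in% names(presets)) stop("unknown preset: ", name)
  args <- presets[[name]]
  kind <- args$kind
  args$kind <- NULL
  args <- modifyList(args, list(...), keep.null = TRUE)
  do.call(synthesis_config, c(list(kind = kind, seed = seed), args))
}

# --- shared rendering helpers ----------------------------------------------

background_canvas <- function(size, bg) {
  nr <- size[1]; nc <- size[2]
  grad <- if (nc > 1) bg$gradient * (col(matrix(0, nr, nc)) - 1) / (nc - 1) else 0
  matrix(bg$level, nr, nc) + grad
}

apply_noise <- function(canvas, noise) {
  if (isTRUE(noise$poisson)) canvas[] <- rpois(length(canvas), pmax(canvas, 0))
  if (noise$gaussian_sd > 0)
    canvas <- canvas + rnorm(length(canvas), 0, noise$gaussian_sd)
  pmax(canvas, 0)
}

# Non-overlapping circle placement with an optional touching fraction.
# Returns centers, honouring per-cell effective radii (body + protrusion).
place_cells <- function(n, size, r_eff, touching_fraction, margin = 3) {
  nr <- size[1]; nc <- size[2]
  centers <- matrix(NA_real_, n, 2)
  n_pairs <- floor(touching_fraction * n / 2)
  touch_partner <- rep(NA_integer_, n)
  if (n_pairs > 0)
    touch_partner[seq_len(n_pairs) * 2] <- seq_len(n_pairs) * 2 - 1
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:4000) {
      if (!is.na(touch_partner[i])) {
        j <- touch_partner[i]
        ang <- runif(1, 0, 2 * pi)
        d <- r_eff[i] + r_eff[j] - 1   # in contact
        cand <- centers[j, ] + d * c(cos(ang), sin(ang))
      } else {
        cand <- c(runif(1, r_eff[i] + 2, nr - r_eff[i] - 1),
                  runif(1, r_eff[i] + 2, nc - r_eff[i] - 1))
      }
      if (cand[1] < r_eff[i] + 2 || cand[1] > nr - r_eff[i] - 1 ||
          cand[2] < r_eff[i] + 2 || cand[2] > nc - r_eff[i] - 1) next
      prev <- seq_len(i - 1L)
      prev <- prev[!is.na(centers[prev, 1])]
      prev <- setdiff(prev, touch_partner[i])
      ok <- TRUE
      if (length(prev)) {
        dd <- sqrt((centers[prev, 1] - cand[1])^2 +
                   (centers[prev, 2] - cand[2])^2)
        ok <- all(dd > r_eff[prev] + r_eff[i] + margin)
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("cells cannot be placed without exceeding the overlap budget; ",
           "image too small for n_cells")
  }
  list(centers = centers, touch_partner = touch_partner)
}

# local window iterator: returns row/col ranges clipped to the canvas
window_at <- function(size, cr, cc, half) {
  list(rr = max(1, floor(cr - half)):min(size[1], ceiling(cr + half)),
       cc = max(1, floor(cc - half)):min(size[2], ceiling(cc + half)))
}

# --- spermatid field --------------------------------------------------------

#' Render a synthetic spermatid field with ground truth
#'
#' Cells are drawn as bright discs over a (possibly sloped) background.
#' Class counts are exact stratified rounds of `class_mixture * n_cells`
#' ([largest_remainder()]); per-object geometry is random. Activated
#' spermatozoa carry a tapered pseudopod, "small protrusion" cells a short
#' bump, and the abnormal class renders one of three sub-morphs: a thin
#' spike, a swollen disc (1.5x area) or an internal dark vacuole.
#'
#' @param config a [synthesis_config()] of kind `"spermatid_field"`.
#' @return list with `image` ([image2d()]), `truth` (per-cell data.frame:
#'   label, class, centroid, radius, protrusion geometry, amplitude,
#'   abnormal sub-morph) and `instances` ([label_map()] of true masks).
#' @export
synth_spermatid_field <- function(config) {
  stopifnot(identical(config$kind, "spermatid_field"))
  with_seed(config$seed, {
    n <- config$n_cells
    size <- config$image_size
    counts <- largest_remainder(config$class_mixture, n)
    classes <- sample(rep(names(counts), counts))
    radius <- pmax(5, rnorm(n, config$cell_radius_px["mean"],
                            config$cell_radius_px["sd"]))
    amp <- pmax(20, rnorm(n, config$cell_amplitude["mean"],
                          config$cell_amplitude["sd"]))
    submorph <- rep(NA_character_, n)
    submorph[classes == "abnormal"] <-
      sample(c("spike", "swollen", "vacuolated"),
             sum(classes == "abnormal"), replace = TRUE)
    radius[which(submorph == "swollen")] <-
      radius[which(submorph == "swollen")] * sqrt(config$swollen_area_factor)
    # protrusion geometry (lengths as fractions of cell diameter)
    prot_len <- numeric(n); prot_w0 <- numeric(n); prot_w1 <- numeric(n)
    for (i in seq_len(n)) {
      if (classes[i] == "spermatozoon") {
        prot_len[i] <- runif(1, config$pseudopod$length[1],
                             config$pseudopod$length[2])
        prot_w0[i] <- config$pseudopod$width * 2 * radius[i]
        prot_w1[i] <- config$pseudopod$tip_width * 2 * radius[i]
      } else if (classes[i] == "small_protrusion") {
        prot_len[i] <- runif(1, config$small_protrusion$length[1],
                             config$small_protrusion$length[2])
        prot_w0[i] <- config$small_protrusion$width * 2 * radius[i]
        prot_w1[i] <- 0.6 * prot_w0[i]
      } else if (!is.na(submorph[i]) && submorph[i] == "spike") {
        prot_len[i] <- runif(1, config$spike$length[1], config$spike$length[2])
        prot_w0[i] <- config$spike$width_px
        prot_w1[i] <- config$spike$width_px
      }
    }
    r_eff <- radius + prot_len * 2 * radius
    pl <- place_cells(n, size, r_eff, config$touching_cell_fraction)
    centers <- pl$centers
    theta <- runif(n, 0, 2 * pi)
    canvas <- matrix(0, size[1], size[2])
    inst <- matrix(0L, size[1], size[2])
    for (i in seq_len(n)) {
      w <- window_at(size, centers[i, 1], centers[i, 2], r_eff[i] + 2)
      dr <- outer(w$rr - centers[i, 1], rep(1, length(w$cc)))
      dc <- outer(rep(1, length(w$rr)), w$cc - centers[i, 2])
      mask <- dr^2 + dc^2 <= radius[i]^2
      a <- matrix(0, length(w$rr), length(w$cc))
      a[mask] <- amp[i]
      if (prot_len[i] > 0) {
        L <- prot_len[i] * 2 * radius[i]
        u <- c(cos(theta[i]), sin(theta[i]))
        base <- c(radius[i] - 1, 0)   # along u from the center
        t <- (dr - base[1] * u[1]) * u[1] + (dc - base[1] * u[2]) * u[2]
        perp <- abs(-(dr - base[1] * u[1]) * u[2] + (dc - base[1] * u[2]) * u[1])
        wd <- prot_w0[i] + (prot_w1[i] - prot_w0[i]) * pmax(0, pmin(1, t / L))
        pm <- t >= 0 & t <= L & perp <= wd / 2
        a[pm & a == 0] <- 0.85 * amp[i]
        mask <- mask | pm
      }
      if (!is.na(submorph[i]) && submorph[i] == "vacuolated") {
        vm <- dr^2 + dc^2 <= (config$vacuole_radius_frac * radius[i])^2
        a[vm] <- 0
      }
      canvas[w$rr, w$cc] <- canvas[w$rr, w$cc] + a
      sub <- inst[w$rr, w$cc]
      sub[mask & sub == 0L] <- i
      inst[w$rr, w$cc] <- sub
    }
    noiseless <- canvas + background_canvas(size, config$background)
    img <- apply_noise(noiseless, config$noise)
    truth <- data.frame(
      label = seq_len(n), class = classes, submorph = submorph,
      centroid_row = centers[, 1], centroid_col = centers[, 2],
      radius_px = radius, prot_len_frac = prot_len,
      prot_base_width_px = prot_w0, amplitude = amp,
      touching = !is.na(pl$touch_partner) | seq_len(n) %in% pl$touch_partner)
    list(image = image2d(img, channel_role = "brightfield"),
         truth = truth, instances = label_map(inst),
         noiseless = image2d(noiseless, channel_role = "brightfield"))
  })
}

# --- JC-1 field -------------------------------------------------------------

#' Render a synthetic two-channel JC-1 field with ground truth
#'
#' Spermatids are discs whose green channel carries a diffuse cell-body
#' signal (so a generous green mask captures whole cells); mitochondria are
#' anisotropic Gaussian blobs with per-mitochondrion red and green
#' amplitudes. A `low_mmp_fraction` of mitochondria (exact stratified
#' count) is green-dominant (depolarised). Non-depolarised red amplitudes
#' are scaled so the expected total red signal is independent of
#' `low_mmp_fraction`, letting presets differ in ratio dispersion but not
#' ratio mean. A per-cell membrane-potential factor (mean-preserving
#' log-normal) scales red amplitudes cell-wise.
#'
#' @param config a [synthesis_config()] of kind `"jc1_field"`.
#' @return list with `stack` ([channel_stack()] red+green), `cells`
#'   ([label_map()] of true cell discs), `truth` (per-cell data.frame with
#'   the true red/green totals and ratio) and `mito_truth`
#'   (per-mitochondrion data.frame with true ellipse parameters and
#'   amplitudes), plus the noiseless channel canvases.
#' @export
synth_jc1_field <- function(config) {
  stopifnot(identical(config$kind, "jc1_field"))
  with_seed(config$seed, {
    n <- config$n_cells
    size <- config$image_size
    radius <- pmax(6, rnorm(n, config$cell_radius_px["mean"],
                            config$cell_radius_px["sd"]))
    pl <- place_cells(n, size, radius + 4, 0)
    centers <- pl$centers
    nm <- pmax(0L, as.integer(round(rnorm(n, config$mito_per_cell["mean"],
                                          config$mito_per_cell["sd"]))))
    total_m <- sum(nm)
    prof <- config$mmp_profile
    f <- config$low_mmp_fraction
    n_low <- as.integer(round(f * total_m))
    low <- rep(FALSE, total_m)
    if (n_low > 0) low[sample.int(total_m, n_low)] <- TRUE
    # mean-preserving compensation so E[total red] does not depend on f
    comp <- if (f < 1) 1 / (1 - f + f * prof$low_red / prof$red_mean) else 1
    cell_factor <- exp(rnorm(n, -prof$cell_log_sd^2 / 2, prof$cell_log_sd))
    red_c <- matrix(0, size[1], size[2])
    green_c <- matrix(0, size[1], size[2])
    inst <- matrix(0L, size[1], size[2])
    mito_rows <- vector("list", total_m)
    cell_red_total <- numeric(n); cell_green_total <- numeric(n)
    mid <- 0L
    for (i in seq_len(n)) {
      w <- window_at(size, centers[i, 1], centers[i, 2], radius[i] + 2)
      dr <- outer(w$rr - centers[i, 1], rep(1, length(w$cc)))
      dc <- outer(rep(1, length(w$rr)), w$cc - centers[i, 2])
      mask <- dr^2 + dc^2 <= radius[i]^2
      # diffuse monomer signal falls off smoothly (a dome), as the
      # out-of-focus cell-body fluorescence does; a hard-edged disc would
      # put a spurious Laplacian edge ring into the blob detector
      body <- config$body_green_amplitude *
        sqrt(pmax(0, 1 - (dr^2 + dc^2) / radius[i]^2))
      green_c[w$rr, w$cc] <- green_c[w$rr, w$cc] + body
      cell_green_total[i] <- cell_green_total[i] + sum(body)
      sub <- inst[w$rr, w$cc]; sub[mask & sub == 0L] <- i
      inst[w$rr, w$cc] <- sub
      # mitochondria inside the cell, kept apart so blobs stay resolvable
      mcent <- matrix(NA_real_, nm[i], 2)
      sy <- pmax(0.8, rnorm(nm[i], config$mito_sigma_px["mean"],
                            config$mito_sigma_px["sd"]))
      ar <- exp(rnorm(nm[i], log(config$mito_elongation["mean"]),
                      config$mito_elongation["sd"]))
      sx <- sy * ar
      for (k in seq_len(nm[i])) {
        for (try in 1:1500) {
          rho <- sqrt(runif(1)) * (radius[i] - sx[k] - 1)
          ang <- runif(1, 0, 2 * pi)
          cand <- centers[i, ] + rho * c(cos(ang), sin(ang))
          prev <- seq_len(k - 1L)
          ok <- !length(prev) ||
            all(sqrt((mcent[prev, 1] - cand[1])^2 +
                     (mcent[prev, 2] - cand[2])^2) > (sx[k] + 3))
          if (ok) { mcent[k, ] <- cand; break }
        }
        if (is.na(mcent[k, 1]))
          stop("mito_per_cell exceeds cell capacity")
      }
      mtheta <- runif(nm[i], 0, pi)
      for (k in seq_len(nm[i])) {
        mid <- mid + 1L
        if (low[mid]) {
          ra <- prof$low_red
          ga <- prof$low_green
        } else {
          ra <- prof$red_mean * comp * cell_factor[i] *
            exp(rnorm(1, -prof$mito_log_sd^2 / 2, prof$mito_log_sd))
          ga <- prof$green_mean *
            exp(rnorm(1, -prof$mito_log_sd^2 / 2, prof$mito_log_sd))
        }
        half <- 3.5 * sx[k] + 1
        mw <- window_at(size, mcent[k, 1], mcent[k, 2], half)
        mdr <- outer(mw$rr - mcent[k, 1], rep(1, length(mw$cc)))
        mdc <- outer(rep(1, length(mw$rr)), mw$cc - mcent[k, 2])
        u <- mdr * cos(mtheta[k]) + mdc * sin(mtheta[k])
        v <- -mdr * sin(mtheta[k]) + mdc * cos(mtheta[k])
        g <- exp(-(u^2 / (2 * sx[k]^2) + v^2 / (2 * sy[k]^2)))
        g[g < 0.01] <- 0
        red_c[mw$rr, mw$cc] <- red_c[mw$rr, mw$cc] + ra * g
        green_c[mw$rr, mw$cc] <- green_c[mw$rr, mw$cc] + ga * g
        cell_red_total[i] <- cell_red_total[i] + ra * sum(g)
        cell_green_total[i] <- cell_green_total[i] + ga * sum(g)
        mito_rows[[mid]] <- data.frame(
          mito_id = mid, cell = i, centroid_row = mcent[k, 1],
          centroid_col = mcent[k, 2], theta = mtheta[k],
          sigma_major = sx[k], sigma_minor = sy[k],
          aspect_ratio = sx[k] / sy[k], red_amp = ra, green_amp = ga,
          low_mmp = low[mid])
      }
    }
    bgc <- background_canvas(size, config$background)
    red_n <- red_c + bgc
    green_n <- green_c + bgc
    red <- apply_noise(red_n, config$noise)
    green <- apply_noise(green_n, config$noise)
    # truth totals are the noiseless rendered signal under each cell mask,
    # so measuring the zero-background noiseless render reproduces the
    # truth ratio exactly
    sel <- inst > 0L
    fct <- factor(inst[sel], levels = seq_len(n))
    cell_red_total <- as.numeric(tapply(red_c[sel], fct, sum, default = 0))
    cell_green_total <- as.numeric(tapply(green_c[sel], fct, sum, default = 0))
    truth <- data.frame(
      label = seq_len(n), centroid_row = centers[, 1],
      centroid_col = centers[, 2], radius_px = radius,
      n_mito = nm, mmp_factor = cell_factor,
      red_total = cell_red_total, green_total = cell_green_total,
      ratio = ifelse(cell_green_total > 0,
                     cell_red_total / cell_green_total, NA_real_))
    list(stack = channel_stack(red = image2d(red, channel_role = "red"),
                               green = image2d(green, channel_role = "green")),
         cells = label_map(inst), truth = truth,
         mito_truth = do.call(rbind, mito_rows),
         noiseless = channel_stack(
           red = image2d(red_n, channel_role = "red"),
           green = image2d(green_n, channel_role = "green")))
  })
}

# --- whole-animal reporter scene -------------------------------------------

#' Render a synthetic whole-animal reporter image with ground truth
#'
#' A worm-shaped region (a thick sinusoidal tube) of known amplitude over a
#' background of known level; `brightness_factor` scales the animal signal
#' to emulate reporter induction. Truth stores the noiseless mean intensity
#' inside the animal mask and over the background.
#'
#' @param config a [synthesis_config()] of kind `"reporter"`.
#' @return list with `image`, `mask` (logical animal ROI), and `truth`
#'   (`animal_mean`, `background_mean` of the noiseless render).
#' @export
synth_reporter_animal <- function(config) {
  stopifnot(identical(config$kind, "reporter"))
  with_seed(config$seed, {
    size <- config$image_size
    nr <- size[1]; nc <- size[2]
    margin <- config$worm_radius_px + 6
    t <- seq(0, 1, length.out = 4 * nc)
    amp_r <- runif(1, 0.1, 0.22) * nr
    ph <- runif(1, 0, 2 * pi)
    cr <- nr / 2 + amp_r * sin(2 * pi * 1.5 * t + ph)
    cc <- margin + t * (nc - 2 * margin)
    mask <- matrix(FALSE, nr, nc)
    for (j in seq_along(t)) {
      w <- window_at(size, cr[j], cc[j], config$worm_radius_px + 1)
      dr <- outer(w$rr - cr[j], rep(1, length(w$cc)))
      dc <- outer(rep(1, length(w$rr)), w$cc - cc[j])
      mask[w$rr, w$cc] <- mask[w$rr, w$cc] |
        (dr^2 + dc^2 <= config$worm_radius_px^2)
    }
    noiseless <- background_canvas(size, config$background)
    noiseless[mask] <- noiseless[mask] +
      config$worm_amplitude * config$brightness_factor
    img <- apply_noise(noiseless, config$noise)
    list(image = image2d(img, channel_role = "green"),
         mask = mask,
         truth = list(animal_mean = mean(noiseless[mask]),
                      background_mean = mean(noiseless[!mask]),
                      brightness_factor = config$brightness_factor))
  })
}

# --- uterus timelapse -------------------------------------------------------

#' Render a synthetic uterus timelapse with ground truth
#'
#' Sperm are bright Gaussian puncta between the vulva and spermatheca
#' landmarks. Initial axis positions follow a Beta distribution (wild-type
#' presets skew towards the spermatheca, mutant presets towards the
#' vulva). Each sperm moves with a constant per-frame step length drawn
#' from the configured speed distribution and a random heading per frame,
#' so the true path speed of a track equals its drawn speed exactly.
#'
#' @param config a [synthesis_config()] of kind `"uterus"`.
#' @return list with `frames` (list of [image2d()]), `scene` (a
#'   [uterus_scene()] of the first-frame positions), `tracks` (data.frame
#'   `track`, `frame`, `t`, `row`, `col`) and `truth` (per-sperm
#'   data.frame: axis fraction, zone, true speed in px/s).
#' @export
synth_uterus_timelapse <- function(config) {
  stopifnot(identical(config$kind, "uterus"))
  if (config$frame_interval_s <= 0) stop("frame interval must be positive")
  with_seed(config$seed, {
    size <- config$image_size
    v <- config$vulva; s <- config$spermatheca
    n <- config$n_sperm
    axis <- s - v
    frac <- stats::rbeta(n, config$axis_beta[1], config$axis_beta[2])
    perp <- rnorm(n, 0, config$perp_sd_px)
    pu <- c(-axis[2], axis[1]) / sqrt(sum(axis^2))
    pos <- cbind(v[1] + frac * axis[1] + perp * pu[1],
                 v[2] + frac * axis[2] + perp * pu[2])
    pos[, 1] <- pmin(pmax(pos[, 1], 5), size[1] - 4)
    pos[, 2] <- pmin(pmax(pos[, 2], 5), size[2] - 4)
    speed <- pmax(0, rnorm(n, config$speed["mean"], config$speed["sd"]))
    dt <- config$frame_interval_s
    step <- speed * dt
    nf <- config$n_frames
    track_rows <- vector("list", nf)
    frames <- vector("list", nf)
    cur <- pos
    for (fidx in seq_len(nf)) {
      if (fidx > 1) {
        for (i in seq_len(n)) {
          if (step[i] == 0) next
          for (try in 1:50) {
            ang <- runif(1, 0, 2 * pi)
            cand <- cur[i, ] + step[i] * c(cos(ang), sin(ang))
            if (cand[1] >= 5 && cand[1] <= size[1] - 4 &&
                cand[2] >= 5 && cand[2] <= size[2] - 4) {
              cur[i, ] <- cand; break
            }
          }
        }
      }
      track_rows[[fidx]] <- data.frame(
        track = seq_len(n), frame = fidx, t = (fidx - 1) * dt,
        row = cur[, 1], col = cur[, 2])
      canvas <- background_canvas(size, config$background)
      for (i in seq_len(n)) {
        w <- window_at(size, cur[i, 1], cur[i, 2], 4 * config$spot$sigma)
        dr <- outer(w$rr - cur[i, 1], rep(1, length(w$cc)))
        dc <- outer(rep(1, length(w$rr)), w$cc - cur[i, 2])
        canvas[w$rr, w$cc] <- canvas[w$rr, w$cc] + config$spot$amplitude *
          exp(-(dr^2 + dc^2) / (2 * config$spot$sigma^2))
      }
      frames[[fidx]] <- image2d(apply_noise(canvas, config$noise),
                                channel_role = "red")
    }
    scene <- uterus_scene(v, s, pos)
    zones <- assign_zones(scene)
    list(frames = frames, scene = scene,
         tracks = do.call(rbind, track_rows),
         truth = data.frame(track = seq_len(n), axis_fraction = frac,
                            zone = zones$zone, speed_px_s = speed))
  })
}
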