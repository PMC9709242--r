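# Shape morphometry and rule-based sperm-activation classification.
#
# Metric conventions follow particle-analysis practice:
#   circularity = 4*pi*area / perimeter^2, capped at 1 (rasterization can
#     push the raw value slightly above 1 on small objects);
#   solidity    = area / convex hull area, the hull area being the pixel
#     count of the rasterized convex hull (so a rasterized disc scores
#     ~1, and solidity <= 1 by construction);
#   aspect ratio = major/minor axis of the moment-fitted ellipse (a 1/12
#     per-pixel variance term keeps one-pixel-wide shapes finite);
#   Feret diameter = maximum caliper distance, computed by rotating
#     calipers over the convex hull of the pixel corners;
#   perimeter   = Crofton-style weighted boundary-configuration length
#     (4-direction integral-geometry weights), the estimator circularity
#     is calibrated against.

# --- low-level metric engine ------------------------------------------------

# Crofton perimeter (4 directions): every 2x2 pixel configuration is coded
# and weighted by the integral-geometry look-up table, converging to the
# continuous perimeter on smooth shapes -- the estimator circularity is
# calibrated against.
crofton_perimeter <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0L, nr + 4, nc + 4)
  P[3:(nr + 2), 3:(nc + 2)] <- m
  i <- 2:(nr + 4); j <- 2:(nc + 4)
  code <- P[i, j] + 4L * P[i, j - 1] + 2L * P[i - 1, j] + 8L * P[i - 1, j - 1]
  h <- tabulate(code, nbins = 15L)
  s2 <- sqrt(2)
  coefs <- c(pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

# Moment-fitted ellipse of a pixel coordinate set (arr.ind matrix).
ellipse_moments <- function(idx) {
  r <- idx[, 1]; c <- idx[, 2]
  cr <- mean(r); cc <- mean(c)
  n <- length(r)
  # central second moments with the 1/12 unit-pixel variance term
  mrr <- sum((r - cr)^2) / n + 1 / 12
  mcc <- sum((c - cc)^2) / n + 1 / 12
  mrc <- sum((r - cr) * (c - cc)) / n
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  theta <- 0.5 * atan2(2 * mrc, mrr - mcc)
  # axes of the constant-density ellipse with these moments: semi-axis 2*sqrt(lambda),
  # then scaled to preserve the pixel area (particle-analysis convention)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  scale <- sqrt(n / (pi * a * b))
  list(cr = cr, cc = cc, theta = theta,
       major = 2 * a * scale, minor = 2 * b * scale,
       aspect_ratio = sqrt(l1 / max(l2, 1e-12)))
}

# Convex hull (as polygon vertices) over the 4 corners of each pixel.
pixel_hull <- function(idx) {
  corners <- rbind(
    cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
    cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(corners[, 2], corners[, 1])
  corners[h, , drop = FALSE]
}

polygon_area <- function(p) {
  x <- p[, 2]; y <- p[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Convex hull area as a pixel count: number of pixel centers inside the
# hull polygon of the pixel centers (the rasterized-hull convention: a
# rasterized disc or rectangle is exactly convex under it).
convex_pixel_area <- function(idx) {
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hull <- idx[h, , drop = FALSE]
  if (nrow(hull) < 3) return(nrow(idx))
  rr <- min(idx[, 1]):max(idx[, 1])
  cc <- min(idx[, 2]):max(idx[, 2])
  pr <- rep(rr, times = length(cc))
  pc <- rep(cc, each = length(rr))
  # orient hull counter-clockwise in (col, row) plane
  if (signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  inside <- rep(TRUE, length(pr))
  m <- nrow(hull)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    cr <- (hull[k2, 2] - hull[k, 2]) * (pr - hull[k, 1]) -
          (hull[k2, 1] - hull[k, 1]) * (pc - hull[k, 2])
    inside <- inside & cr >= -1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

signed_area <- function(p) {
  x <- p[, 2]; y <- p[, 1]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Maximum caliper (Feret) diameter of a point set
#'
#' Rotating calipers over the convex hull.
#'
#' @param pts two-column matrix of (row, col) coordinates.
#' @return the maximum pairwise distance.
#' @export
feret_diameter <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]       # counter-clockwise hull
  m <- nrow(hp)
  if (m == 1L) return(0)
  if (m == 2L) return(sqrt(sum((hp[1, ] - hp[2, ])^2)))
  d2 <- function(i, j) sum((hp[i, ] - hp[j, ])^2)
  cross <- function(o, a, b)
    (hp[a, 2] - hp[o, 2]) * (hp[b, 1] - hp[o, 1]) -
    (hp[a, 1] - hp[o, 1]) * (hp[b, 2] - hp[o, 2])
  best <- 0
  k <- 2L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    # advance the caliper point farthest from edge (i, j)
    repeat {
      kn <- if (k == m) 1L else k + 1L
      if (abs(cross(i, j, kn)) > abs(cross(i, j, k))) k <- kn else break
    }
    best <- max(best, d2(i, k), d2(j, k))
  }
  sqrt(best)
}

# Largest inscribed-disk radius (distance-transform maximum) of a mask.
body_radius <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  max(as.vector(EBImage::distmap(EBImage::Image(m))))
}

# --- per-object measurement -------------------------------------------------

#' Measure shape metrics of one labelled object
#'
#' @param labels a [label_map()].
#' @param label the object id to measure.
#' @param image optional matching intensity image; when given, the mean,
#'   sd and coefficient of variation of the intensity under the mask are
#'   included (used e.g. to flag vacuolated spermatids).
#' @return a one-row data.frame (`CellMorphometry`): `label`, `area_px`,
#'   `area_um2` (if the image carries a pixel size), `perimeter_px`,
#'   `circularity`, `solidity`, `aspect_ratio`, `feret_px`, `centroid_row`,
#'   `centroid_col`, `body_radius_px`, `extension` (how far the longest
#'   axis exceeds the inscribed-body diameter, as a fraction of it),
#'   `protrusion_width_px`, and intensity statistics when available.
#' @export
measure_cell <- function(labels, label, image = NULL) {
  labs <- unclass(labels)
  idx <- which(labs == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("label ", label, " not present")
  area <- nrow(idx)
  # local window mask (padded by 1) for boundary work
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  win <- matrix(FALSE, r1 - r0 + 3, c1 - c0 + 3)
  win[cbind(idx[, 1] - r0 + 2, idx[, 2] - c0 + 2)] <- TRUE
  perim <- crofton_perimeter(win)
  if (perim <= 0) perim <- 4 * sqrt(area)   # single-pixel convention
  circ <- min(1, 4 * pi * area / perim^2)
  hull <- pixel_hull(idx)
  solidity <- min(1, area / max(area, convex_pixel_area(idx)))
  em <- ellipse_moments(idx)
  feret <- feret_diameter(hull)
  rb <- body_radius(win)
  extension <- max(0, feret - 2 * rb) / (2 * rb)
  prot_w <- protrusion_width(win, rb)
  out <- data.frame(
    label = label, area_px = area, perimeter_px = perim,
    circularity = circ, solidity = solidity,
    aspect_ratio = em$aspect_ratio, feret_px = feret,
    centroid_row = em$cr, centroid_col = em$cc,
    body_radius_px = rb, extension = extension,
    protrusion_width_px = prot_w)
  if (!is.null(image)) {
    px <- unclass(image)[cbind(idx[, 1], idx[, 2])]
    out$mean_intensity <- mean(px)
    out$sd_intensity <- sd(px)
    out$intensity_cv <- if (mean(px) > 0) sd(px) / mean(px) else 0
    psz <- attr(image, "pixel_size_um")
    out$area_um2 <- if (is.null(psz) || is.na(psz)) NA_real_ else area * psz^2
  }
  out
}

# Width of the dominant protrusion: open away the cell body (disc element
# scaled to the inscribed radius), dilate the body by one pixel to absorb
# boundary slivers, and report twice the inscribed radius of the largest
# remaining appendage (its full local width).
protrusion_width <- function(win, rb) {
  size <- max(3L, 2L * as.integer(round(0.6 * rb)) + 1L)
  brush <- EBImage::makeBrush(size, "disc")
  m <- EBImage::Image(matrix(as.numeric(win), nrow(win), ncol(win)))
  opened <- EBImage::dilate(EBImage::erode(m, brush), brush)
  body <- matrix(as.vector(EBImage::dilate(opened, matrix(1, 3, 3))) > 0,
                 nrow(win), ncol(win))
  prot <- win & !body
  if (sum(prot) < 4) return(0)
  comps <- label_components(prot, 8L)
  areas <- tabulate(unclass(comps)[unclass(comps) > 0], n_objects(comps))
  main <- unclass(comps) == which.max(areas)
  if (sum(main) < 4) return(0)
  2 * body_radius(main)
}

#' Measure all objects of a label map
#'
#' @inheritParams measure_cell
#' @return a data.frame with one `CellMorphometry` row per object.
#' @export
measure_cells <- function(labels, image = NULL) {
  n <- n_objects(labels)
  if (n == 0L) return(measure_cell(label_map(matrix(1L, 2, 2)), 1L)[0, ])
  do.call(rbind, lapply(seq_len(n), measure_cell, labels = labels,
                        image = image))
}

# --- activation classification ---------------------------------------------

#' Default activation-classification rules
#'
#' The decision tree automates the manual four-class call (spermatid /
#' spermatid with small protrusion / spermatozoon with pseudopod /
#' abnormal). Thresholds are in units that scale with the cell:
#' `extension` is the protrusion length as a fraction of the cell-body
#' diameter. Defaults were calibrated so that noiseless synthetic fields
#' are recovered essentially perfectly; all are user-overridable.
#'
#' @param ext_small below this extension a cell counts as round (no
#'   protrusion). Default 0.20.
#' @param ext_long extension at or above which a protrusion counts as a
#'   full pseudopod. Default 0.50.
#' @param spike_max_width_px protrusions longer than `ext_long` but
#'   thinner than this are the abnormal "spiked" morph, not a pseudopod.
#'   Default 4 px.
#' @param swollen_area_factor round cells with area above this multiple of
#'   the reference (typical round-cell) area are abnormal (swollen).
#'   Default 1.22.
#' @param vacuole_cv round cells whose internal intensity coefficient of
#'   variation exceeds this are abnormal (vacuolated). Default 0.25.
#' @param reference_area typical round-cell area in pixels; `NA` (default)
#'   lets [classify_cells()] use the median area of round cells in the
#'   field.
#' @return a rules list.
#' @export
activation_rules <- function(ext_small = 0.20, ext_long = 0.50,
                             spike_max_width_px = 4,
                             swollen_area_factor = 1.22, vacuole_cv = 0.25,
                             reference_area = NA_real_) {
  list(ext_small = ext_small, ext_long = ext_long,
       spike_max_width_px = spike_max_width_px,
       swollen_area_factor = swollen_area_factor,
       vacuole_cv = vacuole_cv, reference_area = reference_area)
}

ACTIVATION_CLASSES <- c("spermatid", "small_protrusion", "spermatozoon",
                        "abnormal")

#' Classify one cell's activation state from its morphometry
#'
#' @param morph a one-row `CellMorphometry` data.frame from
#'   [measure_cell()].
#' @param rules an [activation_rules()] list.
#' @return a one-row data.frame (`ActivationRecord`): `label`,
#'   `activation_class`, and per-rule diagnostics.
#' @export
classify_activation <- function(morph, rules = activation_rules()) {
  need <- c("extension", "area_px", "protrusion_width_px")
  if (!all(need %in% names(morph)) || any(is.na(morph[need])))
    stop("missing metric(s): ", paste(setdiff(need, names(morph)), collapse = ", "))
  ext <- morph$extension
  cv <- if ("intensity_cv" %in% names(morph)) morph$intensity_cv else NA_real_
  ref <- rules$reference_area
  cls <- if (ext < rules$ext_small) {
    if (!is.na(ref) && morph$area_px > rules$swollen_area_factor * ref)
      "abnormal"
    else if (!is.na(cv) && cv > rules$vacuole_cv)
      "abnormal"
    else "spermatid"
  } else if (ext < rules$ext_long) {
    "small_protrusion"
  } else if (morph$protrusion_width_px < rules$spike_max_width_px) {
    "abnormal"
  } else "spermatozoon"
  data.frame(label = morph$label, activation_class = cls,
             score_extension = ext,
             score_protrusion_width = morph$protrusion_width_px,
             score_area_ratio = if (!is.na(ref)) morph$area_px / ref else NA_real_,
             score_intensity_cv = cv)
}

#' Classify every cell in a morphometry table
#'
#' When `rules$reference_area` is `NA` it is set to the median area of the
#' round cells (extension below `ext_small`) in the field, so the swollen
#' flag adapts to the strain's typical spermatid size.
#'
#' @param morphs data.frame from [measure_cells()].
#' @param rules an [activation_rules()] list.
#' @return data.frame of `ActivationRecord` rows.
#' @export
classify_cells <- function(morphs, rules = activation_rules()) {
  if (nrow(morphs) == 0L) stop("no cells to classify")
  if (is.na(rules$reference_area)) {
    round_cells <- morphs$extension < rules$ext_small
    rules$reference_area <- if (any(round_cells))
      median(morphs$area_px[round_cells]) else median(morphs$area_px)
  }
  do.call(rbind, lapply(seq_len(nrow(morphs)), function(i)
    classify_activation(morphs[i, ], rules)))
}

#' Summarise activation classes over a population
#'
#' @param records data.frame of `ActivationRecord` rows.
#' @return an `AssaySummary` list: `class_counts`, `class_fractions`
#'   (summing to 1), `n_total`.
#' @export
summarize_activation <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no activation records")
  counts <- table(factor(records$activation_class,
                         levels = ACTIVATION_CLASSES))
  counts <- setNames(as.integer(counts), ACTIVATION_CLASSES)
  structure(list(class_counts = counts,
                 class_fractions = counts / sum(counts),
                 n_total = sum(counts)),
            class = "AssaySummary")
}

#' @export
print.AssaySummary <- function(x, ...) {
  cat(sprintf("AssaySummary over %d cells\n", x$n_total))
  for (k in names(x$class_counts))
    cat(sprintf("  %-17s %4d  (%5.1f%%)\n", k, x$class_counts[[k]],
                100 * x$class_fractions[[k]]))
  invisible(x)
}

#' Mean and standard error per group
#'
#' SEM uses the sample (n-1) standard deviation. Groups of size one get
#' `NA` SEM, flagged in the `degenerate` column.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return data.frame with `group`, `mean`, `sem`, `n`, `degenerate`.
#' @export
group_mean_sem <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  gs <- split(values, groups)
  data.frame(
    group = names(gs),
    mean = vapply(gs, mean, numeric(1)),
    sem = vapply(gs, function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_, numeric(1)),
    n = vapply(gs, length, integer(1)),
    degenerate = vapply(gs, function(v) length(v) < 2, logical(1)),
    row.names = NULL)
}

#' Reversion frequency
#'
#' Percentage of assayed animals that reverted to normal fertility, with
#' its integer-rounded display form.
#'
#' @param n_revertant number of revertant animals.
#' @param n_total number of animals assayed (> 0).
#' @return list with `percent` (exact) and `display` (integer-rounded).
#' @export
reversion_frequency <- function(n_revertant, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_revertant < 0 || n_revertant > n_total)
    stop("n_revertant must be in [0, n_total]")
  p <- 100 * n_revertant / n_total
  list(percent = p, display = as.integer(round(p)))
}
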