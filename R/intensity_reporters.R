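# Redox-probe per-spermatid intensities and whole-animal reporter
# quantification (UPRmt and oxidative-stress transcriptional reporters).

#' Mean redox-probe intensity per spermatid
#'
#' Mean fluorescence of the pixels under each (ellipse-shaped) cell label
#' from [segment_redox_cells()].
#'
#' @param image fluorescence [image2d()].
#' @param cells cell [label_map()].
#' @return data.frame with `cell_label`, `area_px`, `mean_intensity`.
#' @export
redox_mean_intensity <- function(image, cells) {
  if (!all(dim(image) == dim(cells))) stop("image and labels shapes differ")
  cl <- unclass(cells); px <- unclass(image)
  n <- n_objects(cells)
  if (n == 0L)
    return(data.frame(cell_label = integer(0), area_px = integer(0),
                      mean_intensity = numeric(0)))
  sel <- cl > 0
  f <- factor(cl[sel], levels = seq_len(n))
  area <- as.integer(table(f))
  if (any(area == 0L)) stop("empty label encountered")
  data.frame(cell_label = seq_len(n), area_px = area,
             mean_intensity = as.numeric(tapply(px[sel], f, mean)))
}

#' Background-adjusted animal fluorescence
#'
#' `adjusted = mean grey value of the animal - mean of all background
#' readings`. A result below zero is returned, flagged.
#'
#' @param animal_mask_mean mean grey value inside the animal ROI.
#' @param background_means one or more background mean grey values.
#' @return list with `adjusted` and `negative` (flag).
#' @export
reporter_adjusted <- function(animal_mask_mean, background_means) {
  if (length(background_means) < 1) stop("at least one background reading")
  adj <- animal_mask_mean - mean(background_means)
  if (adj < 0) warning("background exceeds animal signal; adjusted value negative")
  list(adjusted = adj, negative = adj < 0)
}

#' Relative reporter fluorescence (normalised to the control group)
#'
#' Each adjusted intensity is divided by the mean adjusted intensity of
#' the control (wild-type) group, so the control group's mean relative
#' intensity is 1 by construction. Normalisation is idempotent and
#' invariant to a common intensity scale.
#'
#' @param adjusted_values numeric adjusted intensities, one per animal.
#' @param control_ids indices (or logical mask) of the control animals.
#' @return numeric vector of relative intensities.
#' @export
reporter_relative <- function(adjusted_values, control_ids) {
  ctrl <- adjusted_values[control_ids]
  if (length(ctrl) < 1) stop("control group is empty")
  cm <- mean(ctrl)
  if (cm <= 0) stop("control group mean must be positive")
  adjusted_values / cm
}

#' Quantify a whole-animal reporter image
#'
#' Measures the animal ROI mean and background mean on an image. The ROI
#' is either supplied as a polygon/mask (the manual-selection route) or
#' found automatically as the largest above-threshold component (the
#' synthetic-validation route); the provenance is recorded.
#'
#' @param image [image2d()].
#' @param roi_mask optional logical matrix selecting the animal.
#' @param background_mask optional logical matrix of background readings;
#'   defaults to everything outside (a dilation of) the animal ROI.
#' @return data.frame row: `mean_grey_animal`, `mean_grey_background`,
#'   `adjusted_intensity`, `roi_source`.
#' @export
measure_reporter_animal <- function(image, roi_mask = NULL,
                                    background_mask = NULL) {
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  source <- "supplied"
  if (is.null(roi_mask)) {
    thr <- threshold_otsu(px)
    labs <- label_components(px > thr, 8L)
    if (n_objects(labs) == 0L) stop("no animal found above threshold")
    areas <- tabulate(unclass(labs)[unclass(labs) > 0], n_objects(labs))
    roi_mask <- unclass(labs) == which.max(areas)
    source <- "auto_threshold"
  }
  if (is.null(background_mask)) {
    grown <- binary_closing(roi_mask, 1) |
      (matrix(as.vector(EBImage::dilate(
        EBImage::Image(matrix(as.numeric(roi_mask), nrow(px), ncol(px))),
        EBImage::makeBrush(9, "disc"))) > 0, nrow(px), ncol(px)))
    background_mask <- !grown
  }
  am <- mean(px[roi_mask]); bm <- mean(px[background_mask])
  adj <- reporter_adjusted(am, bm)
  data.frame(mean_grey_animal = am, mean_grey_background = bm,
             adjusted_intensity = adj$adjusted, negative = adj$negative,
             roi_source = source)
}
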