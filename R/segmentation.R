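# Cell masking pipelines.
#
# Two procedures are provided, mirroring the original toolchain:
#  * the "generous" green-channel mask used for JC-1-stained spermatids
#    (Otsu threshold scaled down so whole dim cells are captured, size
#    filter, fill holes, morphological closing, watershed split), and
#  * the Triangle-threshold mask used for redox-probe fields, in which each
#    segmented spermatid is replaced by its moment-fitted ellipse.

#' Masking parameters
#'
#' @param method `"generous_green"` or `"triangle"`.
#' @param generous_factor multiplier in (0, 1] applied to the automatic
#'   Otsu threshold; values below 1 make the mask more inclusive so dim
#'   spermatid borders are retained. Default 0.6.
#' @param min_object_px size filter: components smaller than this are
#'   discarded as debris. Default 50.
#' @param closing_rounds rounds of dilate-then-erode with a 3x3 square
#'   element. Default 2.
#' @param connectivity component connectivity, 4 or 8. Default 8.
#' @param watershed_tolerance minimum basin depth (in distance-map units)
#'   for a watershed seed; shallow basins (e.g. along a pseudopod) are
#'   merged into their parent cell. Default 3.
#' @return a `MaskingParams` list.
#' @export
masking_params <- function(method = c("generous_green", "triangle"),
                           generous_factor = 0.6, min_object_px = 50L,
                           closing_rounds = 2L, connectivity = 8L,
                           watershed_tolerance = 3) {
  method <- match.arg(method)
  if (generous_factor <= 0 || generous_factor > 1)
    stop("generous_factor must be in (0, 1]")
  if (min_object_px < 1) stop("min_object_px must be >= 1")
  structure(list(method = method, generous_factor = generous_factor,
                 min_object_px = as.integer(min_object_px),
                 closing_rounds = as.integer(closing_rounds),
                 connectivity = as.integer(connectivity),
                 watershed_tolerance = watershed_tolerance),
            class = "MaskingParams")
}

#' Fill holes in a binary mask
#'
#' @param mask logical/0-1 matrix.
#' @return logical matrix with all interior holes filled.
#' @export
fill_holes <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  out <- EBImage::fillHull(EBImage::Image(m))
  matrix(as.vector(out) > 0, nrow(mask), ncol(mask))
}

#' Morphological closing (dilate then erode)
#'
#' @param mask binary matrix.
#' @param rounds number of dilate-erode rounds.
#' @param kern structuring element matrix; default 3x3 square.
#' @return logical matrix.
#' @export
binary_closing <- function(mask, rounds = 2L, kern = matrix(1, 3, 3)) {
  m <- EBImage::Image(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  for (i in seq_len(rounds)) {
    m <- EBImage::dilate(m, kern)
    m <- EBImage::erode(m, kern)
  }
  matrix(as.vector(m) > 0, nrow(mask), ncol(mask))
}

#' Split touching objects by a distance-transform watershed
#'
#' Seeds are the maxima of the Euclidean distance map; basins shallower
#' than `tolerance` are merged, so narrow appendages (pseudopods) are not
#' cut off their cell. Foreground is never created: the labelled pixel set
#' equals the input foreground.
#'
#' @param mask binary matrix.
#' @param tolerance minimum seed depth in distance-map units.
#' @return a [label_map()].
#' @export
watershed_split <- function(mask, tolerance = 3) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(label_map(matrix(0L, nrow(mask), ncol(mask))))
  dm <- EBImage::distmap(EBImage::Image(m))
  ws <- EBImage::watershed(dm, tolerance = tolerance)
  relabel(matrix(as.integer(ws), nrow(mask), ncol(mask)))
}

#' Segment JC-1-stained spermatids from the green channel
#'
#' Pipeline (fixed order): generous threshold on the green channel (Otsu
#' scaled by `generous_factor`), size filter, fill holes, `closing_rounds`
#' of dilate/erode, watershed split of touching spermatids. The per-step
#' foreground pixel counts are recorded in the `"step_log"` attribute of
#' the result.
#'
#' @param stack a [channel_stack()] containing a `green` channel.
#' @param params a [masking_params()].
#' @return a [label_map()]; an all-background field yields 0 objects.
#' @export
segment_jc1_cells <- function(stack, params = masking_params()) {
  if (is_image2d(stack)) stack <- channel_stack(green = stack)
  if (!"green" %in% names(stack)) stop("stack has no green channel")
  g <- unclass(stack$green)
  log <- list()
  if (max(g) <= min(g)) {
    out <- label_map(matrix(0L, nrow(g), ncol(g)))
    attr(out, "step_log") <- list(threshold = 0L)
    return(out)
  }
  thr <- threshold_otsu(g) * params$generous_factor
  mask <- g > thr
  log$threshold_value <- thr
  log$threshold <- sum(mask)
  labs <- size_filter(mask, params$min_object_px, params$connectivity)
  mask <- unclass(labs) > 0
  log$size_filter <- sum(mask)
  mask <- fill_holes(mask)
  log$fill_holes <- sum(mask)
  mask <- binary_closing(mask, params$closing_rounds)
  log$closing <- sum(mask)
  out <- watershed_split(mask, params$watershed_tolerance)
  log$watershed_objects <- n_objects(out)
  attr(out, "step_log") <- log
  out
}

# Draw the moment-fitted ellipse of each labelled object; the fitted
# ellipse preserves the object's area and second-moment orientation/axes
# (the particle-analysis convention).
fit_ellipses <- function(labels) {
  labs <- unclass(labels)
  n <- n_objects(labels)
  out <- matrix(FALSE, nrow(labs), ncol(labs))
  params <- vector("list", n)
  for (l in seq_len(n)) {
    idx <- which(labs == l, arr.ind = TRUE)
    e <- ellipse_moments(idx)
    params[[l]] <- e
    # bounding window
    half <- e$major / 2 + 2
    r0 <- max(1, floor(e$cr - half)); r1 <- min(nrow(labs), ceiling(e$cr + half))
    c0 <- max(1, floor(e$cc - half)); c1 <- min(ncol(labs), ceiling(e$cc + half))
    rr <- r0:r1; cc <- c0:c1
    dr <- outer(rr - e$cr, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - e$cc)
    u <- dr * cos(e$theta) + dc * sin(e$theta)
    v <- -dr * sin(e$theta) + dc * cos(e$theta)
    inside <- (u / (e$major / 2))^2 + (v / (e$minor / 2))^2 <= 1
    out[rr, cc] <- out[rr, cc] | inside
  }
  list(mask = out, params = params)
}

#' Segment redox-probe-stained spermatids
#'
#' Pipeline (fixed order): Triangle threshold, fill holes, watershed,
#' size filter, replacement of each object by its moment-fitted ellipse so
#' the mask encapsulates whole spermatids, and a second watershed to
#' re-separate ellipses that merged. Final labels are ellipse shaped.
#'
#' @param image a single fluorescence channel ([image2d()]).
#' @param params a [masking_params()].
#' @return a [label_map()].
#' @export
segment_redox_cells <- function(image, params = masking_params("triangle")) {
  g <- unclass(image)
  thr <- threshold_triangle(g)   # errors on a constant image
  mask <- g > thr
  mask <- fill_holes(mask)
  labs <- watershed_split(mask, params$watershed_tolerance)
  labs <- size_filter(labs, params$min_object_px, params$connectivity)
  if (n_objects(labs) == 0L) return(labs)
  ell <- fit_ellipses(labs)
  out <- watershed_split(ell$mask, params$watershed_tolerance)
  attr(out, "ellipses") <- ell$params
  out
}

#' Outline overlay for segmentation quality control
#'
#' Marks the one-pixel inner boundary of every labelled object on a copy of
#' the original image at its maximum intensity, the usual mask-to-outline
#' QC overlay.
#'
#' @param labels a [label_map()].
#' @param image the matching [image2d()].
#' @return an [image2d()] QC overlay.
#' @export
outline_overlay <- function(labels, image) {
  if (!all(dim(labels) == dim(image))) stop("labels and image shapes differ")
  b <- boundary_mask(unclass(labels))
  out <- unclass(image)
  attributes(out) <- list(dim = dim(out))
  marker <- if (max(out) > min(out)) max(out) else max(out) + 1
  if (any(b)) out[b] <- marker
  image2d(out, bit_depth = attr(image, "bit_depth"),
          pixel_size_um = attr(image, "pixel_size_um"),
          channel_role = attr(image, "channel_role"))
}

# Inner boundary: object pixel with at least one 4-neighbour of a
# different value (background or another label), or on the image edge.
boundary_mask <- function(labs) {
  nr <- nrow(labs); nc <- ncol(labs)
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labs
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  up    <- pad[1:nr, 2:(nc + 1)]
  down  <- pad[3:(nr + 2), 2:(nc + 1)]
  left  <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  ctr > 0 & (up != ctr | down != ctr | left != ctr | right != ctr)
}
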