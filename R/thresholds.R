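# Automatic histogram thresholds and connected-component labeling.
#
# Triangle and IsoData operate on a 256-bin histogram spanning the data
# range, matching the classic implementations: the returned threshold is on
# the native intensity scale and foreground is the strict upper side
# (pixel > threshold).

hist256 <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx <= mn) return(NULL)
  bin <- pmin(255L, as.integer(floor((x - mn) / (mx - mn) * 256)))
  counts <- tabulate(bin + 1L, nbins = 256L)
  centers <- mn + (seq_len(256) - 0.5) / 256 * (mx - mn)
  list(counts = counts, centers = centers, mn = mn, mx = mx)
}

#' Triangle threshold
#'
#' Finds the histogram bin with the maximal perpendicular distance to the
#' chord drawn from the histogram peak to the far end of its longer tail.
#' Designed for strongly skewed histograms such as sparse fluorescence
#' fields.
#'
#' @param x numeric vector or matrix of intensities.
#' @return the threshold on the native intensity scale; foreground is
#'   `x > threshold`.
#' @export
threshold_triangle <- function(x) {
  h <- hist256(x)
  if (is.null(h)) stop("no threshold found: degenerate (constant) histogram")
  counts <- h$counts
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- min(nz); hi <- max(nz)
  # choose the longer tail; mirror so the tail is always to the right
  flipped <- (peak - lo) > (hi - peak)
  if (flipped) {
    counts <- rev(counts)
    peak <- 257L - peak
    hi <- 257L - lo
  }
  if (hi <= peak + 1L) bin <- peak
  else {
    # search strictly between the peak and the tail end: the endpoints
    # themselves are not admissible cuts
    idx <- (peak + 1L):(hi - 1L)
    # distance from (i, counts[i]) to the line from (peak, max) to (hi, 0)
    dx <- hi - peak; dy <- 0 - counts[peak]
    d <- abs(dx * (counts[peak] - counts[idx]) - (peak - idx) * dy)
    bin <- idx[which.max(d)]
  }
  if (flipped) bin <- 257L - bin
  h$mn + bin / 256 * (h$mx - h$mn)
}

#' IsoData (iterative intermeans) threshold
#'
#' Iterates `t <- (mean below t + mean above t) / 2` on a 256-bin histogram
#' until the fixed point is reached.
#'
#' @inheritParams threshold_triangle
#' @return the threshold on the native intensity scale, or `NA` if the
#'   histogram is degenerate (constant image).
#' @export
threshold_isodata <- function(x) {
  h <- hist256(x)
  if (is.null(h)) return(NA_real_)
  counts <- h$counts; centers <- h$centers
  t <- sum(counts * centers) / sum(counts)
  for (i in 1:200) {
    below <- centers <= t
    n0 <- sum(counts[below]); n1 <- sum(counts[!below])
    if (n0 == 0 || n1 == 0) break
    m0 <- sum(counts[below] * centers[below]) / n0
    m1 <- sum(counts[!below] * centers[!below]) / n1
    tn <- (m0 + m1) / 2
    if (abs(tn - t) < 1e-9 * (h$mx - h$mn)) { t <- tn; break }
    t <- tn
  }
  t
}

#' Otsu threshold
#'
#' Between-class variance maximisation on a 256-bin histogram (delegated to
#' EBImage), returned on the native intensity scale.
#'
#' @inheritParams threshold_triangle
#' @export
threshold_otsu <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx <= mn) stop("no threshold found: degenerate (constant) histogram")
  norm <- (as.matrix(x) - mn) / (mx - mn)
  mn + EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256) * (mx - mn)
}

#' Connected-component labeling
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8, the particle-analysis convention).
#' @return a [label_map()].
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab4 <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab4) <= 1L) return(relabel(lab4))
  if (connectivity != 8L) stop("connectivity must be 4 or 8")
  # merge 4-connected components that touch diagonally (union-find on ids)
  nr <- nrow(lab4); nc <- ncol(lab4)
  pairs <- rbind(
    cbind(as.vector(lab4[-nr, -nc]), as.vector(lab4[-1, -1])),
    cbind(as.vector(lab4[-1, -nc]), as.vector(lab4[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(max(lab4))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  out <- lab4
  out[out > 0] <- root[out[out > 0]]
  relabel(out)
}

#' Remove small components from a binary mask or label map
#'
#' Components with an area below `min_px` pixels are removed; everything of
#' `min_px` pixels or more is retained.
#'
#' @param x binary matrix or [label_map()].
#' @param min_px minimum area in pixels.
#' @param connectivity used to label a binary input.
#' @return a [label_map()] of the surviving components, relabelled 1..n.
#' @export
size_filter <- function(x, min_px, connectivity = 8L) {
  labs <- if (inherits(x, "LabelMap")) x else label_components(x, connectivity)
  if (n_objects(labs) == 0L) return(labs)
  areas <- tabulate(labs[labs > 0], nbins = n_objects(labs))
  keep <- which(areas >= min_px)
  out <- unclass(labs)
  out[!(out %in% keep)] <- 0L
  relabel(out)
}
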