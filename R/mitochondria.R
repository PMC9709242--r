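# JC-1 mitochondrial pipelines: preprocessing, blob detection,
# per-mitochondrion morphometry, per-cell counting, and the per-spermatid
# red:green intensity ratio (proportional to membrane potential).

#' Mitochondrial channel preprocessing
#'
#' Rolling-ball-style background subtraction (a separable min-then-max
#' filter of window half-size `ball_radius_px`, subtracted from the image)
#' followed by contrast-limited adaptive histogram equalisation (CLAHE).
#' Both stages are parameterised and the parameters are recorded on the
#' result. CLAHE is nonlinear, so the operation is not idempotent; the
#' output is finite, non-negative, and spans the input dynamic range.
#'
#' @param image fluorescence [image2d()].
#' @param ball_radius_px background window half-size in pixels.
#' @param clahe_tiles number of CLAHE tiles along each axis.
#' @param clahe_clip CLAHE clip limit.
#' @param clahe set `FALSE` to stop after background subtraction.
#' @return preprocessed [image2d()].
#' @export
preprocess_mito <- function(image, ball_radius_px = 25L, clahe_tiles = 4L,
                            clahe_clip = 2, clahe = TRUE) {
  m <- unclass(image); attributes(m) <- list(dim = dim(m))
  nr <- nrow(m); nc <- ncol(m)
  if (clahe_tiles > min(nr, nc)) stop("CLAHE tile grid larger than image")
  bg <- maxfilt(minfilt(m, ball_radius_px), ball_radius_px)
  sub <- pmax(m - bg, 0)
  rng <- max(sub) - min(sub)
  if (!clahe || rng <= 0)
    return(image2d(sub, channel_role = attr(image, "channel_role"),
                   pixel_size_um = attr(image, "pixel_size_um")))
  norm <- (sub - min(sub)) / rng
  eq <- EBImage::clahe(EBImage::Image(norm),
                       nx = clahe_tiles, ny = clahe_tiles, limit = clahe_clip)
  out <- pmax(matrix(as.vector(eq), nr, nc), 0) * rng + min(sub)
  out <- image2d(out, channel_role = attr(image, "channel_role"),
                 pixel_size_um = attr(image, "pixel_size_um"))
  attr(out, "preprocess") <- list(ball_radius_px = ball_radius_px,
                                  clahe_tiles = clahe_tiles,
                                  clahe_clip = clahe_clip)
  out
}

# separable running min/max with window half-size r (square element)
minfilt <- function(m, r) {
  f <- function(v) {
    n <- length(v)
    out <- v
    for (d in seq_len(r)) {
      out <- pmin(out, c(v[-seq_len(d)], rep(v[n], d)),
                  c(rep(v[1], d), v[seq_len(n - d)]))
    }
    out
  }
  t(apply(apply(m, 2, f), 1, f))
}

maxfilt <- function(m, r) -minfilt(-m, r)

#' Detect mitochondria as Laplacian blobs
#'
#' Fixed order: Gaussian-smoothed Laplacian (bright blobs give a negative
#' Laplacian, so the response is the negated filter output, clipped at
#' zero: the negative lobe never marks a blob interior), IsoData
#' (iterative intermeans) threshold on the clipped response, binary mask,
#' size filter keeping components of at least `min_px` pixels (default
#' exactly 7, the published debris cutoff), connected-component labels.
#' Clipping pins the background mode of the response histogram at zero,
#' which keeps the intermeans fixed point between background and blob
#' response rather than inside the noise.
#'
#' Mitochondria are sparse puncta: if the threshold would mark more than
#' `max_foreground_frac` of the field as foreground the response histogram
#' is degenerate (e.g. a signal-free noise field) and no blobs are
#' reported.
#'
#' @param image preprocessed [image2d()].
#' @param sigma Gaussian scale of the Laplacian filter in pixels.
#' @param min_px minimum component size retained.
#' @param connectivity component connectivity.
#' @param max_foreground_frac degenerate-threshold guard (fraction of
#'   pixels).
#' @return a [label_map()]; a constant or signal-free response yields 0
#'   objects.
#' @export
detect_mitochondria <- function(image, sigma = 1.0, min_px = 7L,
                                connectivity = 8L,
                                max_foreground_frac = 0.2) {
  m <- unclass(image); attributes(m) <- list(dim = dim(m))
  sm <- matrix(as.vector(EBImage::gblur(EBImage::Image(m), sigma = sigma)),
               nrow(m), ncol(m))
  lap <- matrix(as.vector(EBImage::filter2(
    EBImage::Image(sm),
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))), nrow(m), ncol(m))
  resp <- pmax(-lap, 0)  # mitochondria are bright: positive lobe of -Laplacian
  thr <- threshold_isodata(resp)
  if (is.na(thr) || mean(resp > thr) > max_foreground_frac)
    return(label_map(matrix(0L, nrow(m), ncol(m))))
  size_filter(resp > thr, min_px, connectivity)
}

#' Measure per-mitochondrion morphometry
#'
#' Reuses the cell metric engine (area, circularity, aspect ratio, Feret
#' diameter...). When a cell label map is provided, each mitochondrion is
#' assigned to the cell with which it shares the most pixels.
#'
#' @param labels mitochondrion [label_map()] from [detect_mitochondria()].
#' @param cells optional cell [label_map()].
#' @param channel optional channel tag recorded on each row.
#' @return data.frame of `MitoMorphometry` rows.
#' @export
measure_mitochondria <- function(labels, cells = NULL, channel = NA_character_) {
  out <- measure_cells(labels)
  if (nrow(out) == 0L) {
    out$cell_label <- integer(0); out$channel <- character(0)
    return(out)
  }
  names(out)[names(out) == "label"] <- "mito_id"
  out$channel <- channel
  out$cell_label <- if (is.null(cells)) NA_integer_
    else majority_cell(labels, cells)
  out
}

# majority-overlap cell assignment for each mito label (0 = orphan)
majority_cell <- function(labels, cells) {
  labs <- unclass(labels); cl <- unclass(cells)
  n <- n_objects(labels)
  sel <- labs > 0
  if (!any(sel)) return(integer(0))
  tab <- table(factor(labs[sel], levels = seq_len(n)), cl[sel])
  cols <- as.integer(colnames(tab))
  vapply(seq_len(n), function(l) {
    r <- tab[l, ]
    nz <- cols != 0L
    if (!any(nz) || all(r[nz] == 0)) 0L else cols[nz][which.max(r[nz])]
  }, integer(1))
}

#' Find one representative point per blob (maxima with tolerance)
#'
#' Within each labelled object, intensity maxima are located and maxima
#' not separated from a higher one by a dip of more than `tolerance`
#' (a fraction of the object's dynamic range) are merged, so a plateau or
#' two near-equal peaks yield a single point. Mirrors the find-maxima /
#' points conversion used to count mitochondria.
#'
#' @param image intensity [image2d()] (or matrix).
#' @param labels [label_map()] of blobs.
#' @param tolerance prominence tolerance as a fraction of each object's
#'   dynamic range.
#' @return data.frame with `row`, `col`, `label`, one or more points per
#'   label (typically exactly one).
#' @export
find_blob_maxima <- function(image, labels, tolerance = 0.10) {
  m <- unclass(image); attributes(m) <- list(dim = dim(m))
  labs <- unclass(labels)
  rows <- list()
  for (l in seq_len(n_objects(labels))) {
    idx <- which(labs == l, arr.ind = TRUE)
    vals <- m[idx]
    vmax <- max(vals); vmin <- min(vals)
    tol <- tolerance * max(vmax - vmin, .Machine$double.eps)
    r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
    nrw <- max(idx[, 1]) - r0 + 1L; ncw <- max(idx[, 2]) - c0 + 1L
    win <- matrix(-Inf, nrw, ncw)
    wi <- cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)
    win[wi] <- vals
    # candidate maxima: pixels with no strictly greater 8-neighbour
    pad <- matrix(-Inf, nrw + 2, ncw + 2)
    pad[2:(nrw + 1), 2:(ncw + 1)] <- win
    nbmax <- win
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbmax <- pmax(nbmax, pad[(2 + dr):(nrw + 1 + dr), (2 + dc):(ncw + 1 + dc)])
    }
    cand <- which(is.finite(win) & win >= nbmax, arr.ind = TRUE)
    cand <- cand[order(win[cand], decreasing = TRUE), , drop = FALSE]
    # a candidate is a real maximum iff the connected part of
    # {f >= v - tol} containing it holds no higher pixel (plateau ties and
    # shallower secondary bumps merge into the first-accepted peak)
    claimed <- matrix(FALSE, nrw, ncw)
    for (k in seq_len(nrow(cand))) {
      p <- cand[k, , drop = FALSE]
      if (claimed[p]) next
      v <- win[p]
      lev <- win >= v - tol
      comp <- label_components(lev, 8L)
      cc <- unclass(comp) == unclass(comp)[p]
      if (any(win[cc] > v) || any(claimed[cc])) { claimed <- claimed | cc; next }
      claimed <- claimed | cc
      rows[[length(rows) + 1L]] <- data.frame(
        row = p[1] + r0 - 1L, col = p[2] + c0 - 1L, label = l)
    }
  }
  if (!length(rows))
    return(data.frame(row = integer(0), col = integer(0), label = integer(0)))
  do.call(rbind, rows)
}

#' Count mitochondria per cell
#'
#' Each detected mitochondrion is collapsed to one representative point
#' (its internal intensity maximum, [find_blob_maxima()]); the count per
#' cell is the number of points falling inside that cell's label -- the
#' arithmetic equivalent of integrating a one-point-per-object mask and
#' dividing by the point value. A point landing on background (e.g. a cell
#' boundary) is assigned by majority overlap of its source blob; points
#' that remain unassigned are reported as orphans.
#'
#' @param labels mitochondrion [label_map()].
#' @param cells cell [label_map()] (same geometry).
#' @param image intensity image used to locate maxima; defaults to the
#'   label mask itself (every blob pixel equal, one plateau point each).
#' @param tolerance maxima prominence tolerance.
#' @return named integer vector of counts per cell label (1..n_cells),
#'   with the number of orphan points in attribute `"orphans"`.
#' @export
count_mitochondria_per_cell <- function(labels, cells, image = NULL,
                                        tolerance = 0.10) {
  if (!all(dim(labels) == dim(cells))) stop("label geometries differ")
  if (is.null(image)) image <- matrix(as.numeric(unclass(labels) > 0),
                                      nrow(labels), ncol(labels))
  pts <- find_blob_maxima(image, labels, tolerance)
  ncell <- n_objects(cells)
  counts <- setNames(integer(ncell), seq_len(ncell))
  orphans <- 0L
  if (nrow(pts)) {
    cl <- unclass(cells)
    assign <- cl[cbind(pts$row, pts$col)]
    fallback <- majority_cell(labels, cells)
    assign[assign == 0L] <- fallback[pts$label[assign == 0L]]
    orphans <- sum(assign == 0L)
    tab <- table(factor(assign[assign > 0L], levels = seq_len(ncell)))
    counts[] <- as.integer(tab)
  }
  attr(counts, "orphans") <- orphans
  attr(counts, "n_points") <- nrow(pts)
  counts
}

#' Per-spermatid JC-1 red:green intensity ratio
#'
#' Total red and green fluorescence under each cell mask; the ratio is
#' total red over total green, the membrane-potential readout. Cells with
#' zero green total get an `NA` ratio (flagged undefined, never infinity).
#'
#' @param stack [channel_stack()] with `red` and `green` channels.
#' @param cells cell [label_map()].
#' @param background_correct optional per-cell background subtraction: the
#'   mean intensity outside all cells times the cell area is subtracted
#'   from each total. Default off (totals are raw, as in the original
#'   measurement).
#' @return data.frame of `IntensityRecord` rows: `cell_label`,
#'   `total_red`, `total_green`, `mean_red`, `mean_green`,
#'   `red_green_ratio`.
#' @export
jc1_ratio <- function(stack, cells, background_correct = FALSE) {
  if (!all(c("red", "green") %in% names(stack)))
    stop("stack must contain red and green channels")
  cl <- unclass(cells)
  n <- n_objects(cells)
  if (n == 0L)
    return(data.frame(cell_label = integer(0), total_red = numeric(0),
                      total_green = numeric(0), mean_red = numeric(0),
                      mean_green = numeric(0), red_green_ratio = numeric(0)))
  red <- unclass(stack$red); green <- unclass(stack$green)
  sel <- cl > 0
  f <- factor(cl[sel], levels = seq_len(n))
  area <- as.numeric(table(f))
  tr <- as.numeric(tapply(red[sel], f, sum, default = 0))
  tg <- as.numeric(tapply(green[sel], f, sum, default = 0))
  if (background_correct) {
    br <- mean(red[!sel]); bg <- mean(green[!sel])
    tr <- tr - br * area
    tg <- tg - bg * area
  }
  data.frame(cell_label = seq_len(n), total_red = tr, total_green = tg,
             mean_red = tr / area, mean_green = tg / area,
             red_green_ratio = ifelse(tg > 0, tr / tg, NA_real_))
}
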