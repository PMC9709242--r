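# End-to-end assay drivers: one call reproduces a figure-level analysis
# from a preset name (or acquired images) and a run configuration, and
# emits the per-object tables its summary aggregates.

#' Run the in vitro sperm-activation assay
#'
#' Pipeline: segment (generous threshold + watershed on the single
#' channel), per-cell morphometry, rule-based activation classification,
#' population summary. Input is either a synthesis preset name
#' (`"wt-pronase"`, `"mut-pronase"`, `"aka36-pronase"`), a
#' `SynthesisConfig`, or a list of [image2d()] images.
#'
#' @param input preset name, [synthesis_config()], or list of images.
#' @param config a [run_config()]; `config$seed` seeds preset generation.
#' @return list with `summary` (an `AssaySummary`), `cells` (morphometry
#'   table), `records` (activation records), `labels` (the label map(s)),
#'   and `truth` when the input was synthetic.
#' @export
run_activation_assay <- function(input, config = run_config()) {
  imgs <- NULL; truth <- NULL
  if (is.character(input)) input <- preset_config(input, seed = config$seed)
  if (inherits(input, "SynthesisConfig")) {
    field <- synth_spermatid_field(input)
    imgs <- list(field$image)
    truth <- field$truth
  } else if (is_image2d(input)) imgs <- list(input)
  else imgs <- input
  params <- masking_params("generous_green",
                           generous_factor = config$segmentation$generous_factor,
                           min_object_px = config$segmentation$min_object_px,
                           closing_rounds = config$segmentation$closing_rounds,
                           connectivity = config$segmentation$connectivity,
                           watershed_tolerance = config$segmentation$watershed_tolerance)
  cells <- list(); records <- list(); labels <- list()
  for (i in seq_along(imgs)) {
    labs <- segment_jc1_cells(channel_stack(green = image2d(
      unclass(imgs[[i]]), channel_role = "green")), params)
    labels[[i]] <- labs
    if (n_objects(labs) == 0L) next
    morphs <- measure_cells(labs, imgs[[i]])
    recs <- classify_cells(morphs, config$rules)
    morphs$image <- i; recs$image <- i
    cells[[length(cells) + 1L]] <- morphs
    records[[length(records) + 1L]] <- recs
  }
  if (!length(records)) stop("zero cells found in all images")
  records <- do.call(rbind, records)
  list(summary = summarize_activation(records),
       cells = do.call(rbind, cells), records = records,
       labels = labels, truth = truth)
}

#' Run the JC-1 membrane-potential and mitochondrial-morphology assay
#'
#' Pipeline: generous green-channel cell segmentation then per-cell
#' red:green ratios; per channel (red and green): preprocessing, Laplacian
#' blob detection, per-mitochondrion morphometry and per-cell counts.
#'
#' @param input preset name (`"wt-jc1"`, `"mut-jc1"`), `SynthesisConfig`,
#'   or a [channel_stack()] with red and green channels.
#' @param config a [run_config()].
#' @return list with `ratios`, `mito` (morphometry, both channels),
#'   `counts` (per cell and channel), `cell_labels`, `mito_labels`, and
#'   `truth`/`mito_truth` when synthetic.
#' @export
run_jc1_assay <- function(input, config = run_config()) {
  truth <- NULL; mito_truth <- NULL
  if (is.character(input)) input <- preset_config(input, seed = config$seed)
  if (inherits(input, "SynthesisConfig")) {
    field <- synth_jc1_field(input)
    stack <- field$stack; truth <- field$truth; mito_truth <- field$mito_truth
  } else stack <- input
  if (!all(c("red", "green") %in% names(stack)))
    stop("stack must contain red and green channels")
  params <- masking_params("generous_green",
                           generous_factor = config$segmentation$generous_factor,
                           min_object_px = config$segmentation$min_object_px,
                           closing_rounds = config$segmentation$closing_rounds,
                           connectivity = config$segmentation$connectivity,
                           watershed_tolerance = config$segmentation$watershed_tolerance)
  cell_labels <- segment_jc1_cells(stack, params)
  ratios <- jc1_ratio(stack, cell_labels)
  mito <- list(); counts <- list(); mito_labels <- list()
  for (ch in c("red", "green")) {
    pre <- preprocess_mito(stack[[ch]],
                           ball_radius_px = config$mito$ball_radius_px,
                           clahe_tiles = config$mito$clahe_tiles,
                           clahe_clip = config$mito$clahe_clip)
    labs <- detect_mitochondria(pre, sigma = config$mito$log_sigma_px,
                                min_px = config$mito$min_mito_px,
                                connectivity = config$segmentation$connectivity)
    mito_labels[[ch]] <- labs
    mito[[ch]] <- measure_mitochondria(labs, cell_labels, channel = ch)
    cnt <- count_mitochondria_per_cell(labs, cell_labels, image = pre,
                                       tolerance = config$mito$maxima_tolerance)
    counts[[ch]] <- data.frame(cell_label = as.integer(names(cnt)),
                               channel = ch, n_mito = as.integer(cnt))
  }
  list(ratios = ratios,
       mito = do.call(rbind, mito),
       counts = do.call(rbind, counts),
       cell_labels = cell_labels, mito_labels = mito_labels,
       truth = truth, mito_truth = mito_truth)
}

#' Group summary (mean +/- SEM) of any assay table column
#'
#' @param table data.frame.
#' @param value_column numeric column to summarise.
#' @param group_column grouping column.
#' @return data.frame from [group_mean_sem()].
#' @export
run_group_summary <- function(table, value_column, group_column) {
  if (!value_column %in% names(table)) stop("no column ", value_column)
  if (!is.numeric(table[[value_column]])) stop("value column must be numeric")
  group_mean_sem(table[[value_column]], table[[group_column]])
}
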