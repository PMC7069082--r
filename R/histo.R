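#' Detect vessel objects in a CD31 immunofluorescence channel
#'
#' Isodata threshold (default) followed by connected-component labeling
#' (8-connectivity); objects below `min_area_px` pixels are removed. Touching
#' objects merge into one — the counter sees connected CD31-positive regions.
#'
#' @param cd31_channel 2D intensity matrix.
#' @param threshold numeric threshold, or `"isodata"`.
#' @param min_area_px minimum object area in pixels.
#' @return list with `labels` (integer matrix, relabeled 1..n), `count`,
#'   `objects` (data.frame id, area_px), `threshold`, `flat` flag (TRUE when
#'   the field carries no signal).
#' @export
detect_vessel_objects <- function(cd31_channel, threshold = "isodata",
                                  min_area_px = 5) {
  img <- as.matrix(cd31_channel)
  if (max(img) - min(img) <= 0)
    return(list(labels = matrix(0L, nrow(img), ncol(img)), count = 0L,
                objects = data.frame(id = integer(), area_px = integer()),
                threshold = NA_real_, flat = TRUE))
  thr <- if (identical(threshold, "isodata")) isodata_threshold(img)
  else as.numeric(threshold)
  mask <- img > thr
  lab <- label_components(mask, 26)  # 8-connectivity in the plane
  if (!any(mask))
    return(list(labels = lab, count = 0L,
                objects = data.frame(id = integer(), area_px = integer()),
                threshold = thr, flat = FALSE))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  out[lab > 0] <- relab[lab[lab > 0]]
  list(labels = out, count = length(keep),
       objects = data.frame(id = seq_along(keep), area_px = sizes[keep]),
       threshold = thr, flat = FALSE)
}

#' CD31-positive surface fraction of the field of view
#'
#' `100 * positive pixels / field pixels`.
#'
#' @param object_mask logical matrix (or labeled matrix; > 0 is positive).
#' @return percent in [0, 100].
#' @export
cd31_surface_fraction <- function(object_mask) {
  m <- object_mask > 0
  100 * sum(m) / length(m)
}

#' Pericyte coverage: fraction of CD31 vessels also alpha-SMA positive
#'
#' A vessel object counts as covered when the alpha-SMA-positive area
#' intersecting it reaches `min_overlap_frac` of the object area (default:
#' any overlap). Coverage = 100 x covered / total objects; undefined (NA,
#' flagged) when there are no objects.
#'
#' @param detection a [detect_vessel_objects()] result.
#' @param sma_channel 2D alpha-SMA intensity matrix (same shape).
#' @param sma_threshold numeric or `"isodata"`.
#' @param min_overlap_frac required overlap fraction in [0, 1]; 0 means any
#'   overlapping pixel.
#' @return list with `coverage_pct`, `n_covered`, `n_objects`, `undefined`.
#' @export
pericyte_coverage <- function(detection, sma_channel,
                              sma_threshold = "isodata",
                              min_overlap_frac = 0) {
  lab <- detection$labels
  stopifnot(identical(dim(lab), dim(sma_channel)))
  n <- detection$count
  if (n == 0)
    return(list(coverage_pct = NA_real_, n_covered = 0L, n_objects = 0L,
                undefined = TRUE))
  sma <- as.matrix(sma_channel)
  thr <- if (identical(sma_threshold, "isodata")) {
    if (max(sma) - min(sma) <= 0) Inf else isodata_threshold(sma)
  } else as.numeric(sma_threshold)
  sma_pos <- sma > thr
  covered <- vapply(seq_len(n), function(i) {
    obj <- lab == i
    ov <- sum(obj & sma_pos)
    if (min_overlap_frac <= 0) ov > 0 else ov >= min_overlap_frac * sum(obj)
  }, logical(1))
  list(coverage_pct = 100 * sum(covered) / n, n_covered = sum(covered),
       n_objects = n, undefined = FALSE)
}

#' Keep only capillary-scale objects (equivalent diameter below a cut)
#'
#' Equivalent diameter `2 * sqrt(area / pi)` in micrometers from the pixel
#' size; objects at or above `diameter_cut_um` are removed.
#'
#' @param detection a [detect_vessel_objects()] result.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param diameter_cut_um diameter cut (default 10 um).
#' @return a filtered detection (labels relabeled 1..k, objects subset with
#'   `equiv_diameter_um`).
#' @export
capillary_filter <- function(detection, pixel_size_um,
                             diameter_cut_um = 10) {
  obj <- detection$objects
  if (!nrow(obj)) return(detection)
  dia <- 2 * sqrt(obj$area_px * pixel_size_um^2 / pi)
  keep <- which(dia < diameter_cut_um)
  relab <- integer(nrow(obj))
  relab[keep] <- seq_along(keep)
  lab <- detection$labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- relab[lab[lab > 0]]
  objects <- obj[keep, , drop = FALSE]
  objects$id <- seq_along(keep)
  objects$equiv_diameter_um <- dia[keep]
  list(labels = out, count = length(keep), objects = objects,
       threshold = detection$threshold, flat = detection$flat)
}
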