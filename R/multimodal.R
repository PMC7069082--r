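#' Crop the ultrafast Doppler volume to the PET tumor VOI
#'
#' Sets power outside the VOI to the background value so that all downstream
#' vascular metrics are restricted to the PET-defined tumor. A grid/shape
#' mismatch is an error — modalities are co-registered by construction and
#' silent resampling would corrupt voxel counts.
#'
#' @param power_volume 3D power array.
#' @param tumor_voi logical mask or a `tumor_voi` object, same shape.
#' @param background value assigned outside the VOI (default 0).
#' @return list with `power` (masked volume), `empty` flag.
#' @export
crop_uui_to_pet_voi <- function(power_volume, tumor_voi, background = 0) {
  voi <- if (inherits(tumor_voi, "tumor_voi")) tumor_voi$mask else tumor_voi
  if (!identical(dim(power_volume), dim(voi)))
    stop("grids differ between PET VOI and power volume (no silent resampling)")
  out <- power_volume
  out[!voi] <- background
  list(power = out, empty = !any(voi))
}

#' Segment the tumor VOI into metabolic SUV bands
#'
#' Half-open bands over the late-frame SUV: low `[1, 2)`, intermediate
#' `[2, 3)`, high `[3, Inf)` by default; VOI voxels below the lowest edge
#' remain explicitly unassigned. Labels outside the VOI are NA.
#'
#' @param suv_volume 3D SUV array.
#' @param tumor_voi logical mask or `tumor_voi` object.
#' @param edges strictly increasing band edges (default `c(1, 2, 3)`).
#' @return object of class `metabolic_bands`: `labels` (integer array: 0 =
#'   unassigned, 1..k bands, NA outside the VOI), `edges`, `band_names`.
#' @export
segment_metabolic_bands <- function(suv_volume, tumor_voi, edges = c(1, 2, 3)) {
  voi <- if (inherits(tumor_voi, "tumor_voi")) tumor_voi$mask else tumor_voi
  stopifnot(identical(dim(suv_volume), dim(voi)))
  if (any(diff(edges) <= 0)) stop("band edges must be strictly increasing")
  lab <- array(NA_integer_, dim(suv_volume))
  lab[voi] <- findInterval(suv_volume[voi], edges)
  nm <- if (length(edges) == 3) c("unassigned", "low", "intermediate", "high")
  else c("unassigned", paste0("band", seq_along(edges)))
  structure(list(labels = lab, edges = edges, band_names = nm),
            class = "metabolic_bands")
}

#' Per-band vessel and region volumes
#'
#' Counts vessel voxels falling in each metabolic band (unassigned included)
#' and the band region volumes, in mm^3.
#'
#' @param vessel_mask logical array on the shared grid.
#' @param bands a [segment_metabolic_bands()] result.
#' @param spacing_mm voxel spacing (mm).
#' @return data.frame with `band`, `region_mm3`, `vessel_mm3`.
#' @export
regional_vessel_volume <- function(vessel_mask, bands, spacing_mm = 0.1) {
  stopifnot(inherits(bands, "metabolic_bands"))
  if (!identical(dim(vessel_mask), dim(bands$labels)))
    stop("grids differ between vessel mask and band labels")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  vv <- prod(spacing_mm)
  k <- length(bands$edges)
  lvl <- 0:k
  region <- vapply(lvl, function(b)
    sum(bands$labels == b, na.rm = TRUE), numeric(1)) * vv
  vessel <- vapply(lvl, function(b)
    sum(vessel_mask & !is.na(bands$labels) & bands$labels == b), numeric(1)) * vv
  data.frame(band = bands$band_names, region_mm3 = region, vessel_mm3 = vessel)
}

#' Regional vessel density per metabolic band
#'
#' Density = band vessel volume / band region volume, in [0, 1]; bands with
#' zero region volume are reported as NA (undefined), never as 0.
#'
#' @param report a [regional_vessel_volume()] data.frame.
#' @return the report with a `density` column added.
#' @export
regional_vessel_density <- function(report) {
  stopifnot(all(c("band", "region_mm3", "vessel_mm3") %in% names(report)))
  report$density <- ifelse(report$region_mm3 > 0,
                           report$vessel_mm3 / report$region_mm3, NA_real_)
  report
}
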