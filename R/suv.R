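#' Standardized uptake value
#'
#' `SUV = activity / (injected dose / body weight)` with activity in kBq/mL,
#' dose in MBq and weight in g (tissue density taken as 1 g/mL), so a uniform
#' distribution of the dose over the body mass gives SUV 1 everywhere.
#'
#' @param activity_kBq_per_mL numeric array (any shape) of activity
#'   concentration, decay-corrected.
#' @param injected_dose_MBq injected activity (MBq), > 0.
#' @param body_weight_g body weight (g), > 0.
#' @return array of dimensionless SUV, same shape as the input.
#' @export
compute_suv <- function(activity_kBq_per_mL, injected_dose_MBq, body_weight_g) {
  if (injected_dose_MBq <= 0) stop("injected dose must be > 0")
  if (body_weight_g <= 0) stop("body weight must be > 0")
  activity_kBq_per_mL / (injected_dose_MBq * 1000 / body_weight_g)
}

#' Segment the tumor volume of interest at a fraction of peak SUV
#'
#' The peak is the hottest voxel inside the search region; the VOI is the
#' connected component (26-connectivity) containing the peak among voxels
#' whose SUV exceeds `fraction * peak`.
#'
#' @param suv 3D SUV array.
#' @param search_region logical array delimiting where to look (default: the
#'   whole volume).
#' @param fraction threshold fraction of the peak SUV (default 0.30).
#' @return object of class `tumor_voi`: list with `mask`, `peak_suv`,
#'   `peak_index` (voxel), `threshold`, `fraction`.
#' @export
segment_tumor_voi <- function(suv, search_region = NULL, fraction = 0.30) {
  suv <- as_array3(suv)
  if (is.null(search_region)) search_region <- array(TRUE, dim(suv))
  stopifnot(identical(dim(search_region), dim(suv)))
  if (!any(search_region)) stop("search region is empty")
  vals <- suv[search_region]
  peak <- max(vals)
  if (peak <= 0) stop("no peak: SUV is non-positive over the search region")
  peak_lin <- which(search_region & suv == peak)[1]
  thr <- fraction * peak
  cand <- search_region & suv > thr
  lab <- label_components(cand, connectivity = 26)
  mask <- lab == lab[peak_lin]
  structure(list(mask = mask, peak_suv = peak,
                 peak_index = arrayInd(peak_lin, dim(suv))[1, ],
                 threshold = thr, fraction = fraction),
            class = "tumor_voi")
}

#' Image-derived input function from a vessel search region
#'
#' Finds the five-voxel connected cluster with the largest summed early-frame
#' uptake inside `vessel_search_mask` and returns the mean TAC over that
#' cluster as the plasma input, sampled at frame midpoints. The cluster is
#' grown greedily (always absorbing the hottest 26-neighbor) from every
#' candidate seed; ties are broken by the lowest linear voxel index of the
#' seed, which makes the result deterministic.
#'
#' @param dynamic_pet a `dynamic_pet` object (see [simulate_dynamic_pet()]).
#' @param vessel_search_mask logical array with >= 5 voxels.
#' @param early_window_s frames with midpoint within this window define
#'   "early uptake" (default 60 s).
#' @param cluster_size number of voxels in the cluster (default 5).
#' @param max_seeds at most this many hottest voxels are tried as seeds when
#'   the mask is large (deterministic; default 200).
#' @return an [input_function()] with an extra `cluster_voxels` attribute
#'   (linear indices of the selected cluster).
#' @export
extract_input_function <- function(dynamic_pet, vessel_search_mask,
                                   early_window_s = 60, cluster_size = 5,
                                   max_seeds = 200) {
  mask <- as_array3(vessel_search_mask)
  d <- dim(mask)
  idx_mask <- which(mask)
  if (length(idx_mask) < cluster_size)
    stop("vessel search mask has fewer voxels than the cluster size")
  sched <- dynamic_pet$schedule
  mids <- frame_midpoints(sched)
  early <- which(mids <= early_window_s)
  if (!length(early)) early <- 1L
  dat <- dynamic_pet$data
  nf <- dim(dat)[4]
  # summed early-frame uptake per voxel
  evol <- array(0, d)
  for (f in early) evol <- evol + dat[, , , f]

  nbrs <- function(lin) {
    co <- arrayInd(lin, d)
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    nb <- sweep(off, 2, as.integer(co), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
  }

  seeds <- idx_mask[order(-evol[idx_mask], idx_mask)]
  if (length(seeds) > max_seeds) seeds <- seeds[seq_len(max_seeds)]
  seeds <- sort(seeds) # deterministic tie-break: lowest linear index first
  best <- NULL
  for (s in seeds) {
    clust <- s
    repeat {
      if (length(clust) >= cluster_size) break
      cand <- setdiff(unique(unlist(lapply(clust, nbrs))), clust)
      cand <- cand[mask[cand]]
      if (!length(cand)) break
      nxt <- cand[order(-evol[cand], cand)][1]
      clust <- c(clust, nxt)
    }
    if (length(clust) < cluster_size) next
    sc <- sum(evol[clust])
    if (is.null(best) || sc > best$score) best <- list(score = sc, clust = clust)
  }
  if (is.null(best))
    stop("no connected cluster of the requested size found in the mask")
  tac <- vapply(seq_len(nf), function(f) {
    fr <- dat[, , , f]
    mean(fr[best$clust])
  }, numeric(1))
  out <- input_function(mids, pmax(tac, 0))
  attr(out, "cluster_voxels") <- best$clust
  out
}

#' Total lesion glycolysis
#'
#' Mean SUV within the VOI times the VOI volume in mL — identically the
#' voxelwise SUV sum times the voxel volume.
#'
#' @param suv 3D SUV array.
#' @param voi logical VOI mask (non-empty).
#' @param voxel_volume_mL volume of one voxel in mL.
#' @export
tlg <- function(suv, voi, voxel_volume_mL) {
  stopifnot(identical(dim(as_array3(suv)), dim(as_array3(voi))))
  if (!any(voi)) stop("VOI is empty")
  sum(suv[voi]) * voxel_volume_mL
}
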