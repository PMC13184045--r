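#' Spheroid VOI rasterisation
#'
#' Builds a voxel mask for a manually-defined spheroid volume of interest
#' (reference-region VOIs in liver and aortic lumen are drawn this way).
#' A voxel belongs to the VOI iff its center c satisfies
#' sum(((c_i - center_i)/semi_axes_i)^2) <= 1. Voxel centers sit at
#' index * spacing with 0-based indices (identity orientation).
#'
#' @param grid a `voxel_volume` supplying the grid geometry (values unused).
#' @param center numeric length-3, world mm.
#' @param semi_axes numeric length-3, mm; all > 0.
#' @return a `voi_mask`: list with `indices` (n x 3 integer matrix of 1-based
#'   voxel indices), `dim`, `spacing`, `source`.
#' @export
spheroid_voi_mask <- function(grid, center, semi_axes) {
  stopifnot(is_voxel_volume(grid), length(center) == 3L, length(semi_axes) == 3L)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  d <- dim(grid$data)
  sp <- grid$spacing
  # candidate index window bounding the ellipsoid, then exact center test
  lo <- pmax(1L, floor((center - semi_axes) / sp) + 1L)
  hi <- pmin(d, ceiling((center + semi_axes) / sp) + 1L)
  if (any(lo > hi)) stop("spheroid lies entirely outside the grid", call. = FALSE)
  idx <- as.matrix(expand.grid(
    i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3], KEEP.OUT.ATTRS = FALSE
  ))
  centers <- sweep(idx - 1, 2, sp, "*")
  r2 <- rowSums(sweep(sweep(centers, 2, center, "-"), 2, semi_axes, "/")^2)
  keep <- idx[r2 <= 1, , drop = FALSE]
  if (nrow(keep) == 0L) stop("spheroid VOI contains no voxel centers", call. = FALSE)
  new_voi_mask(keep, d, sp, "spheroid")
}

new_voi_mask <- function(indices, dim, spacing, source) {
  storage.mode(indices) <- "integer"
  dimnames(indices) <- NULL
  structure(
    list(indices = indices, dim = as.integer(dim), spacing = as.numeric(spacing),
         source = source),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf(
    "<voi_mask> %d voxels (%.2f ccm), source '%s'\n",
    nrow(x$indices), nrow(x$indices) * prod(x$spacing) / 1000, x$source
  ))
  invisible(x)
}

assert_mask_on_grid <- function(mask, vol) {
  stopifnot(inherits(mask, "voi_mask"), is_voxel_volume(vol))
  if (!identical(mask$dim, dim(vol$data)) ||
      max(abs(mask$spacing - vol$spacing)) > 1e-9) {
    stop("grid mismatch between VOI mask and volume", call. = FALSE)
  }
  invisible(TRUE)
}

#' 41% isocontour VOI around the regional maximum
#'
#' Standard lesion segmentation: let M be the maximum SUV within the search
#' region; the VOI is the 26-connected component containing the max voxel of
#' all region voxels with SUV >= fraction * M (inclusive threshold). The max
#' voxel is always a member.
#'
#' @param vol SUV `voxel_volume`.
#' @param region a `voi_mask` (search region) on the same grid.
#' @param fraction threshold fraction of the regional max, default 0.41.
#' @return a `voi_mask` with source `"isocontour"`.
#' @export
isocontour_voi <- function(vol, region, fraction = 0.41) {
  assert_mask_on_grid(region, vol)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)", call. = FALSE)
  vals <- vol$data[region$indices]
  if (all(vals == 0)) stop("search region is all zero", call. = FALSE)
  m <- max(vals)
  keep <- region$indices[vals >= fraction * m, , drop = FALSE]
  seed <- region$indices[which.max(vals), , drop = FALSE]
  comp <- connected_component_26(keep, seed)
  new_voi_mask(comp, dim(vol$data), vol$spacing, "isocontour")
}

# 26-connected component of `indices` containing `seed` (both 1-based n x 3).
# BFS on a hashed index set; fine for VOI-sized regions.
connected_component_26 <- function(indices, seed) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  inset <- new.env(parent = emptyenv())
  for (k in key(indices)) assign(k, TRUE, envir = inset)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- new.env(parent = emptyenv())
  queue <- list(as.integer(seed[1, ]))
  assign(key(seed), TRUE, envir = visited)
  out <- list()
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    out[[length(out) + 1]] <- v
    nb <- sweep(offs, 2, v, "+")
    for (r in seq_len(nrow(nb))) {
      k <- paste(nb[r, 1], nb[r, 2], nb[r, 3], sep = ",")
      if (!is.null(inset[[k]]) && is.null(visited[[k]])) {
        assign(k, TRUE, envir = visited)
        queue[[length(queue) + 1]] <- as.integer(nb[r, ])
      }
    }
  }
  do.call(rbind, out)
}

#' Copy a VOI to another reconstruction
#'
#' VOIs are defined once on the AC-CT reconstructed PET and copied onto the
#' CE-CT reconstruction rather than re-segmented, so SUVmax is compared within
#' an identical voxel set. The target grid must be identical; the index set is
#' carried over unchanged (no re-thresholding on the target image).
#'
#' @param mask a `voi_mask`.
#' @param target `voxel_volume` supplying the target grid.
#' @return a `voi_mask` on the target grid, source suffixed with `"+copied"`.
#' @export
copy_voi <- function(mask, target) {
  assert_mask_on_grid(mask, target)
  new_voi_mask(mask$indices, mask$dim, mask$spacing, paste0(mask$source, "+copied"))
}

#' SUV statistics within a VOI
#'
#' @param vol SUV `voxel_volume`.
#' @param mask `voi_mask` on the same grid.
#' @param patient_id,unit_id,unit_type,recon bookkeeping fields.
#' @return one-row data.frame: patient_id, unit_id, unit_type, recon, suv_max,
#'   suv_mean, volume_ccm.
#' @export
voi_stats <- function(vol, mask, patient_id = NA_character_, unit_id = NA_character_,
                      unit_type = NA_character_, recon = NA_character_) {
  assert_mask_on_grid(mask, vol)
  vals <- vol$data[mask$indices]
  data.frame(
    patient_id = patient_id, unit_id = unit_id, unit_type = unit_type, recon = recon,
    suv_max = max(vals), suv_mean = mean(vals),
    volume_ccm = nrow(mask$indices) * prod(mask$spacing) / 1000,
    stringsAsFactors = FALSE
  )
}

#' Body-weight SUV from an activity-concentration volume
#'
#' SUV = C[Bq/mL] * weight[g] / injected[Bq]; with C in kBq/mL, weight in kg
#' and injected activity in MBq the unit factors cancel to
#' C * weight / injected.
#'
#' @param vol `voxel_volume` of activity concentration in kBq/mL.
#' @param weight_kg body weight, kg (> 0).
#' @param injected_MBq injected activity, MBq (> 0).
#' @return SUV `voxel_volume`.
#' @export
suv_from_activity <- function(vol, weight_kg, injected_MBq) {
  stopifnot(is_voxel_volume(vol))
  if (!(weight_kg > 0)) stop("weight must be positive", call. = FALSE)
  if (!(injected_MBq > 0)) stop("injected activity must be positive", call. = FALSE)
  if (any(vol$data < 0)) stop("activity concentration must be non-negative", call. = FALSE)
  voxel_volume(vol$data * weight_kg / injected_MBq, spacing = vol$spacing, unit = "suv")
}
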