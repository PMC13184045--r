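#' Bilinear HU-to-mu conversion parameters
#'
#' The standard two-segment (bilinear) conversion from CT numbers to linear
#' attenuation coefficients at 511 keV: below the breakpoint the map is the
#' water-scaled line mu_water * (1000 + HU) / 1000 (clamped at 0); above it a
#' shallower bone slope applies, continuous at the breakpoint. The defaults
#' (water 0.096 cm^-1, breakpoint 0 HU, bone slope 5.1e-5 cm^-1/HU) are
#' conventional textbook values; results downstream depend only on relative mu
#' changes, not on the absolute calibration.
#'
#' @param mu_water_511 mu of water at 511 keV, cm^-1.
#' @param breakpoint HU value where the bone segment starts.
#' @param bone_slope slope above the breakpoint, cm^-1 per HU.
#' @return list of class `hu_to_mu_params`.
#' @export
hu_to_mu_params <- function(mu_water_511 = 0.096, breakpoint = 0, bone_slope = 5.1e-5) {
  stopifnot(mu_water_511 > 0, bone_slope > 0)
  structure(
    list(
      mu_water_511 = mu_water_511,
      breakpoint = breakpoint,
      soft_slope = mu_water_511 / 1000,
      bone_slope = bone_slope
    ),
    class = "hu_to_mu_params"
  )
}

#' Convert a HU volume to a 511 keV attenuation map
#'
#' @param vol a `voxel_volume` with unit `"hu"`.
#' @param params see [hu_to_mu_params()].
#' @return a `voxel_volume` with unit `"mu"` (cm^-1), same grid.
#' @export
hu_to_mu <- function(vol, params = hu_to_mu_params()) {
  stopifnot(is_voxel_volume(vol), inherits(params, "hu_to_mu_params"))
  if (vol$unit != "hu") stop("hu_to_mu expects a volume tagged 'hu'", call. = FALSE)
  hu <- vol$data
  mu_bp <- params$mu_water_511 * (1000 + params$breakpoint) / 1000
  mu <- ifelse(
    hu <= params$breakpoint,
    pmax(0, params$mu_water_511 * (1000 + hu) / 1000),
    mu_bp + params$bone_slope * (hu - params$breakpoint)
  )
  voxel_volume(array(mu, dim = dim(hu)), spacing = vol$spacing, unit = "mu")
}

#' Mean linear attenuation coefficient of a labelled organ
#'
#' Arithmetic mean of the mu-map over the voxels carrying `label` in the organ
#' mask; the clinical analogue is averaging the scanner's attenuation map over
#' a TotalSegmentator organ mask. Maps are averaged unsmoothed.
#'
#' @param mu_vol `voxel_volume`, unit `"mu"`.
#' @param mask `voxel_volume`, unit `"label"`, same grid.
#' @param label integer label selecting the organ.
#' @param organ organ tag recorded in the result (e.g. `"aorta"`).
#' @param patient_id,recon bookkeeping fields for the output row.
#' @return one-row data.frame: patient_id, organ, recon, mean_mu, voxel_count.
#' @export
organ_mean_mu <- function(mu_vol, mask, label, organ = as.character(label),
                          patient_id = NA_character_, recon = NA_character_) {
  stopifnot(is_voxel_volume(mu_vol), is_voxel_volume(mask))
  assert_same_grid(mu_vol, mask)
  if (mu_vol$unit != "mu") stop("organ_mean_mu expects a 'mu' volume", call. = FALSE)
  sel <- mask$data == label
  n <- sum(sel)
  if (n == 0L) stop(sprintf("label %s absent from mask", format(label)), call. = FALSE)
  data.frame(
    patient_id = patient_id, organ = organ, recon = recon,
    mean_mu = mean(mu_vol$data[sel]), voxel_count = as.integer(n),
    stringsAsFactors = FALSE
  )
}

#' Fill missing CE-CT slices from the AC-CT volume
#'
#' CE-CT acquisitions may spare part of the axial range (e.g. the
#' neurocranium); the missing whole slices are replaced by the co-registered
#' AC-CT slices. Slices are indexed along the third (z) axis. Every unflagged
#' voxel is preserved bit-exactly, and the operation is idempotent.
#'
#' @param ce_vol CE volume with missing coverage.
#' @param ac_vol AC volume on the identical grid.
#' @param missing_slices integer vector of z indices (1-based) to replace.
#' @return list: `volume` (completed CE volume) and `replaced` (logical per
#'   slice provenance mask, TRUE where the slice came from AC).
#' @export
infill_missing_slices <- function(ce_vol, ac_vol, missing_slices = integer(0)) {
  stopifnot(is_voxel_volume(ce_vol), is_voxel_volume(ac_vol))
  assert_same_grid(ce_vol, ac_vol)
  nz <- dim(ce_vol$data)[3]
  missing_slices <- as.integer(missing_slices)
  if (anyNA(missing_slices) || any(missing_slices < 1L) || any(missing_slices > nz)) {
    stop("missing_slices must be whole-slice z indices within the grid", call. = FALSE)
  }
  out <- ce_vol$data
  out[, , missing_slices] <- ac_vol$data[, , missing_slices]
  replaced <- rep(FALSE, nz)
  replaced[missing_slices] <- TRUE
  list(
    volume = voxel_volume(out, spacing = ce_vol$spacing, unit = ce_vol$unit),
    replaced = replaced
  )
}

#' Paired per-organ attenuation-change table
#'
#' From a long table of per-(patient, organ, recon) mean attenuation
#' coefficients, computes each patient's percent change 100*(mu_CE -
#' mu_AC)/mu_AC and summarises per organ: the median of per-patient changes
#' (the cohort statistic reported for attenuation bias) together with
#' box-plot summaries (median/Q1/Q3 and whiskers at Q1 - 1.5 IQR and
#' Q3 + 1.5 IQR, clamped to the data range) of the raw mu per reconstruction.
#'
#' @param mu_table data.frame with columns patient_id, organ, recon
#'   (`"AC"`/`"CE"`), mean_mu.
#' @return list: `per_patient` (patient x organ percent changes) and
#'   `per_organ` (one row per organ x recon with box-plot stats plus the
#'   median/min/max percent change and increase counts).
#' @export
mu_change_table <- function(mu_table) {
  required <- c("patient_id", "organ", "recon", "mean_mu")
  if (!all(required %in% names(mu_table))) {
    stop("mu_table must have columns patient_id, organ, recon, mean_mu", call. = FALSE)
  }
  wide <- merge(
    mu_table[mu_table$recon == "AC", c("patient_id", "organ", "mean_mu")],
    mu_table[mu_table$recon == "CE", c("patient_id", "organ", "mean_mu")],
    by = c("patient_id", "organ"), suffixes = c("_AC", "_CE")
  )
  n_ac <- sum(mu_table$recon == "AC")
  n_ce <- sum(mu_table$recon == "CE")
  if (nrow(wide) != n_ac || nrow(wide) != n_ce) {
    stop("unpaired entries: every (patient, organ) needs both AC and CE", call. = FALSE)
  }
  wide$percent_change <- percent_change(wide$mean_mu_AC, wide$mean_mu_CE)

  per_organ <- do.call(rbind, lapply(split(wide, wide$organ), function(w) {
    chg <- w$percent_change
    rows <- lapply(c("AC", "CE"), function(rc) {
      x <- if (rc == "AC") w$mean_mu_AC else w$mean_mu_CE
      bx <- box_stats(x)
      data.frame(
        organ = w$organ[1], recon = rc, n = length(x),
        median = bx$median, q1 = bx$q1, q3 = bx$q3,
        whisker_low = bx$whisker_low, whisker_high = bx$whisker_high,
        median_percent_change = stats::median(chg),
        min_percent_change = min(chg), max_percent_change = max(chg),
        n_increase = sum(chg > 0),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }))
  rownames(per_organ) <- NULL
  list(per_patient = wide, per_organ = per_organ)
}

# Box-plot five numbers with whiskers at Q1 - 1.5 IQR / Q3 + 1.5 IQR,
# clamped to the observed data range. Quantile type 7 (linear interpolation).
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = max(min(x), q[1] - 1.5 * iqr),
    whisker_high = min(max(x), q[3] + 1.5 * iqr)
  )
}
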