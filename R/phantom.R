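#' Phantom geometry specification
#'
#' Geometry of the voxel phantom used in volume mode: a liver ellipsoid, an
#' aortic tube (cylinder along z), a gluteal-muscle slab, an L5-vertebra block
#' and spherical lesions, on a background of soft tissue. Defaults give a
#' 64^3 grid at 4 mm spacing (25.6 cm cube); the default aorta radius was
#' chosen so a reference spheroid VOI inside it has the published ~3 ccm
#' scale.
#'
#' @param dim grid dimensions, default c(64, 64, 64).
#' @param spacing voxel spacing mm, default c(4, 4, 4).
#' @param liver_center,liver_axes ellipsoid center and semi-axes, mm.
#' @param aorta_center_xy,aorta_radius,aorta_z_range cylinder geometry, mm.
#' @param muscle_box,vertebra_box 2x3 matrices (rows = lo, hi corner, mm).
#' @param lesion_centers n x 3 matrix of sphere centers, mm (may be NULL to
#'   auto-place along a diagonal).
#' @param background_suv,background_mu background tissue values.
#' @param noise_sd additive Gaussian noise sigma on the SUV volumes (SUV
#'   units; 0 = noise-free).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(
  dim = c(64, 64, 64), spacing = c(4, 4, 4),
  liver_center = c(76, 92, 140), liver_axes = c(46, 40, 36),
  aorta_center_xy = c(168, 128), aorta_radius = 11, aorta_z_range = c(40, 216),
  muscle_box = rbind(c(8, 8, 8), c(52, 244, 60)),
  vertebra_box = rbind(c(204, 112, 96), c(236, 144, 168)),
  lesion_centers = NULL,
  background_suv = 0.3, background_mu = 0.096,
  noise_sd = 0
) {
  structure(
    list(dim = as.integer(dim), spacing = as.numeric(spacing),
         liver_center = liver_center, liver_axes = liver_axes,
         aorta_center_xy = aorta_center_xy, aorta_radius = aorta_radius,
         aorta_z_range = aorta_z_range,
         muscle_box = muscle_box, vertebra_box = vertebra_box,
         lesion_centers = lesion_centers,
         background_suv = background_suv, background_mu = background_mu,
         noise_sd = noise_sd),
    class = "phantom_spec"
  )
}

# organ label codes used in phantom organ masks
PHANTOM_LABELS <- c(background = 0L, liver = 1L, aorta = 2L, muscle = 3L, vertebra_L5 = 4L)

#' Rasterise a piecewise-constant paired-reconstruction phantom
#'
#' Builds the six volumes of one synthetic patient: SUV and attenuation maps
#' under both reconstructions plus organ and lesion label masks. Values inside
#' each organ are the patient's truth constants (so mask means recover the
#' truth exactly with noise off); the CE volumes are the AC volumes with the
#' organ-specific multiplicative factors applied. Lesions are spheres whose
#' radius is derived from the truth VOI volume.
#'
#' @param patient_values named list per organ (`aorta`, `liver`, `muscle`,
#'   `vertebra_L5`) of lists with `suv_ac`, `suv_factor`, `mu_ac`,
#'   `mu_factor`; optional `lesions` data.frame with columns `suv_ac`,
#'   `suv_factor`, `volume_ccm`.
#' @param spec a [phantom_spec()].
#' @param seed seed for the optional additive noise.
#' @return list: `suv_ac`, `suv_ce`, `mu_ac`, `mu_ce` (`voxel_volume`s),
#'   `organ_mask`, `lesion_mask` (label volumes), `lesion_centers_mm`.
#' @export
generate_phantom <- function(patient_values, spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  sp <- spec$spacing
  ax <- (seq_len(d[1]) - 1) * sp[1]
  ay <- (seq_len(d[2]) - 1) * sp[2]
  az <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(ax, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ay, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(az, each = d[1] * d[2]), dim = d)

  in_liver <- ((X - spec$liver_center[1]) / spec$liver_axes[1])^2 +
    ((Y - spec$liver_center[2]) / spec$liver_axes[2])^2 +
    ((Z - spec$liver_center[3]) / spec$liver_axes[3])^2 <= 1
  in_aorta <- ((X - spec$aorta_center_xy[1])^2 + (Y - spec$aorta_center_xy[2])^2
               <= spec$aorta_radius^2) &
    Z >= spec$aorta_z_range[1] & Z <= spec$aorta_z_range[2]
  in_box <- function(b) {
    X >= b[1, 1] & X <= b[2, 1] & Y >= b[1, 2] & Y <= b[2, 2] & Z >= b[1, 3] & Z <= b[2, 3]
  }
  in_muscle <- in_box(spec$muscle_box)
  in_vertebra <- in_box(spec$vertebra_box)

  organ_sets <- list(liver = in_liver, aorta = in_aorta,
                     muscle = in_muscle, vertebra_L5 = in_vertebra)
  for (i in seq_along(organ_sets)) {
    for (j in seq_along(organ_sets)) {
      if (i < j && any(organ_sets[[i]] & organ_sets[[j]])) {
        stop(sprintf("phantom organs overlap: %s and %s",
                     names(organ_sets)[i], names(organ_sets)[j]), call. = FALSE)
      }
    }
  }

  suv_ac <- array(spec$background_suv, dim = d)
  suv_ce <- array(spec$background_suv, dim = d)
  mu_ac <- array(spec$background_mu, dim = d)
  mu_ce <- array(spec$background_mu, dim = d)
  organ_mask <- array(PHANTOM_LABELS[["background"]], dim = d)

  for (org in names(organ_sets)) {
    pv <- patient_values[[org]]
    if (is.null(pv)) next
    sel <- organ_sets[[org]]
    suv_ac[sel] <- pv$suv_ac
    suv_ce[sel] <- pv$suv_ac * pv$suv_factor
    mu_ac[sel] <- pv$mu_ac
    mu_ce[sel] <- pv$mu_ac * pv$mu_factor
    organ_mask[sel] <- PHANTOM_LABELS[[org]]
  }

  lesion_mask <- array(0L, dim = d)
  centers_mm <- NULL
  lesions <- patient_values$lesions
  if (!is.null(lesions) && nrow(lesions) > 0) {
    nl <- nrow(lesions)
    centers_mm <- spec$lesion_centers
    if (is.null(centers_mm)) {
      # default placement: spaced along the free diagonal band, clear of organs
      t <- seq(0.25, 0.75, length.out = nl)
      centers_mm <- cbind(
        120 + 60 * t, (d[2] - 1) * sp[2] * t, (d[3] - 1) * sp[3] * (1 - t)
      )
    }
    if (nrow(centers_mm) != nl) stop("one center per lesion required", call. = FALSE)
    min_sp <- min(sp)
    for (li in seq_len(nl)) {
      radius <- (3 * lesions$volume_ccm[li] * 1000 / (4 * pi))^(1 / 3)
      if (radius < min_sp) {
        stop("lesion sphere radius smaller than the voxel size", call. = FALSE)
      }
      c0 <- centers_mm[li, ]
      sel <- (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= radius^2
      if (!any(sel)) stop("lesion lies outside the grid", call. = FALSE)
      if (any(organ_mask[sel] != 0L) || any(lesion_mask[sel] != 0L)) {
        stop("lesion overlaps an organ or another lesion", call. = FALSE)
      }
      suv_ac[sel] <- lesions$suv_ac[li]
      suv_ce[sel] <- lesions$suv_ac[li] * lesions$suv_factor[li]
      lesion_mask[sel] <- li
    }
  }

  if (spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    suv_ac <- suv_ac + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
    suv_ce <- suv_ce + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }

  list(
    suv_ac = voxel_volume(suv_ac, sp, "suv"),
    suv_ce = voxel_volume(suv_ce, sp, "suv"),
    mu_ac = voxel_volume(mu_ac, sp, "mu"),
    mu_ce = voxel_volume(mu_ce, sp, "mu"),
    organ_mask = voxel_volume(organ_mask, sp, "label"),
    lesion_mask = voxel_volume(lesion_mask, sp, "label"),
    lesion_centers_mm = centers_mm
  )
}

#' LOR attenuation-bias field (physics mode)
#'
#' Optional first-principles generator mode: for each voxel, the multiplicative
#' SUV bias induced by replacing the AC attenuation map with the CE map is
#' approximated by the mean, over lines of response through the voxel within
#' the scanner's acceptance angle, of exp(line integral of (mu_CE - mu_AC)).
#' The attenuation factor along a LOR is exp(-integral mu dl), so using the
#' higher-mu CE map over-corrects by exactly this exponential of the
#' difference integral. Direction obliquity is measured from the transaxial
#' (xy) plane, as in a cylindrical PET geometry where the ultra-high
#' sensitivity mode accepts LORs up to 52 degrees.
#'
#' Intended for small grids (the oblique-ray integration is O(voxels x
#' directions x steps) in plain R); the default tabular generator applies the
#' calibrated factors directly.
#'
#' @param mu_ac,mu_ce attenuation `voxel_volume`s on a shared grid, cm^-1.
#' @param acceptance_angle maximum obliquity from the transaxial plane,
#'   degrees, in (0, 90].
#' @param n_directions number of LOR directions sampled per voxel (>= 1);
#'   deterministic grid over azimuth x obliquity.
#' @param directions optional n x 3 matrix of explicit unit direction vectors
#'   overriding the sampling (e.g. a single axis).
#' @param step_mm integration step, default half the smallest voxel side.
#' @return unitless bias `voxel_volume` (values >= 1 when mu_CE >= mu_AC
#'   everywhere).
#' @export
lor_bias_field <- function(mu_ac, mu_ce, acceptance_angle = 52, n_directions = 8,
                           directions = NULL, step_mm = NULL) {
  assert_same_grid(mu_ac, mu_ce)
  if (!(acceptance_angle > 0 && acceptance_angle <= 90)) {
    stop("acceptance_angle must be in (0, 90] degrees", call. = FALSE)
  }
  if (is.null(directions)) {
    if (n_directions < 1) stop("n_directions must be >= 1", call. = FALSE)
    directions <- lor_direction_grid(acceptance_angle, n_directions)
  }
  d <- dim(mu_ac$data)
  sp <- mu_ac$spacing
  if (is.null(step_mm)) step_mm <- min(sp) / 2
  dmu <- mu_ce$data - mu_ac$data
  # grid bounding box: voxel extents, centers at (idx-1)*spacing
  lo <- -sp / 2
  hi <- (d - 1) * sp + sp / 2
  bias <- array(NA_real_, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- (c(i, j, k) - 1) * sp
    acc <- 0
    for (r in seq_len(nrow(directions))) {
      u <- directions[r, ]
      tt <- ray_box_range(p, u, lo, hi)
      n_steps <- max(1L, ceiling((tt[2] - tt[1]) / step_mm))
      ts <- tt[1] + (seq_len(n_steps) - 0.5) * (tt[2] - tt[1]) / n_steps
      # nearest-voxel samples of the difference map along the line
      pos <- outer(ts, u)
      idx <- round(sweep(pos, 2, p, "+") / rep(sp, each = n_steps)) + 1
      idx[, 1] <- pmin(pmax(idx[, 1], 1L), d[1])
      idx[, 2] <- pmin(pmax(idx[, 2], 1L), d[2])
      idx[, 3] <- pmin(pmax(idx[, 3], 1L), d[3])
      integral_cm <- sum(dmu[cbind(idx[, 1], idx[, 2], idx[, 3])]) *
        (tt[2] - tt[1]) / n_steps / 10
      acc <- acc + exp(integral_cm)
    }
    bias[i, j, k] <- acc / nrow(directions)
  }
  voxel_volume(bias, sp, "suv")
}

# deterministic direction set: obliquity angles psi (from the xy plane) and
# azimuths phi spread over the acceptance cone; n = n_psi * n_phi >= n_req
lor_direction_grid <- function(acceptance_angle, n_req) {
  n_psi <- max(1L, floor(sqrt(n_req)))
  n_phi <- ceiling(n_req / n_psi)
  psi <- (seq_len(n_psi) - 0.5) / n_psi * acceptance_angle * pi / 180
  phi <- (seq_len(n_phi) - 1) / n_phi * pi
  g <- expand.grid(psi = psi, phi = phi)
  g <- g[seq_len(n_req), , drop = FALSE]
  cbind(
    cos(g$psi) * cos(g$phi),
    cos(g$psi) * sin(g$phi),
    sin(g$psi)
  )
}

# [t_min, t_max] of the full line p + t*u inside the axis-aligned box [lo, hi]
ray_box_range <- function(p, u, lo, hi) {
  tmin <- -Inf
  tmax <- Inf
  for (a in 1:3) {
    if (abs(u[a]) < 1e-12) {
      if (p[a] < lo[a] || p[a] > hi[a]) return(c(0, 0))
    } else {
      t1 <- (lo[a] - p[a]) / u[a]
      t2 <- (hi[a] - p[a]) / u[a]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax <= tmin) return(c(0, 0))
  c(tmin, tmax)
}
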