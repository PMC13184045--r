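#' Generator configuration for the synthetic restaging cohort
#'
#' Calibration constants for the seeded synthetic cohort emulating a 21-patient
#' lymphoma restaging population scanned on a long-axial-FOV PET/CT with both a
#' low-dose attenuation-correction CT (AC) and a contrast-enhanced diagnostic
#' CT (CE) reconstruction. Defaults encode the published cohort structure:
#' organ attenuation-coefficient medians and spreads, reference and lesion
#' SUVmax distributions (log-normal, fitted to median and quartiles), and
#' multiplicative CE/AC bias factors parameterised by their *median* (the
#' cohort statistics of interest are medians of multiplicative changes, and the
#' log-normal median is exp of the log-mean, so medians are exactly
#' controllable).
#'
#' Key bias medians: blood-pool (aorta) SUVmax factor `m_bp` = 1.0878 (+8.78%
#' median intra-patient increase), liver `m_liver` = 1.0786 (+7.86%), lesion
#' marginal `m_lesion` = 1.0580 (+5.80%), aorta attenuation-map factor
#' `m_mu_aorta` = 1.1040 (+10.4%), and the per-lesion blood-pool SUVR ratio
#' factor `r_bp` = 0.9510 (-4.90%).
#'
#' With `lesion_coupling = "suvr"` (default) each lesion's CE/AC factor is its
#' patient's aorta factor times a dedicated SUVR-ratio draw with median
#' `r_bp`, so the per-lesion SUVR change median is controlled directly (median
#' changes do not compose under division, so the three published medians
#' cannot all hold in one multiplicative model; this coupling reproduces the
#' aorta and SUVR medians). `"marginal"` draws lesion factors independently
#' with median `m_lesion` instead.
#'
#' @param n_patients cohort size (default 21).
#' @param n_with_lesions patients with measurable lesions (default 18).
#' @param total_lesions lesions across the cohort (default 66).
#' @param mu_medians_ac,mu_medians_ce named per-organ attenuation-coefficient
#'   medians, cm^-1 (aorta, liver, muscle, vertebra_L5).
#' @param mu_sigma_ac per-organ log-normal sigma of the patient-level AC
#'   attenuation coefficient (from published quartiles).
#' @param mu_factor_medians per-organ median CE/AC attenuation factor.
#' @param mu_factor_sigma per-organ log-normal sigma of that factor.
#' @param ref_suv_quartiles named list per reference organ: c(q1, median, q3)
#'   of SUVmax.
#' @param lesion_suv_quartiles c(q1, median, q3) of lesion SUVmax.
#' @param m_bp,m_liver,m_lesion,m_mu_aorta,r_bp calibration medians, see above.
#' @param suv_factor_medians per-organ median CE/AC SUVmax factor (aorta =
#'   `m_bp`, liver = `m_liver`; muscle/vertebra small).
#' @param suv_factor_sigma per-organ log-normal sigma of the SUV factor.
#' @param suvr_ratio_sigma log-normal sigma of the per-lesion SUVR ratio draw.
#' @param rho_mu_suv per-patient correlation between log attenuation factor
#'   and log SUV factor within an organ (drives the pooled correlation).
#' @param mean_max_ratio per-unit-type SUVmean / SUVmax ratio used to fill
#'   `suv_mean`.
#' @param voi_volume_ccm per-unit-type VOI volumes (ccm); lesion entry is the
#'   median of a log-normal volume distribution.
#' @param weight_median_kg,weight_sigma log-normal body-weight parameters; the
#'   injected activity is 3 MBq/kg.
#' @param truncate_positive if TRUE, every CE/AC SUV and attenuation factor is
#'   truncated to > 1, so every CE value strictly exceeds its AC counterpart.
#' @param lesion_coupling `"suvr"` or `"marginal"`, see above.
#' @param seed master seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
  n_patients = 21, n_with_lesions = 18, total_lesions = 66,
  mu_medians_ac = c(aorta = 0.0992, liver = 0.0998, muscle = 0.0981, vertebra_L5 = 0.1215),
  mu_medians_ce = c(aorta = 0.1091, liver = 0.1044, muscle = 0.0988, vertebra_L5 = 0.1264),
  mu_sigma_ac = c(aorta = 0.0030, liver = 0.0082, muscle = 0.0083, vertebra_L5 = 0.0497),
  mu_factor_medians = c(aorta = 1.1040, liver = 1.0490, muscle = 1.0071, vertebra_L5 = 1.0403),
  mu_factor_sigma = c(aorta = 0.020, liver = 0.010, muscle = 0.003, vertebra_L5 = 0.0235),
  ref_suv_quartiles = list(
    aorta = c(q1 = 1.88, median = 2.21, q3 = 2.41),
    liver = c(q1 = 2.60, median = 2.87, q3 = 3.24),
    muscle = c(q1 = 0.60, median = 0.70, q3 = 0.82),
    vertebra_L5 = c(q1 = 1.50, median = 1.80, q3 = 2.16)
  ),
  lesion_suv_quartiles = c(q1 = 2.53, median = 5.68, q3 = 12.26),
  m_bp = 1.0878, m_liver = 1.0786, m_lesion = 1.0580, m_mu_aorta = 1.1040,
  r_bp = 0.9510,
  suv_factor_medians = c(aorta = m_bp, liver = m_liver, muscle = 1.004, vertebra_L5 = 1.020),
  suv_factor_sigma = c(aorta = 0.030, liver = 0.030, muscle = 0.010, vertebra_L5 = 0.015),
  suvr_ratio_sigma = 0.0375,
  rho_mu_suv = 0.5,
  mean_max_ratio = c(aorta = 0.80, liver = 0.81, muscle = 0.85, vertebra_L5 = 0.85, lesion = 0.65),
  voi_volume_ccm = c(aorta = 3.1, liver = 60.2, muscle = 10, vertebra_L5 = 15, lesion = 5),
  weight_median_kg = 70, weight_sigma = 0.15,
  truncate_positive = FALSE,
  lesion_coupling = c("suvr", "marginal"),
  seed = 1L
) {
  lesion_coupling <- match.arg(lesion_coupling)
  if (n_with_lesions > n_patients) {
    stop("n_with_lesions cannot exceed n_patients", call. = FALSE)
  }
  if (n_patients < 1 || total_lesions < n_with_lesions) {
    stop("invalid cohort counts", call. = FALSE)
  }
  mu_factor_medians["aorta"] <- m_mu_aorta
  suv_factor_medians["aorta"] <- m_bp
  suv_factor_medians["liver"] <- m_liver
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_with_lesions = as.integer(n_with_lesions),
    total_lesions = as.integer(total_lesions),
    mu_medians_ac = mu_medians_ac, mu_medians_ce = mu_medians_ce,
    mu_sigma_ac = mu_sigma_ac,
    mu_factor_medians = mu_factor_medians, mu_factor_sigma = mu_factor_sigma,
    ref_suv_quartiles = ref_suv_quartiles,
    lesion_suv_quartiles = lesion_suv_quartiles,
    m_bp = m_bp, m_liver = m_liver, m_lesion = m_lesion,
    m_mu_aorta = m_mu_aorta, r_bp = r_bp,
    suv_factor_medians = suv_factor_medians, suv_factor_sigma = suv_factor_sigma,
    suvr_ratio_sigma = suvr_ratio_sigma,
    rho_mu_suv = rho_mu_suv,
    mean_max_ratio = mean_max_ratio,
    voi_volume_ccm = voi_volume_ccm,
    weight_median_kg = weight_median_kg, weight_sigma = weight_sigma,
    truncate_positive = isTRUE(truncate_positive),
    lesion_coupling = lesion_coupling,
    seed = as.integer(seed)
  )
  stopifnot(all(unlist(cfg$mu_factor_medians) > 0), all(unlist(cfg$suv_factor_medians) > 0))
  for (q in c(ref_suv_quartiles, list(lesion_suv_quartiles))) {
    stopifnot(q["q1"] < q["median"], q["median"] < q["q3"])
  }
  structure(cfg, class = "generator_config")
}

# log-normal sigma from symmetric quartiles: (log Q3 - log Q1) / (2 * z_.75)
lognorm_sigma_from_quartiles <- function(q) {
  (log(q[["q3"]]) - log(q[["q1"]])) / (2 * stats::qnorm(0.75))
}

#' Draw multiplicative CE/AC bias factors
#'
#' Log-normal draws parameterised by the configured median: log(factor) ~
#' Normal(log M_tissue, sigma^2), so the population median is exactly
#' M_tissue. With `truncate_positive` the draw is conditioned on factor > 1
#' via inverse-CDF truncation. `sigma = 0` degenerates to the constant
#' M_tissue. Uses the current R RNG state (seed upstream).
#'
#' @param tissue one of `"aorta"`, `"liver"`, `"muscle"`, `"vertebra_L5"`,
#'   `"lesion"`, `"suvr_ratio"` (SUV factors; `"lesion"` uses `m_lesion`,
#'   `"suvr_ratio"` uses `r_bp`), or `"mu_<organ>"` for attenuation factors.
#' @param config a `generator_config`.
#' @param n number of draws.
#' @return numeric vector of positive factors.
#' @export
sample_bias_factor <- function(tissue, config, n = 1) {
  stopifnot(inherits(config, "generator_config"))
  if (startsWith(tissue, "mu_")) {
    organ <- sub("^mu_", "", tissue)
    if (!organ %in% names(config$mu_factor_medians)) {
      stop(sprintf("unknown tissue tag '%s'", tissue), call. = FALSE)
    }
    m <- config$mu_factor_medians[[organ]]
    s <- config$mu_factor_sigma[[organ]]
  } else if (tissue == "lesion") {
    m <- config$m_lesion
    s <- sqrt(config$suv_factor_sigma[["aorta"]]^2 + config$suvr_ratio_sigma^2)
  } else if (tissue == "suvr_ratio") {
    m <- config$r_bp
    s <- config$suvr_ratio_sigma
  } else if (tissue %in% names(config$suv_factor_medians)) {
    m <- config$suv_factor_medians[[tissue]]
    s <- config$suv_factor_sigma[[tissue]]
  } else {
    stop(sprintf("unknown tissue tag '%s'", tissue), call. = FALSE)
  }
  rlnorm_median(n, m, s, truncate_at_1 = config$truncate_positive)
}

# log-normal with stated median; optional left truncation at 1 (factor > 1)
# by inverse-CDF sampling so no rejection loop is needed.
rlnorm_median <- function(n, median, sigma, truncate_at_1 = FALSE) {
  if (sigma == 0) {
    if (truncate_at_1 && median <= 1) {
      stop("cannot truncate a degenerate factor <= 1 to be > 1", call. = FALSE)
    }
    return(rep(median, n))
  }
  if (!truncate_at_1) {
    return(exp(stats::rnorm(n, mean = log(median), sd = sigma)))
  }
  p0 <- stats::pnorm(0, mean = log(median), sd = sigma) # P(log f <= 0)
  u <- stats::runif(n, min = p0, max = 1)
  exp(stats::qnorm(u, mean = log(median), sd = sigma))
}

#' Generate a synthetic paired-reconstruction cohort
#'
#' Draws a full cohort (tabular mode): per-patient weights and injected
#' activities (3 MBq/kg), per-organ reference SUVmax and attenuation
#' coefficients under the AC reconstruction, multiplicative CE/AC bias
#' factors, and per-lesion SUVs. Returns both the ground truth (for
#' parameter-recovery tests) and the long measurement table the analysis
#' pipeline consumes. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of class `cohort`: `patients`, `truth` (list with `organs` and
#'   `lesions` data.frames holding drawn factors), `measurements` (long
#'   data.frame: patient_id, unit_id, unit_type, recon, suv_max, suv_mean,
#'   volume_ccm, mu_mean), `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  np <- config$n_patients
  organs <- names(config$mu_medians_ac)
  pid <- sprintf("P%03d", seq_len(np))

  weight <- exp(stats::rnorm(np, log(config$weight_median_kg), config$weight_sigma))
  patients <- data.frame(
    patient_id = pid,
    weight = weight,
    injected_activity = 3 * weight,
    has_lesions = c(rep(TRUE, config$n_with_lesions),
                    rep(FALSE, np - config$n_with_lesions)),
    stringsAsFactors = FALSE
  )

  # per-patient, per-organ truth: AC values and correlated (mu, SUV) factors
  organ_truth <- do.call(rbind, lapply(organs, function(org) {
    qs <- config$ref_suv_quartiles[[org]]
    suv_sigma <- lognorm_sigma_from_quartiles(as.list(qs))
    suv_ac <- exp(stats::rnorm(np, log(qs[["median"]]), suv_sigma))
    mu_ac <- exp(stats::rnorm(np, log(config$mu_medians_ac[[org]]), config$mu_sigma_ac[[org]]))
    z <- stats::rnorm(np)
    w <- stats::rnorm(np)
    rho <- config$rho_mu_suv
    zc <- rho * z + sqrt(1 - rho^2) * w
    mu_factor <- factor_from_z(z, config$mu_factor_medians[[org]],
                               config$mu_factor_sigma[[org]], config$truncate_positive)
    suv_factor <- factor_from_z(zc, config$suv_factor_medians[[org]],
                                config$suv_factor_sigma[[org]], config$truncate_positive)
    data.frame(
      patient_id = pid, organ = org,
      suv_ac = suv_ac, mu_ac = mu_ac,
      mu_factor = mu_factor, suv_factor = suv_factor,
      stringsAsFactors = FALSE
    )
  }))

  # lesions: every lesion-bearing patient gets one, the rest spread at random
  nwl <- config$n_with_lesions
  lesion_truth <- NULL
  if (nwl > 0 && config$total_lesions > 0) {
    extra <- config$total_lesions - nwl
    owners <- c(seq_len(nwl),
                if (extra > 0) sample.int(nwl, extra, replace = TRUE))
    owners <- sort(owners)
    nl <- length(owners)
    lq <- config$lesion_suv_quartiles
    lesion_sigma <- lognorm_sigma_from_quartiles(as.list(lq))
    suv_ac <- exp(stats::rnorm(nl, log(lq[["median"]]), lesion_sigma))
    aorta_rows <- organ_truth[organ_truth$organ == "aorta", ]
    aorta_factor <- aorta_rows$suv_factor[match(pid[owners], aorta_rows$patient_id)]
    if (config$lesion_coupling == "suvr") {
      ratio <- sample_ratio_conditional(aorta_factor, config)
      lesion_factor <- aorta_factor * ratio
    } else {
      lesion_factor <- sample_bias_factor("lesion", config, nl)
      ratio <- lesion_factor / aorta_factor
    }
    vol_med <- config$voi_volume_ccm[["lesion"]]
    volume <- exp(stats::rnorm(nl, log(vol_med), 0.6))
    lesion_truth <- data.frame(
      lesion_id = sprintf("L%03d", seq_len(nl)),
      patient_id = pid[owners],
      suv_ac = suv_ac, suv_factor = lesion_factor, suvr_ratio = ratio,
      volume_ccm = volume,
      stringsAsFactors = FALSE
    )
  }

  measurements <- build_measurement_table(patients, organ_truth, lesion_truth, config)
  structure(
    list(patients = patients,
         truth = list(organs = organ_truth, lesions = lesion_truth),
         measurements = measurements,
         config = config),
    class = "cohort"
  )
}

# map standard-normal draws to a median-M log-normal factor; under truncation
# the normal quantile is squeezed into the admissible upper tail so that the
# per-draw correlation structure with the shared z is preserved.
factor_from_z <- function(z, median, sigma, truncate_at_1) {
  if (sigma == 0) return(rep(median, length(z)))
  if (!truncate_at_1) return(exp(log(median) + sigma * z))
  p0 <- stats::pnorm(0, mean = log(median), sd = sigma)
  u <- p0 + stats::pnorm(z) * (1 - p0)
  exp(stats::qnorm(u, mean = log(median), sd = sigma))
}

# SUVR ratio draw conditioned, under truncate_positive, on the lesion's total
# factor (aorta_factor * ratio) staying > 1.
sample_ratio_conditional <- function(aorta_factor, config) {
  n <- length(aorta_factor)
  if (!config$truncate_positive) {
    return(rlnorm_median(n, config$r_bp, config$suvr_ratio_sigma))
  }
  s <- config$suvr_ratio_sigma
  if (s == 0) stop("truncate_positive with zero ratio dispersion is infeasible", call. = FALSE)
  lo <- stats::pnorm(-log(aorta_factor), mean = log(config$r_bp), sd = s)
  u <- stats::runif(n, min = lo, max = 1)
  exp(stats::qnorm(u, mean = log(config$r_bp), sd = s))
}

build_measurement_table <- function(patients, organ_truth, lesion_truth, config) {
  rows <- list()
  mm <- config$mean_max_ratio
  for (r in seq_len(nrow(organ_truth))) {
    o <- organ_truth[r, ]
    vol <- config$voi_volume_ccm[[o$organ]]
    for (recon in c("AC", "CE")) {
      f_suv <- if (recon == "AC") 1 else o$suv_factor
      f_mu <- if (recon == "AC") 1 else o$mu_factor
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = o$patient_id, unit_id = paste0(o$patient_id, "_", o$organ),
        unit_type = o$organ, recon = recon,
        suv_max = o$suv_ac * f_suv,
        suv_mean = o$suv_ac * f_suv * mm[[o$organ]],
        volume_ccm = vol,
        mu_mean = o$mu_ac * f_mu,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(lesion_truth)) {
    for (r in seq_len(nrow(lesion_truth))) {
      l <- lesion_truth[r, ]
      for (recon in c("AC", "CE")) {
        f <- if (recon == "AC") 1 else l$suv_factor
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = l$patient_id, unit_id = l$lesion_id,
          unit_type = "lesion", recon = recon,
          suv_max = l$suv_ac * f,
          suv_mean = l$suv_ac * f * mm[["lesion"]],
          volume_ccm = l$volume_ccm,
          mu_mean = NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
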