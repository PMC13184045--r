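#' SUV ratio
#'
#' Ratio of lesion SUV to a reference-region SUV (blood pool = aortic lumen,
#' or liver). Vectorised.
#'
#' @param lesion_suv lesion SUV value(s).
#' @param reference_suv reference SUV value(s), > 0.
#' @return ratio(s).
#' @export
suvr <- function(lesion_suv, reference_suv) {
  if (any(!(reference_suv > 0))) stop("reference SUV must be positive", call. = FALSE)
  lesion_suv / reference_suv
}

#' Rule-based Deauville score from SUV ratios
#'
#' The threshold rule on measured ratios: score 2 if SUVR_aorta <= 1; score 3
#' if SUVR_aorta > 1 and SUVR_liver <= 1; score 4 if SUVR_liver > 1. The
#' boundary value 1.0 maps to the lower score. Scores 1 and 5 require
#' comparison to a prior examination and are never emitted. The liver clause
#' takes precedence as written, so the (rare) combination SUVR_aorta <= 1 with
#' SUVR_liver > 1 (possible only when the liver SUV is below the blood pool)
#' yields 4. Vectorised.
#'
#' @param suvr_aorta,suvr_liver positive ratios.
#' @return integer score(s) in {2, 3, 4}.
#' @export
deauville_score <- function(suvr_aorta, suvr_liver) {
  if (any(!(suvr_aorta > 0)) || any(!(suvr_liver > 0))) {
    stop("SUV ratios must be positive", call. = FALSE)
  }
  ifelse(suvr_liver > 1, 4L, ifelse(suvr_aorta > 1, 3L, 2L))
}

#' Ordinary least squares fit of SUVR_AC on SUVR_CE
#'
#' The regression underlying the misclassification model: the AC-based ratio
#' (the ground-truth-role reading) regressed on the observed CE-based ratio,
#' because the clinical question is "given the CE-based reading, what was the
#' AC-based class". Returns the design summaries needed for prediction
#' intervals.
#'
#' @param suvr_ce predictor (observed CE-based SUVR), n >= 3, non-constant.
#' @param suvr_ac response (AC-based SUVR).
#' @return list of class `suvr_fit`: intercept `a`, slope `b`, residual SD `s`
#'   (denominator n - 2), `n`, predictor mean `x_bar`, predictor sum of
#'   squares `s_xx`.
#' @export
fit_suvr_regression <- function(suvr_ce, suvr_ac) {
  n <- length(suvr_ce)
  if (n != length(suvr_ac)) stop("unpaired input lengths", call. = FALSE)
  if (n < 3L) stop("need n >= 3 pairs", call. = FALSE)
  s_xx <- sum((suvr_ce - mean(suvr_ce))^2)
  if (s_xx == 0) stop("constant predictor: degenerate design", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, suvr_ce), suvr_ac)
  a <- unname(fit$coefficients[1])
  b <- unname(fit$coefficients[2])
  s <- sqrt(sum(fit$residuals^2) / (n - 2))
  structure(
    list(a = a, b = b, s = s, n = n, x_bar = mean(suvr_ce), s_xx = s_xx),
    class = "suvr_fit"
  )
}

#' @export
print.suvr_fit <- function(x, ...) {
  cat(sprintf("<suvr_fit> SUVR_AC = %.4f + %.4f * SUVR_CE, residual SD %.4f (n = %d)\n",
              x$a, x$b, x$s, x$n))
  invisible(x)
}

#' Predictive distribution of the AC-based SUVR given an observed CE-based SUVR
#'
#' Gaussian prediction-interval form: mean a + b*r and standard deviation
#' s * sqrt(1 + 1/n + (r - x_bar)^2 / S_xx). The prediction (not confidence)
#' band is used because the question concerns a single new lesion, not the
#' mean response; the `interval` switch exposes the confidence-band
#' alternative.
#'
#' @param fit a `suvr_fit`.
#' @param r observed SUVR_CE value(s).
#' @param interval `"prediction"` (default) or `"confidence"`.
#' @return list: `mean`, `sd` (vectors along `r`).
#' @export
prediction_distribution <- function(fit, r, interval = c("prediction", "confidence")) {
  stopifnot(inherits(fit, "suvr_fit"))
  interval <- match.arg(interval)
  lev <- 1 / fit$n + (r - fit$x_bar)^2 / fit$s_xx
  if (interval == "prediction") lev <- 1 + lev
  list(mean = fit$a + fit$b * r, sd = fit$s * sqrt(lev))
}

#' Probability of a Deauville misclassification at an observed SUVR
#'
#' For an observed CE-based ratio r on one side of the decision threshold
#' (1 by the scoring rule), the probability that the AC-based ratio lay on the
#' other side, under the Gaussian predictive distribution of the fit: for
#' r > threshold a *false upgrade* (true AC reading was <= threshold); for
#' r < threshold a *false downgrade* (true AC reading was > threshold).
#' Degenerate fits (s = 0) return a deterministic 0/1, and are undefined at
#' mean exactly equal to the threshold. Vectorised over `r`.
#'
#' @param fit a `suvr_fit`.
#' @param r observed SUVR_CE, must differ from `threshold`.
#' @param threshold decision threshold, default 1.
#' @param interval see [prediction_distribution()].
#' @return probability vector in [0, 1].
#' @export
misclassification_probability <- function(fit, r, threshold = 1,
                                          interval = c("prediction", "confidence")) {
  stopifnot(inherits(fit, "suvr_fit"))
  interval <- match.arg(interval)
  if (any(r == threshold)) stop("r must differ from the threshold", call. = FALSE)
  pd <- prediction_distribution(fit, r, interval)
  out <- numeric(length(r))
  zero_sd <- pd$sd == 0
  if (any(zero_sd & pd$mean == threshold)) {
    stop("undefined: zero predictive sd with mean exactly at the threshold", call. = FALSE)
  }
  up <- r > threshold
  # false upgrade: P(AC <= threshold); false downgrade: P(AC > threshold)
  out[up] <- stats::pnorm(threshold, pd$mean[up], pmax(pd$sd[up], .Machine$double.xmin))
  out[!up] <- stats::pnorm(threshold, pd$mean[!up], pmax(pd$sd[!up], .Machine$double.xmin),
                           lower.tail = FALSE)
  if (any(zero_sd)) {
    out[zero_sd & up] <- as.numeric(pd$mean[zero_sd & up] <= threshold)
    out[zero_sd & !up] <- as.numeric(pd$mean[zero_sd & !up] > threshold)
  }
  out
}

#' Misclassification risk flag
#'
#' TRUE when the misclassification probability at the observed ratio exceeds
#' `alpha` (default 5%), the band of ratios within which a CE-based reading
#' should not be trusted for scoring.
#'
#' @inheritParams misclassification_probability
#' @param alpha risk tolerance, default 0.05.
#' @return logical vector.
#' @export
risk_flag <- function(fit, r, alpha = 0.05, threshold = 1) {
  misclassification_probability(fit, r, threshold) > alpha
}

#' Risk curve over a grid of observed SUVRs
#'
#' Evaluates the false-upgrade / false-downgrade probability on a grid of
#' observed CE-based ratios around the threshold (the data behind the risk
#' figure: upgrade branch for r > 1, downgrade branch for r < 1).
#'
#' @param fit a `suvr_fit`.
#' @param r_grid grid of observed SUVR_CE values (threshold value excluded
#'   automatically).
#' @param threshold decision threshold, default 1.
#' @return data.frame: r, outcome (`"upgrade"`/`"downgrade"`), probability.
#' @export
risk_curve <- function(fit, r_grid = seq(0.5, 2, by = 0.01), threshold = 1) {
  r_grid <- r_grid[r_grid != threshold]
  data.frame(
    r = r_grid,
    outcome = ifelse(r_grid > threshold, "upgrade", "downgrade"),
    probability = misclassification_probability(fit, r_grid, threshold),
    stringsAsFactors = FALSE
  )
}

#' Cross-tabulate Deauville scores between reconstructions
#'
#' Assigns each lesion its rule-based score under both reconstructions and
#' tabulates agreement: the score_AC x score_CE contingency table plus the
#' list of lesions whose score changed, with direction.
#'
#' @param suvr_table data.frame with columns lesion_id, recon (`"AC"`/`"CE"`),
#'   suvr_aorta, suvr_liver; every lesion must appear under both recons.
#' @return list: `table` (3x3 score contingency matrix, rows = AC), `changes`
#'   (data.frame lesion_id, score_ac, score_ce, direction), `n_upgraded`,
#'   `n_downgraded`.
#' @export
score_change_table <- function(suvr_table) {
  need <- c("lesion_id", "recon", "suvr_aorta", "suvr_liver")
  if (!all(need %in% names(suvr_table))) {
    stop("suvr_table needs columns lesion_id, recon, suvr_aorta, suvr_liver", call. = FALSE)
  }
  ac <- suvr_table[suvr_table$recon == "AC", ]
  ce <- suvr_table[suvr_table$recon == "CE", ]
  m <- merge(ac, ce, by = "lesion_id", suffixes = c("_ac", "_ce"))
  if (nrow(m) != nrow(ac) || nrow(m) != nrow(ce)) {
    stop("every lesion needs both an AC and a CE record", call. = FALSE)
  }
  score_ac <- deauville_score(m$suvr_aorta_ac, m$suvr_liver_ac)
  score_ce <- deauville_score(m$suvr_aorta_ce, m$suvr_liver_ce)
  tab <- table(factor(score_ac, levels = 2:4), factor(score_ce, levels = 2:4))
  dimnames(tab) <- list(score_ac = 2:4, score_ce = 2:4)
  changed <- score_ac != score_ce
  changes <- data.frame(
    lesion_id = m$lesion_id[changed],
    score_ac = score_ac[changed], score_ce = score_ce[changed],
    direction = ifelse(score_ce[changed] > score_ac[changed], "upgrade", "downgrade"),
    stringsAsFactors = FALSE
  )
  list(
    table = tab, changes = changes,
    n_upgraded = sum(score_ce > score_ac),
    n_downgraded = sum(score_ce < score_ac)
  )
}

#' Build the per-lesion SUVR table from a measurement table
#'
#' Joins each lesion measurement with its patient's reference-organ
#' measurements under the same reconstruction and computes SUVR_aorta and
#' SUVR_liver. The denominator is the reference SUVmax by default; the
#' `"max_mean"` mode divides lesion SUVmax by reference SUVmean (a common
#' re-analysis convention).
#'
#' @param measurements long table as produced by [generate_cohort()]
#'   (columns patient_id, unit_id, unit_type, recon, suv_max, suv_mean).
#' @param reference_metric `"max_max"` (default) or `"max_mean"`.
#' @return data.frame: lesion_id, patient_id, recon, suvr_aorta, suvr_liver.
#' @export
suvr_table <- function(measurements, reference_metric = c("max_max", "max_mean")) {
  reference_metric <- match.arg(reference_metric)
  ref_col <- if (reference_metric == "max_max") "suv_max" else "suv_mean"
  les <- measurements[measurements$unit_type == "lesion", ]
  if (nrow(les) == 0L) stop("no lesion rows in measurement table", call. = FALSE)
  out <- les[, c("unit_id", "patient_id", "recon", "suv_max")]
  names(out)[1] <- "lesion_id"
  for (org in c("aorta", "liver")) {
    ref <- measurements[measurements$unit_type == org, c("patient_id", "recon", ref_col)]
    names(ref)[3] <- "ref_suv"
    out <- merge(out, ref, by = c("patient_id", "recon"), sort = FALSE)
    out[[paste0("suvr_", org)]] <- suvr(out$suv_max, out$ref_suv)
    out$ref_suv <- NULL
  }
  out[order(out$lesion_id, out$recon), c("lesion_id", "patient_id", "recon",
                                         "suvr_aorta", "suvr_liver")]
}
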