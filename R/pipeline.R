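#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> measure -> stats -> deauville into one
#' reproducible run: generates (or accepts) a cohort, computes the per-organ
#' attenuation-change table, the paired SUV summaries, the SUVR table with
#' rule-based scores, the regressions per reference organ with risk curves,
#' and the attenuation-vs-SUV change correlations. Identical config + seed
#' yields byte-identical output tables.
#'
#' @param config a [generator_config()]; ignored when `cohort` is supplied.
#' @param cohort optionally a pre-generated `cohort` object.
#' @param out_dir if non-NULL, write every table as CSV/JSON under this
#'   directory (created if needed) plus a manifest recording seed and config.
#' @param alternative Wilcoxon alternative for the increase tests.
#' @param wilcoxon_method `"auto"` (default), `"exact"` or `"normal"`.
#' @param reference_metric SUVR denominator mode, see [suvr_table()].
#' @param risk_alpha risk-flag threshold, default 0.05.
#' @return list of class `pipeline_result`: `mu` (per-organ attenuation
#'   summary), `suv` (per-unit-type paired SUV summary), `suvr` (per-lesion
#'   ratios + scores), `suvr_change` (paired SUVR summaries per reference),
#'   `fits`, `risk_curves`, `score_changes`, `correlations`, `cohort`.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL, out_dir = NULL,
                         alternative = "greater",
                         wilcoxon_method = c("auto", "exact", "normal"),
                         reference_metric = c("max_max", "max_mean"),
                         risk_alpha = 0.05) {
  wilcoxon_method <- match.arg(wilcoxon_method)
  reference_metric <- match.arg(reference_metric)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  meas <- cohort$measurements

  # attenuation-change table (reference + control organs)
  mu_rows <- meas[!is.na(meas$mu_mean), c("patient_id", "unit_type", "recon", "mu_mean")]
  names(mu_rows) <- c("patient_id", "organ", "recon", "mean_mu")
  mu_res <- mu_change_table(mu_rows)

  # paired SUVmax summaries per unit type
  suv_summaries <- list()
  for (ut in unique(meas$unit_type)) {
    sub <- meas[meas$unit_type == ut, ]
    wide <- merge(
      sub[sub$recon == "AC", c("unit_id", "suv_max")],
      sub[sub$recon == "CE", c("unit_id", "suv_max")],
      by = "unit_id", suffixes = c("_ac", "_ce")
    )
    ps <- paired_summary(wide$suv_max_ac, wide$suv_max_ce,
                         alternative = alternative, method = wilcoxon_method)
    suv_summaries[[ut]] <- cbind(unit_type = ut, ps$change,
                                 median_ac = ps$per_arm$median[1],
                                 median_ce = ps$per_arm$median[2],
                                 mad_ac = ps$per_arm$mad[1],
                                 mad_ce = ps$per_arm$mad[2])
  }
  suv_table_out <- do.call(rbind, suv_summaries)
  rownames(suv_table_out) <- NULL

  # SUVR, Deauville scores, regression + risk per reference organ
  has_lesions <- any(meas$unit_type == "lesion")
  suvr_tab <- NULL; fits <- list(); curves <- list(); score_changes <- NULL
  suvr_change <- NULL
  if (has_lesions) {
    suvr_tab <- suvr_table(meas, reference_metric)
    suvr_tab$score <- deauville_score(suvr_tab$suvr_aorta, suvr_tab$suvr_liver)
    wide <- merge(
      suvr_tab[suvr_tab$recon == "AC", c("lesion_id", "suvr_aorta", "suvr_liver")],
      suvr_tab[suvr_tab$recon == "CE", c("lesion_id", "suvr_aorta", "suvr_liver")],
      by = "lesion_id", suffixes = c("_ac", "_ce")
    )
    chg <- list()
    for (org in c("aorta", "liver")) {
      x_ac <- wide[[paste0("suvr_", org, "_ac")]]
      x_ce <- wide[[paste0("suvr_", org, "_ce")]]
      ps <- paired_summary(x_ac, x_ce, alternative = "less", method = wilcoxon_method)
      chg[[org]] <- cbind(reference = org, ps$change,
                          n_decrease = ps$change$n - ps$change$n_increase,
                          median_ac = ps$per_arm$median[1],
                          median_ce = ps$per_arm$median[2])
      fits[[org]] <- fit_suvr_regression(x_ce, x_ac)
      cv <- risk_curve(fits[[org]])
      cv$reference <- org
      cv$flagged <- cv$probability > risk_alpha
      curves[[org]] <- cv
    }
    suvr_change <- do.call(rbind, chg)
    rownames(suvr_change) <- NULL
    score_changes <- score_change_table(suvr_tab)
  }

  # correlation of percent changes: d(mu)% vs d(SUVmax)% per organ and pooled
  correlations <- NULL
  pp <- mu_res$per_patient
  suv_wide <- merge(
    meas[meas$recon == "AC" & !is.na(meas$mu_mean),
         c("patient_id", "unit_type", "suv_max")],
    meas[meas$recon == "CE" & !is.na(meas$mu_mean),
         c("patient_id", "unit_type", "suv_max")],
    by = c("patient_id", "unit_type"), suffixes = c("_ac", "_ce")
  )
  suv_wide$suv_change <- percent_change(suv_wide$suv_max_ac, suv_wide$suv_max_ce)
  both <- merge(pp, suv_wide, by.x = c("patient_id", "organ"),
                by.y = c("patient_id", "unit_type"))
  groups <- c(as.list(unique(both$organ)), list("pooled"))
  correlations <- do.call(rbind, lapply(groups, function(g) {
    sub <- if (identical(g, "pooled")) both else both[both$organ == g, ]
    res <- lapply(c("pearson", "spearman"), function(mth) {
      ct <- correlation(sub$percent_change, sub$suv_change, method = mth)
      data.frame(tissue = if (identical(g, "pooled")) "pooled" else g,
                 method = mth, coefficient = ct$coefficient, p = ct$p,
                 n = nrow(sub), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }))

  result <- structure(
    list(mu = mu_res$per_organ, mu_per_patient = mu_res$per_patient,
         suv = suv_table_out, suvr = suvr_tab, suvr_change = suvr_change,
         fits = fits, risk_curves = if (length(curves)) do.call(rbind, curves) else NULL,
         score_changes = score_changes, correlations = correlations,
         cohort = cohort),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  cohort: %d patients, %d lesions\n",
              nrow(x$cohort$patients),
              if (is.null(x$cohort$truth$lesions)) 0L else nrow(x$cohort$truth$lesions)))
  aor <- x$suv[x$suv$unit_type == "aorta", ]
  if (nrow(aor)) {
    cat(sprintf("  aorta SUVmax: median change %+.2f%% (increase in %d/%d), Wilcoxon p = %.2g\n",
                aor$median_percent_change, aor$n_increase, aor$n, aor$wilcoxon_p))
  }
  if (!is.null(x$score_changes)) {
    cat(sprintf("  Deauville changes: %d upgraded, %d downgraded\n",
                x$score_changes$n_upgraded, x$score_changes$n_downgraded))
  }
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Emits the analogue tables as CSV (attenuation, SUV, SUVR, correlations,
#' risk curves, score changes) plus fit summaries and a manifest (seed,
#' package version, config echo, config hash) as JSON.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir` invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(result$mu, "mu_table.csv")
  wr(result$mu_per_patient, "mu_per_patient.csv")
  wr(result$suv, "suv_table.csv")
  wr(result$suvr, "suvr_table.csv")
  wr(result$suvr_change, "suvr_change_table.csv")
  wr(result$correlations, "correlation_table.csv")
  wr(result$risk_curves, "risk_curves.csv")
  wr(result$cohort$measurements, "measurements.csv")
  if (!is.null(result$score_changes)) {
    wr(result$score_changes$changes, "score_changes.csv")
  }
  fits <- lapply(result$fits, unclass)
  cfg <- result$cohort$config
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("suvshift")),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    fits = fits,
    tables = c("mu_table.csv", "mu_per_patient.csv", "suv_table.csv",
               "suvr_table.csv", "suvr_change_table.csv", "correlation_table.csv",
               "risk_curves.csv", "measurements.csv", "score_changes.csv"),
    schema_version = "1"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# order-stable hash of the configuration (no digest dependency): sum of a
# simple rolling hash over the deparsed config text
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%d", h)
}

#' Read a generator configuration from JSON
#'
#' Companion to the CLI: reads a JSON file whose fields override
#' [generator_config()] defaults (unknown fields are rejected).
#'
#' @param path JSON file path.
#' @param seed optional seed overriding the file's.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(generator_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config fields: %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in c("mu_medians_ac", "mu_medians_ce", "mu_sigma_ac", "mu_factor_medians",
               "mu_factor_sigma", "suv_factor_medians", "suv_factor_sigma",
               "mean_max_ratio", "voi_volume_ccm", "lesion_suv_quartiles")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$ref_suv_quartiles)) {
    raw$ref_suv_quartiles <- lapply(raw$ref_suv_quartiles, unlist)
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(generator_config, raw)
}
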