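#' @title End-to-end pipeline
#' @description
#' One reproducible run: simulate a cohort (or load one from CSV), apply
#' the selection cascade and episode extraction, run the dosing-pattern,
#' comparative, post hoc, logistic and trajectory analyses, and write the
#' full set of machine-readable outputs plus a Markdown report and a run
#' manifest with content digests.
#' @name fever-pipeline
NULL

welch_block <- function(eps, var) {
  a <- eps[[var]][eps$antipyretic_flag]
  b <- eps[[var]][!eps$antipyretic_flag]
  if (length(a) < 2 || length(b) < 2) return(NULL)
  w <- welch_t_test(a, b)
  list(variable = var, mean_antipyretic = w$mean_a, sd_antipyretic = w$sd_a,
       mean_no_antipyretic = w$mean_b, sd_no_antipyretic = w$sd_b,
       mean_diff = w$mean_diff, t = w$t, df = w$df, p = w$p)
}

#' Run the full postvaccination fever pipeline
#'
#' Simulates a seeded cohort, writes the three record streams, applies the
#' cascade, and emits: `episodes.csv`, `cascade.json`, `fig_dose.json`
#' (dose timing and temperature-at-dose), `tables.json` (cohort summary,
#' antipyretic contrasts, ANOVA + Levene + Dunnett T3, logistic + VIF),
#' `fig_trajectory.json` (binned trajectories and decay fits), `report.md`
#' and `manifest.json`. Outputs are byte-identical across runs with the
#' same seed and configuration.
#'
#' @param out_dir Output directory.
#' @param n_children Cohort size to simulate.
#' @param seed Integer seed.
#' @param config A [fever_config()].
#' @param kinetics,policy Generator settings (see [default_kinetics()],
#'   [caregiver_policy()]).
#' @param cohort Optional pre-built `fever_cohort` (or list with
#'   `readings`, `events`, `doses`); skips simulation.
#' @return Invisibly, a list with the `fever_records` object and every
#'   analysis result.
#' @export
run_fever_pipeline <- function(out_dir, n_children = 3000, seed = 1,
                               config = fever_config(),
                               kinetics = default_kinetics(),
                               policy = caregiver_policy(),
                               cohort = NULL) {
  config <- as_fever_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(n_children, kinetics, policy, seed = seed)
  }
  paths <- write_records(cohort$readings, cohort$events, cohort$doses,
                         out_dir)

  fr <- apply_cascade(cohort$readings, cohort$events, cohort$doses, config)
  eps <- fr$episodes
  utils::write.csv(
    eps[c("child_id", "vaccine", "onset_h", "offset_h", "duration_h",
          "tmax_c", "onset_censored", "antipyretic_flag")],
    file.path(out_dir, "episodes.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(fr$cascade),
                       file.path(out_dir, "cascade.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- list(records = fr, summary = summarize_cohort(fr))

  if (nrow(fr$doses) > 0) {
    res$dose_timing <- first_dose_timing(fr)
    res$dose_temps <- temperature_at_dose(fr)
    jsonlite::write_json(list(
      first_dose_hour_counts = res$dose_timing$counts,
      first_dose_cumulative = res$dose_timing$cumulative,
      temp_bins = as.list(res$dose_temps$bin_counts),
      frac_at_or_above_threshold =
        res$dose_temps$frac_at_or_above_threshold,
      frac_below_37 = res$dose_temps$frac_below_37,
      frac_above_40 = res$dose_temps$frac_above_40,
      n_unlocatable = res$dose_temps$n_unlocatable
    ), file.path(out_dir, "fig_dose.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  tables <- list(cohort_summary = as.data.frame(res$summary))
  if (nrow(eps) > 0 && length(unique(eps$antipyretic_flag)) == 2) {
    tables$antipyretic_contrasts <- Filter(Negate(is.null), lapply(
      c("onset_h", "offset_h", "duration_h", "tmax_c"),
      function(v) welch_block(eps, v)))
    res$contrasts <- tables$antipyretic_contrasts
  }
  if (length(unique(eps$vaccine)) >= 3) {
    for (v in c("tmax_c", "duration_h")) {
      an <- oneway_anova_levene(eps[[v]], eps$vaccine)
      t3 <- dunnett_t3(eps[[v]], eps$vaccine, config$alpha)
      key <- if (v == "tmax_c") "max_temperature" else "duration"
      tables[[paste0("anova_", key)]] <- list(
        f = an$f, df_between = an$df_between, df_within = an$df_within,
        p = an$p, levene_f = an$levene_f, levene_p = an$levene_p,
        per_group = an$per_group, dunnett_t3 = t3$table,
        partition = t3$partition)
      res[[paste0("anova_", key)]] <- an
      res[[paste0("dunnett_", key)]] <- t3
    }
  }
  hf <- high_fever_data(fr)
  if (nrow(hf) > 0) {
    tmax_ok <- !is.na(hf$tmax_c)
    hi <- hf$tmax_c >= config$high_fever_threshold
    if (sum(hi[tmax_ok]) > 0 && sum(!hi[tmax_ok]) > 0) {
      res$logistic <- fit_high_fever_logistic(hf, config)
      tables$high_fever_logistic <- list(
        coefficients = res$logistic$coefficients,
        vif = as.data.frame(res$logistic$vif),
        n = res$logistic$n, n_events = res$logistic$n_events)
    }
  }
  jsonlite::write_json(tables, file.path(out_dir, "tables.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (nrow(eps) > 0) {
    res$trajectory <- align_and_bin(fr, by = "both")
    traj_anti <- align_and_bin(fr, by = "antipyretic")
    decays <- lapply(unique(traj_anti$group), function(g) {
      fd <- tryCatch(fit_decay(traj_anti, group = g),
                     error = function(e) NULL)
      if (is.null(fd)) return(NULL)
      list(group = g, slope = fd$slope, intercept = fd$intercept,
           r_squared = fd$r_squared, n_bins = fd$n_bins)
    })
    res$decay <- Filter(Negate(is.null), decays)
    jsonlite::write_json(list(
      bins = as.data.frame(res$trajectory), decay_fits = res$decay),
      file.path(out_dir, "fig_trajectory.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }

  write_report_md(file.path(out_dir, "report.md"), res, config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("feverpattern")),
    seed = seed, n_children = nrow(cohort$events),
    config = unclass(config),
    input_digests = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

write_report_md <- function(path, res, config) {
  fr <- res$records
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Postvaccination fever analysis report")
  w("")
  w("## Selection cascade")
  cc <- fr$cascade
  for (nm in names(cc)) w("- %s: %d", gsub("_", " ", nm), cc[[nm]])
  w("")
  w("## Cohort characteristics")
  s <- as.data.frame(res$summary)
  if (nrow(s) > 0) {
    w("| vaccine | records | antipyretic %% | age mean (SD) | reading temp mean (SD) |")
    w("|---|---|---|---|---|")
    for (i in seq_len(nrow(s))) {
      w("| %s | %d | %.1f | %.1f (%.1f) | %.2f (%.2f) |", s$vaccine[i],
        s$n_records[i], s$antipyretic_pct[i], s$age_mean[i], s$age_sd[i],
        s$temp_mean[i], s$temp_sd[i])
    }
  }
  w("")
  if (!is.null(res$dose_timing)) {
    w("## Antipyretic administration pattern")
    w("- first dose within 1 h: %.2f%%", 100 * res$dose_timing$cumulative[1])
    w("- first dose within 10 h: %.2f%%",
      100 * res$dose_timing$cumulative[10])
    w("- doses at or above %.1f °C: %.2f%%", config$fever_threshold,
      100 * res$dose_temps$frac_at_or_above_threshold)
    w("")
  }
  if (!is.null(res$contrasts)) {
    w("## Antipyretic vs no-antipyretic contrasts (Welch)")
    w("| variable | antipyretic mean (SD) | none mean (SD) | t | p |")
    w("|---|---|---|---|---|")
    for (ct in res$contrasts) {
      w("| %s | %.2f (%.2f) | %.2f (%.2f) | %.2f | %.3g |", ct$variable,
        ct$mean_antipyretic, ct$sd_antipyretic, ct$mean_no_antipyretic,
        ct$sd_no_antipyretic, ct$t, ct$p)
    }
    w("")
  }
  for (key in c("max_temperature", "duration")) {
    an <- res[[paste0("anova_", key)]]
    t3 <- res[[paste0("dunnett_", key)]]
    if (is.null(an)) next
    w("## ANOVA across vaccines: %s", gsub("_", " ", key))
    w("- F(%d, %d) = %.1f, p = %.3g; Levene p = %.3g", an$df_between,
      an$df_within, an$f, an$p, an$levene_p)
    w("- Dunnett T3 grouping (decreasing mean): %s",
      paste(vapply(t3$partition, paste, "", collapse = ", "),
            collapse = " > "))
    w("")
  }
  if (!is.null(res$logistic)) {
    w("## High-fever logistic regression (Tmax >= %.1f °C)",
      config$high_fever_threshold)
    co <- res$logistic$coefficients
    w("| predictor | B (SE) | p | adjusted OR (95%% CI) |")
    w("|---|---|---|---|")
    for (i in seq_len(nrow(co))) {
      w("| %s | %.3f (%.3f) | %.3g | %.3f (%.3f-%.3f) |", co$predictor[i],
        co$B[i], co$SE[i], co$p[i], co$or[i], co$or_lo[i], co$or_hi[i])
    }
    v <- as.data.frame(res$logistic$vif)
    w("- VIF: %s", paste(sprintf("%s %.2f", v$predictor, v$vif),
                         collapse = ", "))
    w("")
  }
  if (!is.null(res$decay)) {
    w("## Onset-aligned trajectory decay fits")
    for (d in res$decay) {
      w("- %s: slope %.3f °C/h, R² = %.2f", d$group, d$slope, d$r_squared)
    }
  }
}
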