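#' Run the full genome-instability pipeline on a synthetic cohort
#'
#' Stages, in order: cohort simulation, microsatellite typing, broad
#' copy-number calling, BCNA scoring, LB/HB classification of MSS samples
#' at the first quartile, tumor-group versus normal expression contrasts
#' with DEG cross-classification, and histology composition summaries.
#' Deterministic given the configuration; every threshold actually used is
#' recorded in the returned report (and logged when `verbose`).
#'
#' Expression contrasts use the *computed* genome-instability classes
#' (MSI from the panel, LB/HB from the scores), not the generator's
#' ground-truth labels, so classification errors propagate honestly.
#'
#' @param config a `pipeline_config`
#' @param verbose log stage progress and thresholds via `message()`
#' @return list of class `cohort_report`: `scorecards`, `threshold` (Q1),
#'   `group_summary`, `group_sizes`, `msi`, `calls`, `arm_frequency`,
#'   `contrasts`, `deg_categories`, `deg_counts`, `composition`,
#'   `parameters`, `ground_truth`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  log_ <- function(...) if (verbose) message(...)
  th <- config$thresholds
  log_("thresholds: gain > ", th$upper_autosome, ", loss < ",
       th$lower_autosome, " (male X/Y ", th$upper_male_xy, "/",
       th$lower_male_xy, "), min run ", th$min_run_markers,
       " markers, max gap ", th$max_intersegment_distance,
       " bp, min arm fraction ", th$min_arm_fraction,
       "; MSI >= ", config$msi_threshold,
       "; FC cut ", config$fc_cut, ", FDR cut ", config$fdr_cut)

  sim_cfg <- simulation_config(markers_per_mb = config$markers_per_mb,
                               noise_sd = config$noise_sd,
                               seed = config$seed,
                               group_sizes = config$group_sizes,
                               expr_noise_sd = config$expr_noise_sd)
  arms <- make_default_genome()
  log_("simulating cohort (seed ", config$seed, ")")
  cohort <- simulate_cohort(sim_cfg, arms)

  log_("typing microsatellite instability")
  msi <- msi_type_cohort(cohort$msi_panel, config$msi_threshold)
  msi_status <- stats::setNames(msi$status, msi$sample_id)

  log_("calling broad copy number aberrations in ",
       length(cohort$tracks), " tracks")
  calls <- lapply(cohort$tracks, call_bcnas, arms = arms, thresholds = th)

  log_("scoring (", config$scoring_system, " system)")
  sc <- score_cohort(calls, arms, msi_status,
                     system = config$scoring_system,
                     quantile_type = config$quantile_type)
  cards <- sc$scorecards
  if (!any(cards$msi_status == "MSS"))
    warning("no MSS samples; LB/HB classification skipped")
  log_("first-quartile threshold: ", sc$threshold)

  # expression groups: computed classes for tumors, Normal for the rest
  gi <- stats::setNames(cards$gi_class, cards$sample_id)
  groups <- cohort$expression$groups
  tumors <- names(groups)[names(groups) %in% names(gi)]
  groups[tumors] <- gi[tumors]
  usable <- groups %in% c("HB", "LB", "MSI", "Normal") &
    !is.na(groups)
  study <- expression_study(
    cohort$expression$expr[, usable, drop = FALSE],
    cohort$expression$annotation, groups[usable])

  log_("filtering genes and contrasting groups vs normal")
  study <- filter_study(study)
  contrasts <- contrast_all(study)
  degs <- classify_degs(contrasts, config$fc_cut, config$fdr_cut)
  deg_counts <- as.data.frame(table(direction = degs$direction,
                                    category = degs$category),
                              stringsAsFactors = FALSE)
  deg_counts <- deg_counts[deg_counts$Freq > 0 &
                             deg_counts$category != "unassigned", ]

  labels <- merge(cohort$labels, cards[, c("sample_id", "gi_class")],
                  by = "sample_id", all.x = TRUE)
  composition <- list(
    histology = composition_summary(labels[!is.na(labels$gi_class), ],
                                    group_col = "gi_class",
                                    label_col = "histology"),
    site = composition_summary(labels[!is.na(labels$gi_class), ],
                               group_col = "gi_class",
                               label_col = "site"))

  report <- structure(list(
    scorecards = cards,
    threshold = sc$threshold,
    group_summary = summarize_groups(cards),
    group_sizes = as.list(table(cards$gi_class)),
    msi = msi,
    calls = calls,
    arm_frequency = arm_event_frequency(calls),
    contrasts = contrasts,
    deg_categories = degs,
    deg_counts = deg_counts,
    composition = composition,
    parameters = list(thresholds = unclass(th),
                      scoring_system = config$scoring_system,
                      quantile_type = config$quantile_type,
                      msi_threshold = config$msi_threshold,
                      fc_cut = config$fc_cut, fdr_cut = config$fdr_cut,
                      seed = config$seed),
    ground_truth = cohort$ground_truth), class = "cohort_report")

  if (!is.null(config$out_dir)) {
    log_("writing stage outputs to ", config$out_dir)
    write_report(report, cohort, arms, config$out_dir)
  }
  report
}

#' Write every stage output of a pipeline run
#'
#' Emits the marker tracks, arm definitions, MSI table, SEG-style calls,
#' scorecards, expression tables, contrasts, DEG categories and a JSON
#' cohort report into `out_dir`. Each file is re-loadable with the
#' matching `read_*` function, and re-running downstream stages from the
#' intermediates reproduces the end-to-end run.
#'
#' @param report a `cohort_report`
#' @param cohort the simulated cohort that produced it
#' @param arms arm-definition table
#' @param out_dir output directory (created if absent)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, cohort, arms, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_tracks_tsv(cohort$tracks, fp("marker_tracks.tsv"))
  write_arms_bed(arms, fp("arms.bed"))
  utils::write.table(cohort$msi_panel, fp("msi_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$msi, fp("msi_status.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seg(report$calls, fp("bcna_calls.seg"))
  utils::write.table(report$scorecards, fp("scorecards.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$arm_frequency, fp("arm_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_tsv(cohort$expression, fp("expression.tsv"),
                       fp("annotation.tsv"), fp("groups.tsv"))
  utils::write.table(report$contrasts, fp("contrasts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$deg_categories, fp("deg_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort_report_json(report), fp("cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Condense a cohort report for JSON serialisation
#' @param report a `cohort_report`
#' @return plain list (group sizes, score summaries, Q1 threshold,
#'   arm-event frequencies, DEG category counts, parameters)
#' @export
cohort_report_json <- function(report) {
  list(group_sizes = report$group_sizes,
       score_summary = report$group_summary,
       q1_threshold = report$threshold,
       arm_event_frequency = report$arm_frequency,
       deg_counts = report$deg_counts,
       parameters = report$parameters)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Genome-instability cohort report\n")
  cat("  samples:",
      paste(sprintf("%s=%d", names(x$group_sizes),
                    unlist(x$group_sizes)), collapse = ", "), "\n")
  cat("  MSS first-quartile (Q1) threshold:", x$threshold, "\n")
  cat("  BCNA score by class:\n")
  print(x$group_summary, row.names = FALSE)
  if (nrow(x$deg_counts)) {
    cat("  DEG categories (", sum(x$deg_counts$Freq), " genes):\n",
        sep = "")
    print(x$deg_counts, row.names = FALSE)
  }
  invisible(x)
}
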