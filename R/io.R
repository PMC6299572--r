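# On-disk formats. Marker tracks, SEG-style calls and expression tables are
# plain TSV with 1-based inclusive coordinates; the arm table is BED-like
# (0-based half-open) on disk and converted explicitly on read/write.

#' Write marker tracks as TSV
#'
#' Columns: sample_id, sex, marker_id, chromosome, position, log2ratio.
#' Calibrated values and arm assignments are derived, not stored.
#'
#' @param tracks a single marker track or a list of them
#' @param path output file
#' @export
write_tracks_tsv <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  all <- do.call(rbind, tracks)
  utils::write.table(all[, c("sample_id", "sex", "marker_id", "chromosome",
                             "position", "log2ratio")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read marker tracks from TSV
#'
#' Recomputes calibrated values and arm assignments on load.
#'
#' @param path track TSV ([write_tracks_tsv()])
#' @param arms arm-definition table
#' @return named list of marker tracks, one per sample
#' @export
read_tracks_tsv <- function(path, arms) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chromosome = "character"))
  x$calibrated_value <- calibrate_log2ratio(x$log2ratio)
  x$arm <- assign_arms(x$chromosome, x$position, arms)
  out <- split(x, x$sample_id)
  lapply(out, function(t) {
    t <- t[order(match(t$chromosome, unique(arms$chromosome)),
                 t$position), ]
    rownames(t) <- NULL
    t
  })
}

#' Write arm definitions as BED-like TSV (0-based half-open)
#' @param arms arm-definition table (1-based inclusive, in memory)
#' @param path output file
#' @export
write_arms_bed <- function(arms, path) {
  bed <- data.frame(chromosome = arms$chromosome,
                    start = arms$start_bp - 1L, end = arms$end_bp,
                    arm = arms$arm, acrocentric = arms$acrocentric)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a BED-like arm-definition TSV (0-based half-open) to 1-based
#' @param path arm BED file ([write_arms_bed()])
#' @return arm-definition table, 1-based inclusive
#' @export
read_arms_bed <- function(path) {
  bed <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chromosome = "character"))
  arms <- data.frame(chromosome = bed$chromosome, arm = bed$arm,
                     start_bp = bed$start + 1L, end_bp = bed$end,
                     acrocentric = bed$acrocentric,
                     stringsAsFactors = FALSE)
  validate_arms(arms)
  arms
}

#' Write BCNA calls as SEG-style TSV (1-based inclusive)
#' @param calls call data.frame or named list of per-sample call tables
#' @param path output file
#' @export
write_seg <- function(calls, path) {
  if (!is.data.frame(calls)) calls <- do.call(rbind, calls)
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a SEG-style call TSV
#' @param path SEG file ([write_seg()])
#' @return named list of per-sample call tables
#' @export
read_seg <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chromosome = "character"))
  out <- split(x, x$sample_id)
  lapply(out, function(t) { rownames(t) <- NULL; t })
}

#' Write an expression study as three TSV files
#' @param study an `expression_study`
#' @param expr_path,anno_path,groups_path output files
#' @export
write_expression_tsv <- function(study, expr_path, anno_path, groups_path) {
  utils::write.table(data.frame(gene = rownames(study$expr), study$expr,
                                check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$annotation, anno_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(study$groups),
                                group = unname(study$groups)),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read an expression study from three TSV files
#' @param expr_path,anno_path,groups_path files from
#'   [write_expression_tsv()]
#' @return an `expression_study`
#' @export
read_expression_tsv <- function(expr_path, anno_path, groups_path) {
  ex <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex$gene
  anno <- utils::read.delim(anno_path, stringsAsFactors = FALSE)
  gr <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_study(m, anno, stats::setNames(gr$group, gr$sample_id))
}

#' Pipeline configuration
#'
#' Every numeric default is the published value where one exists
#' (calibrated thresholds 2.21/1.74 and 1.24/0.81, 50-marker isosegments,
#' 25\% arm fraction, 30\% MSI threshold, FC cut 2, FDR cut 0.05). The
#' configuration round-trips losslessly through YAML
#' ([write_config()]/[read_config()]).
#'
#' @param seed integer seed for the synthetic cohort
#' @param group_sizes cohort composition (see [simulation_config()])
#' @param markers_per_mb,noise_sd,expr_noise_sd generator knobs
#' @param thresholds a `calling_thresholds`
#' @param scoring_system "pqw" or "pq"
#' @param quantile_type quartile estimator for LB/HB classification
#' @param msi_threshold inclusive MSI fraction threshold
#' @param fc_cut,fdr_cut DEG thresholds
#' @param out_dir optional output directory for stage files
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            group_sizes = c(HB = 21L, LB = 7L, MSI = 5L,
                                            Normal = 25L),
                            markers_per_mb = 10, noise_sd = 0.1,
                            expr_noise_sd = 0.3,
                            thresholds = default_thresholds(),
                            scoring_system = "pqw", quantile_type = 7,
                            msi_threshold = 0.30,
                            fc_cut = 2, fdr_cut = 0.05,
                            out_dir = NULL) {
  stopifnot(scoring_system %in% c("pqw", "pq"),
            msi_threshold > 0, msi_threshold <= 1,
            fc_cut > 0, fdr_cut > 0, fdr_cut < 1)
  structure(list(seed = as.integer(seed), group_sizes = group_sizes,
                 markers_per_mb = markers_per_mb, noise_sd = noise_sd,
                 expr_noise_sd = expr_noise_sd, thresholds = thresholds,
                 scoring_system = scoring_system,
                 quantile_type = quantile_type,
                 msi_threshold = msi_threshold,
                 fc_cut = fc_cut, fdr_cut = fdr_cut, out_dir = out_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`
#' @param path output file
#' @export
write_config <- function(config, path) {
  flat <- unclass(config)
  flat$thresholds <- unclass(flat$thresholds)
  flat$group_sizes <- as.list(flat$group_sizes)
  yaml::write_yaml(flat, path)
}

#' Read and validate a pipeline configuration from YAML
#' @param path YAML file from [write_config()]
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("seed", "group_sizes", "markers_per_mb", "noise_sd",
            "expr_noise_sd", "thresholds", "scoring_system",
            "quantile_type", "msi_threshold", "fc_cut", "fdr_cut")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  pipeline_config(seed = y$seed,
                  group_sizes = unlist(y$group_sizes),
                  markers_per_mb = y$markers_per_mb,
                  noise_sd = y$noise_sd, expr_noise_sd = y$expr_noise_sd,
                  thresholds = do.call(default_thresholds, y$thresholds),
                  scoring_system = y$scoring_system,
                  quantile_type = y$quantile_type,
                  msi_threshold = y$msi_threshold,
                  fc_cut = y$fc_cut, fdr_cut = y$fdr_cut,
                  out_dir = y$out_dir)
}
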