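#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. All randomness is
#' governed by `seed`: two runs with identical configuration are
#' bit-identical.
#'
#' @param markers_per_mb marker density; default 10 (one marker per 100 kb,
#'   roughly 30k markers genome-wide), dense enough that any event covering
#'   more than a quarter of an arm comfortably exceeds the 50-contiguous-
#'   marker rule.
#' @param noise_sd standard deviation of per-marker Gaussian noise on the
#'   log2-ratio scale.
#' @param seed integer random seed.
#' @param group_sizes named integer vector with entries HB, LB, MSI and
#'   Normal (sample counts per group).
#' @param expression_effects data.frame of per-gene per-group log2 shifts
#'   (columns `gene`, `effect_HB`, `effect_LB`, `effect_MSI`); defaults to
#'   [default_expression_effects()].
#' @param expr_noise_sd standard deviation of expression noise (log2 scale).
#' @return a list of class `sim_config`
#' @export
simulation_config <- function(markers_per_mb = 10,
                              noise_sd = 0.1,
                              seed = 1L,
                              group_sizes = c(HB = 21L, LB = 7L,
                                              MSI = 5L, Normal = 25L),
                              expression_effects = default_expression_effects(),
                              expr_noise_sd = 0.3) {
  stopifnot(markers_per_mb > 0, noise_sd >= 0, expr_noise_sd >= 0)
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  structure(list(markers_per_mb = markers_per_mb,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 group_sizes = group_sizes,
                 expression_effects = expression_effects,
                 expr_noise_sd = expr_noise_sd),
            class = "sim_config")
}

#' Cohort configuration matching the published series
#'
#' 33 tumor samples (21 high-BCNA, 7 low-BCNA, 5 MSI) and 25 normal
#' tissue samples.
#'
#' @param seed integer random seed
#' @param ... further arguments to [simulation_config()]
#' @return a `sim_config`
#' @export
published_cohort_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed,
                    group_sizes = c(HB = 21L, LB = 7L, MSI = 5L,
                                    Normal = 25L), ...)
}

#' Build an implanted-event table
#'
#' @param chromosome chromosome label(s)
#' @param arm_or_whole "p", "q" or "w" (whole chromosome)
#' @param type "gain" or "loss"
#' @param arm_fraction fraction of the arm covered, in (0, 1]
#' @param magnitude target calibrated copy-number value inside the event
#'   (3 for a one-copy gain, 1 for a one-copy loss on the diploid scale)
#' @return data.frame of events
#' @export
bcna_event <- function(chromosome, arm_or_whole, type,
                       arm_fraction = 1,
                       magnitude = ifelse(type == "gain", 3, 1)) {
  n <- length(chromosome)
  arm_fraction <- rep_len(arm_fraction, n)
  magnitude <- rep_len(magnitude, n)
  ev <- data.frame(chromosome = as.character(chromosome),
                   arm_or_whole = arm_or_whole, type = type,
                   arm_fraction = arm_fraction, magnitude = magnitude,
                   stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

validate_events <- function(events) {
  if (nrow(events) == 0L) return(invisible(events))
  stopifnot(all(events$type %in% c("gain", "loss")),
            all(events$arm_or_whole %in% c("p", "q", "w")))
  if (any(events$arm_fraction <= 0 | events$arm_fraction > 1))
    stop("arm_fraction must lie in (0, 1]")
  # implants must be recoverable in the noiseless limit
  bad_gain <- events$type == "gain" & events$magnitude <= 2.21
  bad_loss <- events$type == "loss" & events$magnitude >= 1.74
  if (any(bad_gain | bad_loss))
    stop("event magnitude must exceed the calling threshold ",
         "(> 2.21 for gains, < 1.74 for losses)")
  invisible(events)
}

#' Simulate one marker-level copy-number track
#'
#' Places markers at the configured density along every arm, draws Gaussian
#' log2-ratio noise around the diploid baseline (log2 ratio 0, calibrated
#' value 2), and shifts markers inside each implanted event so that the
#' expected calibrated value equals the event magnitude. Noise acts on the
#' log2 scale and is then transformed to the calibrated scale, mirroring
#' how array log2 ratios behave.
#'
#' @param genome arm-definition table ([make_default_genome()])
#' @param events data.frame of implanted events ([bcna_event()]); may have
#'   zero rows
#' @param config a `sim_config`; `markers_per_mb` and `noise_sd` are used
#' @param sample_id sample label
#' @param sex "male", "female" or "unknown"; females carry no Y markers
#' @param use_seed if TRUE (default), seed the generator from
#'   `config$seed`; set FALSE when calling inside an outer seeded stream
#' @return a marker-track data.frame: `sample_id`, `sex`, `marker_id`,
#'   `chromosome`, `position`, `log2ratio`, `calibrated_value`, `arm`
#' @export
simulate_marker_track <- function(genome, events, config,
                                  sample_id = "S1", sex = "female",
                                  use_seed = TRUE) {
  validate_arms(genome)
  validate_events(events)
  if (use_seed) set.seed(config$seed)
  if (sex == "female") genome <- genome[genome$chromosome != "Y", ]

  step <- 1e6 / config$markers_per_mb
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    pos <- seq(genome$start_bp[i], genome$end_bp[i], by = step)
    data.frame(chromosome = genome$chromosome[i], position = pos,
               arm = genome$arm[i], stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, pieces)
  ord <- order(match(mk$chromosome, unique(genome$chromosome)), mk$position)
  mk <- mk[ord, ]
  mk$log2ratio <- stats::rnorm(nrow(mk), 0, config$noise_sd)

  if (nrow(events) > 0) {
    for (j in seq_len(nrow(events))) {
      ev <- events[j, ]
      arms_hit <- if (ev$arm_or_whole == "w") {
        genome[genome$chromosome == ev$chromosome, , drop = FALSE]
      } else {
        genome[genome$chromosome == ev$chromosome &
                 genome$arm == ev$arm_or_whole, , drop = FALSE]
      }
      if (nrow(arms_hit) == 0L)
        stop("event ", j, ": chromosome ", ev$chromosome, " arm '",
             ev$arm_or_whole, "' is not present in the genome definition")
      shift <- log2(ev$magnitude / 2)
      for (k in seq_len(nrow(arms_hit))) {
        span_len <- (arms_hit$end_bp[k] - arms_hit$start_bp[k] + 1) *
          ev$arm_fraction
        lo <- arms_hit$start_bp[k]
        hi <- lo + span_len - 1
        sel <- mk$chromosome == ev$chromosome & mk$arm == arms_hit$arm[k] &
          mk$position >= lo & mk$position <= hi
        mk$log2ratio[sel] <- mk$log2ratio[sel] + shift
      }
    }
  }

  mk$calibrated_value <- calibrate_log2ratio(mk$log2ratio)
  mk$marker_id <- sprintf("mk_%s_%d", mk$chromosome, mk$position)
  mk$sample_id <- sample_id
  mk$sex <- sex
  rownames(mk) <- NULL
  mk[, c("sample_id", "sex", "marker_id", "chromosome", "position",
         "log2ratio", "calibrated_value", "arm")]
}

#' Default per-gene group expression effects
#'
#' A gene panel with known differential-expression ground truth: for each
#' of the seven up-regulated and seven down-regulated specific/shared
#' categories (HB, LB, MSI, HB+LB, LB+MSI, HB+MSI, HB+LB+MSI) there are
#' `genes_per_category` genes with a log2 shift of +/- `effect` in the
#' affected group(s); the remaining `n_null` genes carry no effect.
#'
#' @param genes_per_category genes per truth category (default 12)
#' @param n_null unaffected genes (default 300)
#' @param effect absolute log2 shift in affected groups (default 2,
#'   i.e. a linear fold change of 4, well clear of the FC = 2 cut)
#' @return data.frame: `gene`, `truth_category`, `truth_direction`,
#'   `effect_HB`, `effect_LB`, `effect_MSI`
#' @export
default_expression_effects <- function(genes_per_category = 12,
                                       n_null = 300, effect = 2) {
  cats <- c("HB", "LB", "MSI", "HB+LB", "LB+MSI", "HB+MSI", "HB+LB+MSI")
  rows <- list()
  idx <- 1L
  for (dir in c("up", "down")) {
    sgn <- if (dir == "up") 1 else -1
    for (cat in cats) {
      members <- strsplit(cat, "+", fixed = TRUE)[[1]]
      for (g in seq_len(genes_per_category)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("GENE%04d", idx),
          truth_category = cat, truth_direction = dir,
          effect_HB = sgn * effect * ("HB" %in% members),
          effect_LB = sgn * effect * ("LB" %in% members),
          effect_MSI = sgn * effect * ("MSI" %in% members),
          stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
  }
  null <- data.frame(gene = sprintf("GENE%04d", seq(idx, idx + n_null - 1L)),
                     truth_category = "none", truth_direction = "none",
                     effect_HB = 0, effect_LB = 0, effect_MSI = 0,
                     stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), null)
  rownames(out) <- NULL
  out
}

msi_panel_markers <- function() {
  c("D2S123", "D5S346", "D17S250", "BAT25", "BAT26", "BAT40")
}

# per-group histology/site draws; the published cohort's counts are used as
# sampling weights so any group size yields a realistic mix
.histology_probs <- list(
  LB  = c(mucinous = 3, mucinous_features = 2, signet_ring = 1, NOS = 1),
  HB  = c(mucinous = 3, mucinous_features = 2, signet_ring = 1, NOS = 15),
  MSI = c(mucinous = 1, mucinous_features = 2, signet_ring = 0, NOS = 2))
.site_probs <- list(
  LB  = c(proximal = 3, distal = 2, rectum = 2),
  HB  = c(proximal = 10, distal = 9, rectum = 2),
  MSI = c(proximal = 4, distal = 1, rectum = 0))

#' Simulate a full cohort with known ground truth
#'
#' Generates, under one seed: a marker track per tumor sample with
#' implanted broad gains/losses (LB samples carry 0-5 events, HB samples
#' 6 or more, MSI samples few), a six-marker microsatellite panel (MSI
#' samples have at least 2/6 unstable markers), histology and site labels,
#' and a gene x sample log2 expression matrix (normal baseline + group
#' effects + Gaussian noise) for all tumor and normal samples. The ground
#' truth records every implant and label, including the expected BCNA
#' score per sample under both scoring systems.
#'
#' @param config a `sim_config`; [published_cohort_config()] reproduces the
#'   published cohort composition (33 tumors: 21 HB, 7 LB, 5 MSI; 25
#'   normals)
#' @param genome arm-definition table; default [make_default_genome()]
#' @return list with elements `tracks` (named list of marker tracks, tumors
#'   only), `msi_panel` (sample x marker calls), `labels` (sample, group,
#'   histology, site), `expression` (an expression study; see
#'   [expression_study()]) and `ground_truth` (list: `events`, `scores`)
#' @export
simulate_cohort <- function(config, genome = make_default_genome()) {
  if (sum(config$group_sizes) == 0L) stop("all group sizes are zero")
  set.seed(config$seed)
  sizes <- config$group_sizes
  groups <- rep(names(sizes), sizes)
  ids <- sprintf("%s_%02d", groups, unlist(lapply(sizes, seq_len)))
  tumor <- groups != "Normal"

  # --- implanted copy-number events per tumor sample ---
  autosomes <- as.character(1:22)
  acro <- c("13", "14", "15", "21", "22")
  all_events <- list()
  truth_scores <- data.frame(sample_id = ids, group = groups,
                             n_events = 0L, score_pqw = 0L, score_pq = 0L,
                             stringsAsFactors = FALSE)
  tracks <- list()
  for (i in which(tumor)) {
    n_ev <- switch(groups[i],
                   LB  = sample(0:5, 1, prob = c(4, 4, 3, 2, 1, 1)),
                   HB  = sample(6:21, 1, prob = stats::dnorm(6:21, 13, 4.7)),
                   MSI = sample(0:5, 1, prob = c(1, 2, 3, 2, 1, 0.5)))
    evs <- NULL
    if (n_ev > 0) {
      chroms <- sample(autosomes, n_ev)
      whole <- stats::runif(n_ev) < 0.5 & !(chroms %in% acro)
      arm_choice <- ifelse(chroms %in% acro, "q",
                           sample(c("p", "q"), n_ev, replace = TRUE))
      type <- sample(c("gain", "loss"), n_ev, replace = TRUE)
      evs <- bcna_event(chromosome = chroms,
                        arm_or_whole = ifelse(whole, "w", arm_choice),
                        type = type,
                        arm_fraction = ifelse(whole, 1,
                                              stats::runif(n_ev, 0.35, 1)))
      evs$sample_id <- ids[i]
      all_events[[length(all_events) + 1L]] <- evs
    }
    truth_scores$n_events[truth_scores$sample_id == ids[i]] <- n_ev
    truth_scores$score_pqw[truth_scores$sample_id == ids[i]] <- n_ev
    n_w <- if (is.null(evs)) 0L else sum(evs$arm_or_whole == "w")
    truth_scores$score_pq[truth_scores$sample_id == ids[i]] <- n_ev + n_w
    ev_in <- if (is.null(evs)) bcna_event(character(), character(),
                                          character()) else evs
    tracks[[ids[i]]] <- simulate_marker_track(genome, ev_in, config,
                                              sample_id = ids[i],
                                              sex = "female",
                                              use_seed = FALSE)
  }
  events_df <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(chromosome = character(), arm_or_whole = character(),
               type = character(), arm_fraction = numeric(),
               magnitude = numeric(), sample_id = character(),
               stringsAsFactors = FALSE)

  # --- microsatellite panel (tumors only) ---
  markers <- msi_panel_markers()
  panel <- NULL
  if (any(tumor)) {
    calls <- t(vapply(which(tumor), function(i) {
      n_unst <- if (groups[i] == "MSI") sample(2:6, 1, prob = c(3, 3, 2, 1, 1))
                else sample(0:1, 1, prob = c(5, 1))
      out <- rep("stable", 6L)
      out[sample(6L, n_unst)] <- "unstable"
      out
    }, character(6)))
    panel <- data.frame(sample_id = ids[tumor], calls,
                        stringsAsFactors = FALSE)
    names(panel) <- c("sample_id", markers)
  }

  # --- histology and site labels (tumors only) ---
  labels <- data.frame(sample_id = ids, group = groups,
                       histology = NA_character_, site = NA_character_,
                       stringsAsFactors = FALSE)
  for (g in c("LB", "HB", "MSI")) {
    sel <- labels$group == g
    n <- sum(sel)
    if (n == 0) next
    hp <- .histology_probs[[g]]
    sp <- .site_probs[[g]]
    labels$histology[sel] <- sample(names(hp), n, replace = TRUE, prob = hp)
    labels$site[sel] <- sample(names(sp), n, replace = TRUE, prob = sp)
  }

  # --- expression matrix: baseline + group effects + noise ---
  eff <- config$expression_effects
  n_genes <- nrow(eff)
  baseline <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
  expr <- matrix(stats::rnorm(n_genes * length(ids), 0, config$expr_noise_sd),
                 nrow = n_genes)
  expr <- expr + baseline
  for (g in c("HB", "LB", "MSI")) {
    cols <- which(groups == g)
    if (length(cols))
      expr[, cols] <- expr[, cols] + eff[[paste0("effect_", g)]]
  }
  dimnames(expr) <- list(eff$gene, ids)
  anno <- data.frame(symbol = eff$gene,
                     description = "simulated protein coding gene",
                     chromosome = paste0("chr", sample(1:22, n_genes,
                                                      replace = TRUE)),
                     stringsAsFactors = FALSE)
  study <- expression_study(expr, anno, stats::setNames(groups, ids))

  list(tracks = tracks, msi_panel = panel, labels = labels,
       expression = study,
       ground_truth = list(events = events_df, scores = truth_scores))
}
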