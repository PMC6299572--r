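#' Per-arm coverage of BCNA calls
#'
#' For each (chromosome, type) with at least one call, the percentage of
#' each arm's length covered by the call spans. Calls of one type on one
#' arm never overlap (the caller emits at most one per chain), so coverage
#' is the plain sum of span lengths. Acrocentric chromosomes have no
#' usable p arm; their `pct_p` is `NA`.
#'
#' @param calls call data.frame from one sample ([call_bcnas()])
#' @param arms arm-definition table
#' @return data.frame: `chromosome`, `type`, `pct_p`, `pct_q` (0-100)
#' @export
arm_coverage <- function(calls, arms) {
  if (nrow(calls) == 0L)
    return(data.frame(chromosome = character(), type = character(),
                      pct_p = numeric(), pct_q = numeric(),
                      stringsAsFactors = FALSE))
  known <- paste(arms$chromosome, arms$arm)
  bad <- !(paste(calls$chromosome, calls$arm) %in% known)
  if (any(bad))
    stop("call on undefined arm: ",
         paste(unique(paste0(calls$chromosome, calls$arm)[bad]),
               collapse = ", "))
  combos <- unique(calls[, c("chromosome", "type")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ch <- combos$chromosome[i]; ty <- combos$type[i]
    sub <- calls[calls$chromosome == ch & calls$type == ty, , drop = FALSE]
    pct <- function(a) {
      alen <- arm_length(arms, ch, a)
      if (is.na(alen)) return(NA_real_)
      s <- sub[sub$arm == a, , drop = FALSE]
      if (nrow(s) == 0L) return(0)
      100 * sum(s$end_bp - s$start_bp + 1) / alen
    }
    data.frame(chromosome = ch, type = ty, pct_p = pct("p"), pct_q = pct("q"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score one chromosome's coverage
#'
#' The p-q-w attribution rules, applied per (chromosome, type):
#' \itemize{
#'   \item aberration on a single arm only (including the q arm of an
#'     acrocentric chromosome): score 1 to that arm;
#'   \item same-type aberrations on both arms with \%p + \%q greater than
#'     150: score 1 to the whole chromosome ("w");
#'   \item both arms with \%p + \%q less than 150: score 1 to each arm.
#' }
#' A sum of exactly 150 is attributed to both arms: whole-chromosome
#' consolidation requires strictly more than 150.
#'
#' @param coverage one row of [arm_coverage()] output (or a data.frame of
#'   such rows, scored independently)
#' @return data.frame of attributions: `chromosome`, `type`, `unit`
#'   ("p", "q" or "w"), `score` (always 1 under the p-q-w rules)
#' @export
score_chromosome <- function(coverage) {
  rows <- lapply(seq_len(nrow(coverage)), function(i) {
    ch <- coverage$chromosome[i]; ty <- coverage$type[i]
    p <- coverage$pct_p[i]; q <- coverage$pct_q[i]
    p_in <- !is.na(p) && p > 0
    q_in <- !is.na(q) && q > 0
    if (!p_in && !q_in) return(NULL)
    att <- function(unit) data.frame(chromosome = ch, type = ty,
                                     unit = unit, score = 1L,
                                     stringsAsFactors = FALSE)
    if (xor(p_in, q_in)) return(att(if (p_in) "p" else "q"))
    if (p + q > 150) att("w") else rbind(att("p"), att("q"))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chromosome = character(), type = character(),
                      unit = character(), score = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total BCNA score under a scoring system
#'
#' Attributions come from the p-q-w rules. Under "pqw" every attribution
#' (arm or whole chromosome) counts 1; under the alternative "pq" system a
#' whole-chromosome attribution counts 2 (one per arm) and arm
#' attributions count 1.
#'
#' @param attributions data.frame from [score_chromosome()]
#' @param system "pqw" (default) or "pq"
#' @return integer total score
#' @export
total_score <- function(attributions, system = c("pqw", "pq")) {
  system <- match.arg(system)
  if (nrow(attributions) == 0L) return(0L)
  w <- attributions$unit == "w"
  if (system == "pqw") as.integer(nrow(attributions))
  else as.integer(sum(ifelse(w, 2L, 1L)))
}

format_attributions <- function(attributions) {
  if (nrow(attributions) == 0L) return("")
  sgn <- ifelse(attributions$type == "gain", "+", "-")
  paste0(attributions$chromosome, attributions$unit, sgn, collapse = ",")
}

#' Score one sample
#'
#' @param calls call data.frame for one sample
#' @param arms arm-definition table
#' @param sample_id sample label (defaults to the calls' sample_id)
#' @param system scoring system, "pqw" or "pq"
#' @return one-row data.frame: `sample_id`, `system`, `attributions`
#'   (compact string such as "8w+,18q-"), `bcna_score`
#' @export
score_sample <- function(calls, arms, sample_id = NULL,
                         system = c("pqw", "pq")) {
  system <- match.arg(system)
  if (is.null(sample_id))
    sample_id <- if (nrow(calls)) calls$sample_id[1] else NA_character_
  att <- score_chromosome(arm_coverage(calls, arms))
  data.frame(sample_id = sample_id, system = system,
             attributions = format_attributions(att),
             bcna_score = total_score(att, system),
             stringsAsFactors = FALSE)
}

#' Classify MSS samples into low- and high-BCNA groups
#'
#' The threshold is the first quartile of the MSS BCNA-score distribution;
#' a sample is low-BCNA (LB) iff its score is strictly below the
#' threshold, high-BCNA (HB) otherwise. MSI samples must be excluded
#' before calling this. The default quartile estimator is linear
#' interpolation at plotting position (k-1)/(n-1) (`stats::quantile`
#' type 7, the common spreadsheet default): with 28 scores whose 7th and
#' 8th order statistics are 5 and 6 this yields Q1 = 5.75.
#'
#' @param scores integer BCNA scores of the MSS samples (named vector
#'   names are carried through)
#' @param quantile_type `stats::quantile` type (default 7, linear
#'   interpolation)
#' @return list: `threshold` (Q1) and `class` (character vector "LB"/"HB",
#'   same order/names as `scores`)
#' @export
classify_mss <- function(scores, quantile_type = 7) {
  if (length(scores) < 4L)
    stop("need at least 4 MSS scores for a stable first quartile; got ",
         length(scores))
  q1 <- unname(stats::quantile(scores, 0.25, type = quantile_type))
  cls <- ifelse(scores < q1, "LB", "HB")
  list(threshold = q1, class = cls)
}

#' Score a cohort and assign genome-instability classes
#'
#' Runs per-sample scoring over a list of call tables, attaches MSI
#' status, and classifies MSS samples into LB/HB at the first quartile of
#' the MSS score distribution. MSI samples keep class "MSI" regardless of
#' score.
#'
#' @param calls_by_sample named list of call data.frames (one per sample)
#' @param arms arm-definition table
#' @param msi_status named character vector ("MSI"/"MSS") per sample
#' @param system scoring system
#' @param quantile_type quartile estimator (see [classify_mss()])
#' @param samples sample ids to score; defaults to the names of
#'   `calls_by_sample`. Samples listed here but absent from the call list
#'   (e.g. dropped from a SEG file because they have no segments) are
#'   scored 0.
#' @return list: `scorecards` (data.frame: sample_id, system,
#'   attributions, bcna_score, msi_status, gi_class) and `threshold`
#'   (the Q1 used, NA if no classification was possible)
#' @export
score_cohort <- function(calls_by_sample, arms, msi_status,
                         system = c("pqw", "pq"), quantile_type = 7,
                         samples = names(calls_by_sample)) {
  system <- match.arg(system)
  no_calls <- data.frame(sample_id = character(), chromosome = character(),
                         arm = character(), type = character(),
                         start_bp = numeric(), end_bp = numeric(),
                         stringsAsFactors = FALSE)
  cards <- do.call(rbind, lapply(samples, function(s)
    score_sample(if (s %in% names(calls_by_sample)) calls_by_sample[[s]]
                 else no_calls,
                 arms, sample_id = s, system = system)))
  missing <- setdiff(cards$sample_id, names(msi_status))
  if (length(missing))
    stop("no MSI status for sample(s): ", paste(missing, collapse = ", "))
  cards$msi_status <- unname(msi_status[cards$sample_id])
  cards$gi_class <- ifelse(cards$msi_status == "MSI", "MSI", "unassigned")
  mss <- cards$msi_status == "MSS"
  threshold <- NA_real_
  if (sum(mss) >= 4L) {
    cl <- classify_mss(cards$bcna_score[mss], quantile_type)
    threshold <- cl$threshold
    cards$gi_class[mss] <- cl$class
  } else if (any(mss)) {
    warning("fewer than 4 MSS samples; LB/HB classification skipped")
  }
  list(scorecards = cards, threshold = threshold)
}

#' Per-group BCNA-score summaries
#'
#' Mean, sample standard deviation (n - 1 denominator), n, min and max of
#' the BCNA score per genome-instability class. A single-sample group
#' reports `NA` for the SD; empty groups are omitted.
#'
#' @param scorecards data.frame with `gi_class` and `bcna_score`
#' @return data.frame: `gi_class`, `n`, `mean`, `sd`, `min`, `max`
#' @export
summarize_groups <- function(scorecards) {
  grps <- split(scorecards$bcna_score, scorecards$gi_class)
  grps <- grps[vapply(grps, length, integer(1)) > 0]
  out <- do.call(rbind, lapply(names(grps), function(g) {
    x <- grps[[g]]
    data.frame(gi_class = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Arm-level event frequencies across a cohort
#'
#' Plain tabulation of how often each (chromosome, arm, type) is involved
#' in a retained call, as a fraction of samples.
#'
#' @param calls_by_sample named list of call data.frames
#' @return data.frame: `chromosome`, `arm`, `type`, `n_samples`,
#'   `frequency`
#' @export
arm_event_frequency <- function(calls_by_sample) {
  n <- length(calls_by_sample)
  all <- do.call(rbind, lapply(names(calls_by_sample), function(s) {
    x <- calls_by_sample[[s]]
    if (nrow(x) == 0L) return(NULL)
    unique(data.frame(sample_id = s, chromosome = x$chromosome,
                      arm = x$arm, type = x$type, stringsAsFactors = FALSE))
  }))
  if (is.null(all))
    return(data.frame(chromosome = character(), arm = character(),
                      type = character(), n_samples = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  tab <- stats::aggregate(sample_id ~ chromosome + arm + type, data = all,
                          FUN = length)
  names(tab)[4] <- "n_samples"
  tab$frequency <- tab$n_samples / n
  tab
}
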