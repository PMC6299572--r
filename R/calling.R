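#' Calling thresholds
#'
#' The marker-level and segment-level thresholds of the broad copy number
#' aberration (BCNA) caller. Defaults are the published values: calibrated
#' 2.21/1.74 for autosomes and the female X (mean +/- 2 SD of a normal
#' diploid control group), 1.24/0.81 for male X and Y, isosegments of at
#' least 50 contiguous same-direction markers, and a minimum span of 25%
#' of the chromosomal arm. The intersegment gap threshold is not printed
#' in the source method and defaults to 1 Mb; it is configurable.
#'
#' All inequalities are strict: a calibrated value exactly at a threshold
#' is neutral, a span mean exactly at a threshold fails condition 2, and a
#' span of exactly 25% of an arm fails condition 3.
#'
#' @param upper_autosome,lower_autosome gain/loss calibrated thresholds for
#'   autosomes and female X
#' @param upper_male_xy,lower_male_xy thresholds for male X and Y
#' @param min_run_markers minimum contiguous markers in an isosegment
#' @param max_intersegment_distance maximum base-pair gap joined between
#'   isosegments (measured last-marker to first-marker)
#' @param min_arm_fraction minimum fraction of the arm a retained call must
#'   span (strictly exceeded)
#' @return list of class `calling_thresholds`
#' @export
default_thresholds <- function(upper_autosome = 2.21, lower_autosome = 1.74,
                               upper_male_xy = 1.24, lower_male_xy = 0.81,
                               min_run_markers = 50L,
                               max_intersegment_distance = 1e6,
                               min_arm_fraction = 0.25) {
  stopifnot(lower_autosome < 2, 2 < upper_autosome,
            lower_male_xy < 1, 1 < upper_male_xy,
            min_run_markers >= 1,
            min_arm_fraction > 0, min_arm_fraction <= 1)
  structure(list(upper_autosome = upper_autosome,
                 lower_autosome = lower_autosome,
                 upper_male_xy = upper_male_xy,
                 lower_male_xy = lower_male_xy,
                 min_run_markers = as.integer(min_run_markers),
                 max_intersegment_distance = max_intersegment_distance,
                 min_arm_fraction = min_arm_fraction),
            class = "calling_thresholds")
}

#' Calibrate a log2 ratio to the copy-number scale
#'
#' The reference (diploid) group is assigned the value 2, so a log2 ratio
#' r maps to 2 * 2^r: ratio 0 is diploid (2), +0.585 is a one-copy gain
#' (3), -1 is a one-copy loss (1).
#'
#' @param log2ratio numeric vector of log2 ratios versus the reference
#'   median
#' @return calibrated values
#' @examples
#' calibrate_log2ratio(0)    # 2, diploid
#' calibrate_log2ratio(0.15) # 2.219..., above the 2.21 gain threshold
#' @export
calibrate_log2ratio <- function(log2ratio) {
  if (any(!is.finite(log2ratio)))
    stop("log2ratio must be finite")
  2 * 2^log2ratio
}

# which threshold pair applies to each marker
.threshold_pair <- function(chromosome, sex, thresholds) {
  sexed <- chromosome %in% c("X", "Y")
  if (any(sexed) && any(sex == "unknown"))
    stop("X/Y markers present but sample sex is unknown; ",
         "cannot choose the threshold pair")
  male_xy <- sexed & sex == "male"
  list(upper = ifelse(male_xy, thresholds$upper_male_xy,
                      thresholds$upper_autosome),
       lower = ifelse(male_xy, thresholds$lower_male_xy,
                      thresholds$lower_autosome))
}

#' Classify markers as gain / loss / neutral
#'
#' Autosomes and the female X use the autosome pair; male X and Y use the
#' male pair. Strict inequalities: a marker exactly at a threshold is
#' neutral.
#'
#' @param track marker-track data.frame (needs `chromosome`, `sex`,
#'   `calibrated_value`)
#' @param thresholds a `calling_thresholds`
#' @return character vector, one of "gain", "loss", "neutral" per marker
#' @export
classify_markers <- function(track, thresholds = default_thresholds()) {
  pair <- .threshold_pair(track$chromosome, track$sex, thresholds)
  ifelse(track$calibrated_value > pair$upper, "gain",
         ifelse(track$calibrated_value < pair$lower, "loss", "neutral"))
}

#' Find isosegments
#'
#' An isosegment is a maximal run of at least `min_run_markers` contiguous
#' markers with the same non-neutral direction, confined to one chromosome
#' arm. Runs are broken by any neutral or opposite-direction marker and by
#' arm boundaries. Markers with no arm assignment (centromeric gaps,
#' unplaced scaffolds) are excluded before run detection.
#'
#' @param track marker-track data.frame, sorted by (chromosome, position)
#' @param thresholds a `calling_thresholds`
#' @return data.frame: `chromosome`, `arm`, `type`, `start_bp`, `end_bp`,
#'   `n_markers`, plus `first_idx`/`last_idx` (row indices into the
#'   arm-assigned, sorted track)
#' @export
find_isosegments <- function(track, thresholds = default_thresholds()) {
  track <- track[!is.na(track$arm), , drop = FALSE]
  empty <- data.frame(chromosome = character(), arm = character(),
                      type = character(), start_bp = numeric(),
                      end_bp = numeric(), n_markers = integer(),
                      first_idx = integer(), last_idx = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(track) == 0L) return(empty)
  dir <- classify_markers(track, thresholds)
  # break runs at arm boundaries by folding the arm key into the run value
  key <- paste(track$chromosome, track$arm, dir, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= thresholds$min_run_markers &
    !grepl("\rneutral$", r$values)
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(chromosome = track$chromosome[starts],
             arm = track$arm[starts],
             type = sub("^.*\r", "", r$values[keep]),
             start_bp = track$position[starts],
             end_bp = track$position[ends],
             n_markers = ends - starts + 1L,
             first_idx = starts, last_idx = ends,
             stringsAsFactors = FALSE)
}

#' Join isosegments and filter to broad calls
#'
#' Same-arm, same-type isosegments are chained transitively whenever the
#' base-pair gap between the last marker of one and the first marker of
#' the next is below `max_intersegment_distance` (condition 1). Each
#' resulting candidate span (isosegments plus intersegment intervals) is
#' retained only if its mean calibrated value over every marker in the
#' span, gap markers included, strictly passes the direction's threshold
#' (condition 2) and the span covers strictly more than `min_arm_fraction`
#' of the containing arm (condition 3).
#'
#' @param isosegments output of [find_isosegments()]
#' @param track the same marker track
#' @param arms arm-definition table
#' @param thresholds a `calling_thresholds`
#' @return data.frame of calls: `sample_id`, `chromosome`, `arm`, `type`,
#'   `start_bp`, `end_bp`, `n_markers`, `mean_calibrated`, `arm_fraction`
#' @export
join_and_filter <- function(isosegments, track, arms,
                            thresholds = default_thresholds()) {
  track <- track[!is.na(track$arm), , drop = FALSE]
  out <- list()
  if (nrow(isosegments) > 0L) {
    grp <- split(isosegments,
                 paste(isosegments$chromosome, isosegments$arm,
                       isosegments$type, sep = "\r"))
    for (g in grp) {
      g <- g[order(g$start_bp), , drop = FALSE]
      gap_ok <- if (nrow(g) > 1L)
        (g$start_bp[-1L] - g$end_bp[-nrow(g)]) <
          thresholds$max_intersegment_distance else logical(0)
      chain_id <- cumsum(c(TRUE, !gap_ok))
      for (cid in unique(chain_id)) {
        ch <- g[chain_id == cid, , drop = FALSE]
        span_lo <- min(ch$start_bp); span_hi <- max(ch$end_bp)
        sel <- track$chromosome == ch$chromosome[1] &
          track$arm == ch$arm[1] &
          track$position >= span_lo & track$position <= span_hi
        mean_cal <- mean(track$calibrated_value[sel])
        pair <- .threshold_pair(ch$chromosome[1],
                                track$sex[which(sel)[1]], thresholds)
        passes_mean <- if (ch$type[1] == "gain")
          mean_cal > pair$upper[1] else mean_cal < pair$lower[1]
        a_len <- arm_length(arms, ch$chromosome[1], ch$arm[1])
        if (is.na(a_len))
          stop("call on chromosome ", ch$chromosome[1], ch$arm[1],
               " but that arm is absent from the arm definitions")
        frac <- (span_hi - span_lo + 1) / a_len
        if (passes_mean && frac > thresholds$min_arm_fraction) {
          out[[length(out) + 1L]] <- data.frame(
            sample_id = track$sample_id[1],
            chromosome = ch$chromosome[1], arm = ch$arm[1],
            type = ch$type[1], start_bp = span_lo, end_bp = span_hi,
            n_markers = sum(sel), mean_calibrated = mean_cal,
            arm_fraction = frac, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chromosome = character(),
                      arm = character(), type = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_markers = integer(), mean_calibrated = numeric(),
                      arm_fraction = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(match(res$chromosome, unique(track$chromosome)),
                   res$arm, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call broad copy number aberrations for one sample
#'
#' Convenience wrapper: classify markers, detect isosegments, join and
#' filter.
#'
#' @inheritParams join_and_filter
#' @param track one sample's marker track
#' @return a call data.frame (see [join_and_filter()])
#' @export
call_bcnas <- function(track, arms, thresholds = default_thresholds()) {
  iso <- find_isosegments(track, thresholds)
  join_and_filter(iso, track, arms, thresholds)
}
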