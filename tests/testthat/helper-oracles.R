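# Fixtures and independent oracles used across the suite. The oracles
# re-derive each result from first principles and never call the package's
# own code path for the quantity they check.

# small arm tables for hand-built tracks
toy_arms <- function(q_len = 2e7, p_len = 1e7, chromosome = "5") {
  data.frame(chromosome = chromosome, arm = c("p", "q"),
             start_bp = c(1, p_len + 1),
             end_bp = c(p_len, p_len + q_len),
             acrocentric = FALSE, stringsAsFactors = FALSE)
}

# build a one-arm marker track directly from calibrated values
make_track <- function(calibrated, chromosome = "5", arm = "q",
                       start_pos = 1e7 + 1, spacing = 1e5,
                       sample_id = "S1", sex = "female") {
  n <- length(calibrated)
  data.frame(sample_id = sample_id, sex = sex,
             marker_id = sprintf("m%04d", seq_len(n)),
             chromosome = chromosome,
             position = start_pos + (seq_len(n) - 1) * spacing,
             log2ratio = log2(calibrated / 2),
             calibrated_value = calibrated, arm = arm,
             stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} m p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj_sorted[i] <- min(1, min(m * p[o][js] / js))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# independent scoring-rule oracle: literal restatement of the three rules
bf_score_rules <- function(pct_p, pct_q) {
  p_in <- !is.na(pct_p) && pct_p > 0
  q_in <- !is.na(pct_q) && pct_q > 0
  if (!p_in && !q_in) return(character(0))
  if (p_in && !q_in) return("p")
  if (q_in && !p_in) return("q")
  if (pct_p + pct_q > 150) "w" else c("p", "q")
}

# brute-force BCNA caller: re-derives marker directions, enumerates every
# candidate run for isosegments, and every contiguous isosegment range for
# chains, checking gap validity, maximality and conditions 1-3.
bf_call_oracle <- function(track, arms, th = default_thresholds()) {
  track <- track[!is.na(track$arm), , drop = FALSE]
  cal <- 2 * 2^track$log2ratio
  male_xy <- track$chromosome %in% c("X", "Y") & track$sex == "male"
  up <- ifelse(male_xy, th$upper_male_xy, th$upper_autosome)
  lo <- ifelse(male_xy, th$lower_male_xy, th$lower_autosome)
  dir <- ifelse(cal > up, "gain", ifelse(cal < lo, "loss", "neutral"))

  out <- list()
  for (key in unique(paste(track$chromosome, track$arm))) {
    sel <- paste(track$chromosome, track$arm) == key
    pos <- track$position[sel]; d <- dir[sel]; cv <- cal[sel]
    ch <- track$chromosome[sel][1]; arm <- track$arm[sel][1]
    n <- length(d)
    for (ty in c("gain", "loss")) {
      # isosegments: maximal same-direction runs of >= min_run_markers,
      # found by checking every start position
      segs <- list()
      i <- 1L
      while (i <= n) {
        if (d[i] == ty && (i == 1L || d[i - 1L] != ty)) {
          j <- i
          while (j < n && d[j + 1L] == ty) j <- j + 1L
          if (j - i + 1L >= th$min_run_markers)
            segs[[length(segs) + 1L]] <- c(i, j)
          i <- j + 1L
        } else i <- i + 1L
      }
      if (!length(segs)) next
      k <- length(segs)
      starts <- vapply(segs, `[`, numeric(1), 1)
      ends <- vapply(segs, `[`, numeric(1), 2)
      gap_ok <- function(a, b)  # bp gap from last marker of a to first of b
        (pos[starts[b]] - pos[ends[a]]) < th$max_intersegment_distance
      for (a in seq_len(k)) for (b in a:k) {
        valid <- all(vapply(seq_len(max(0, b - a)), function(m)
          gap_ok(a + m - 1L, a + m), logical(1)))
        if (!valid) next
        maximal <- (a == 1L || !gap_ok(a - 1L, a)) &&
          (b == k || !gap_ok(b, b + 1L))
        if (!maximal) next
        span <- which(pos >= pos[starts[a]] & pos <= pos[ends[b]])
        mean_cal <- mean(cv[span])
        mean_ok <- if (ty == "gain") mean_cal > up[sel][span][1]
                   else mean_cal < lo[sel][span][1]
        alen <- arms$end_bp[arms$chromosome == ch & arms$arm == arm] -
          arms$start_bp[arms$chromosome == ch & arms$arm == arm] + 1
        frac <- (pos[ends[b]] - pos[starts[a]] + 1) / alen
        if (mean_ok && frac > th$min_arm_fraction)
          out[[length(out) + 1L]] <- data.frame(
            chromosome = ch, arm = arm, type = ty,
            start_bp = pos[starts[a]], end_bp = pos[ends[b]],
            mean_calibrated = mean_cal, arm_fraction = frac,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), arm = character(),
                      type = character(), start_bp = numeric(),
                      end_bp = numeric(), mean_calibrated = numeric(),
                      arm_fraction = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$arm, res$type, res$start_bp), ]
}

# random noisy track with implanted blocks, for oracle-equivalence checks
random_test_track <- function(arms, n_markers, n_blocks = 3,
                              spacing_pool = c(5e4, 1e5, 4e5, 1.2e6)) {
  arm_row <- arms[sample(nrow(arms), 1), ]
  spacing <- sample(spacing_pool, n_markers - 1, replace = TRUE,
                    prob = c(0.55, 0.3, 0.1, 0.05))
  pos <- arm_row$start_bp + cumsum(c(0, spacing))
  pos <- pos[pos <= arm_row$end_bp]
  n <- length(pos)
  l2r <- rnorm(n, 0, 0.05)
  for (b in seq_len(n_blocks)) {
    len <- sample(20:400, 1)
    at <- sample(n, 1)
    idx <- at:min(n, at + len - 1)
    l2r[idx] <- l2r[idx] + sample(c(log2(3 / 2), log2(1 / 2),
                                    log2(2.3 / 2), log2(1.6 / 2)), 1)
  }
  data.frame(sample_id = "R1", sex = "female",
             marker_id = sprintf("m%05d", seq_len(n)),
             chromosome = arm_row$chromosome, position = pos,
             log2ratio = l2r, calibrated_value = 2 * 2^l2r,
             arm = arm_row$arm, stringsAsFactors = FALSE)
}

# align a calls table with the oracle's column subset for comparison
call_key <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  sort(sprintf("%s|%s|%s|%d|%d", calls$chromosome, calls$arm, calls$type,
               as.integer(calls$start_bp), as.integer(calls$end_bp)))
}
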