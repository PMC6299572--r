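#!/usr/bin/env Rscript
# Call broad copy number aberrations in every simulated tumor track:
# calibrate log2 ratios to the diploid-2 scale, detect isosegments of at
# least 50 same-direction markers, join across sub-threshold gaps, and
# keep spans whose mean stays beyond 2.21/1.74 and that exceed 25% of the
# arm. Writes a SEG-style call table.

suppressPackageStartupMessages(library(bcnascore))

indir <- "results/cohort"
arms <- read_arms_bed(file.path(indir, "arms.bed"))
tracks <- read_tracks_tsv(file.path(indir, "marker_tracks.tsv"), arms)

th <- default_thresholds()
calls <- lapply(tracks, call_bcnas, arms = arms, thresholds = th)
write_seg(calls, file.path(indir, "bcna_calls.seg"))

n_calls <- vapply(calls, nrow, integer(1))
message("called ", sum(n_calls), " broad aberrations in ", length(tracks),
        " samples (per-sample range ", min(n_calls), "-", max(n_calls), ")")
freq <- arm_event_frequency(calls)
freq <- freq[order(-freq$frequency), ]
write.table(freq, file.path(indir, "arm_frequency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("most recurrent arms: ",
        paste(utils::head(sprintf("%s%s %s (%.0f%%)", freq$chromosome,
                                  freq$arm, freq$type,
                                  100 * freq$frequency), 5),
              collapse = ", "))
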