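#!/usr/bin/env Rscript
# Simulate the study cohort: 33 tumors (21 HB, 7 LB, 5 MSI) and 25
# normals, with implanted broad copy-number events, a six-marker
# microsatellite panel, histology labels and a group-structured expression
# matrix. Writes every input the downstream stages read.

suppressPackageStartupMessages(library(bcnascore))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- published_cohort_config(seed = 20260930)
arms <- make_default_genome()
cohort <- simulate_cohort(cfg, arms)

write_tracks_tsv(cohort$tracks, file.path(out, "marker_tracks.tsv"))
write_arms_bed(arms, file.path(out, "arms.bed"))
write.table(cohort$msi_panel, file.path(out, "msi_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$labels, file.path(out, "labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_expression_tsv(cohort$expression,
                     file.path(out, "expression.tsv"),
                     file.path(out, "annotation.tsv"),
                     file.path(out, "groups.tsv"))
jsonlite::write_json(cohort$ground_truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

gt <- cohort$ground_truth$scores
message("simulated ", sum(gt$group != "Normal"), " tumor tracks and ",
        sum(cohort$expression$groups == "Normal"), " normal samples")
message("implanted events per group (mean): ",
        paste(sprintf("%s=%.1f", names(tapply(gt$n_events, gt$group, mean)),
                      tapply(gt$n_events, gt$group, mean)), collapse = " "))
message("inputs written under ", out)
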