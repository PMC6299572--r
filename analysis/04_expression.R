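#!/usr/bin/env Rscript
# Differential expression: filter genes by annotation, contrast each
# computed genome-instability class (HB, LB, MSI) against normal colon
# with signed linear fold changes and one-way ANOVA + Benjamini-Hochberg,
# then cross-classify DEGs as group-specific or shared and list the
# top-ranked genes per class.

suppressPackageStartupMessages(library(bcnascore))

indir <- "results/cohort"
study <- read_expression_tsv(file.path(indir, "expression.tsv"),
                             file.path(indir, "annotation.tsv"),
                             file.path(indir, "groups.tsv"))
cards <- read.delim(file.path(indir, "scorecards.tsv"),
                    stringsAsFactors = FALSE)

# relabel tumor columns with the classes computed in step 03
groups <- study$groups
gi <- setNames(cards$gi_class, cards$sample_id)
groups[names(gi)] <- gi
study <- expression_study(study$expr, study$annotation, groups)

n0 <- nrow(study$expr)
study <- filter_study(study)
message("gene filter kept ", nrow(study$expr), "/", n0, " genes")

contrasts <- contrast_all(study)
write.table(contrasts, file.path(indir, "contrasts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

degs <- classify_degs(contrasts, fc_cut = 2, fdr_cut = 0.05)
write.table(degs, file.path(indir, "deg_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
counts <- table(degs$direction, degs$category)
message("DEG category counts (columns are specific/shared sets):")
print(counts)

for (g in c("HB", "LB", "MSI")) {
  for (dir in c("up", "down")) {
    top <- top_ranked(contrasts[contrasts$group == g, ], dir, n = 30)
    write.table(top, file.path(indir, sprintf("top30_%s_%s.tsv", g, dir)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
message("top-30 lists written under ", indir)
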