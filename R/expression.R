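#' Construct an expression study
#'
#' A filtered gene x sample matrix of log2-scale (RMA-like) expression
#' values, with gene annotation and sample group labels.
#'
#' @param expr numeric matrix, genes x samples, log2 scale; rownames are
#'   gene symbols
#' @param annotation data.frame with `symbol`, `description`, `chromosome`
#'   (one row per matrix row, same order)
#' @param groups named character vector mapping every sample (column) to
#'   one of "HB", "LB", "MSI", "Normal"
#' @return list of class `expression_study`
#' @export
expression_study <- function(expr, annotation, groups) {
  stopifnot(is.matrix(expr), nrow(expr) == nrow(annotation))
  if (!all(colnames(expr) %in% names(groups)))
    stop("samples without a group assignment: ",
         paste(setdiff(colnames(expr), names(groups)), collapse = ", "))
  groups <- groups[colnames(expr)]
  bad <- setdiff(unique(groups), c("HB", "LB", "MSI", "Normal"))
  if (length(bad)) stop("unknown group label(s): ",
                        paste(bad, collapse = ", "))
  if (any(!is.finite(expr))) stop("expression values must be finite")
  structure(list(expr = expr, annotation = annotation, groups = groups),
            class = "expression_study")
}

# scaffolds excluded from expression analysis (unplaced / haplotype contigs)
excluded_scaffolds <- function() {
  c("chr1_gl000191_random", "chr4_ctg9_hap1", "chr4_gl000193_random",
    "chr4_gl000194_random", "chr6_apd_hap1", "chr6_cox_hap2",
    "chr6_dbb_hap3", "chr6_mann_hap4", "chr6_mcf_hap5", "chr6_qbl_hap6",
    "chr6_ssto_hap7", "chr7_gl000195_random", "chr17_ctg5_hap1",
    "chr17_gl000204_random", "chr19_gl000209_random", "chrUn_gl000211",
    "chrUn_gl000212", "chrUn_gl000218", "chrUn_gl000219", "chrUn_gl000220",
    "chrUn_gl000222", "chrUn_gl000223", "chrUn_gl000228")
}

#' Default gene-exclusion rules
#'
#' Pattern rules for the annotation-based gene filter, loaded from the
#' editable file `extdata/gene_exclusion_rules.tsv` shipped with the
#' package. Each rule names the annotation field it applies to (`symbol`
#' or `description`) and a case-insensitive regular expression; any match
#' removes the gene. The unplaced/haplotype scaffold list is handled
#' separately (see [excluded_scaffolds()]).
#'
#' @return data.frame with columns `field`, `pattern`, `note`
#' @export
default_gene_filters <- function() {
  path <- system.file("extdata", "gene_exclusion_rules.tsv",
                      package = "bcnascore")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Filter genes by annotation
#'
#' Removes genes with no symbol; placeholder "OTTHUMG..." symbols; genes
#' whose only description begins "uncharacterized LOC"; small-RNA classes
#' (snoRNA, scaRNA, snRNA, small NF90-associated RNA, 5S rRNA genes and
#' pseudogenes, 5.8S rRNA pseudogenes, Y RNA, mitochondrial rRNA,
#' microRNA); olfactory receptor and histone cluster genes; and anything
#' annotated to an unplaced or haplotype scaffold.
#'
#' @param annotation data.frame with `symbol`, `description`, `chromosome`
#' @param rules pattern rules, default [default_gene_filters()]
#' @param scaffolds excluded scaffold names, default [excluded_scaffolds()]
#' @return logical vector: TRUE = retained
#' @export
filter_genes <- function(annotation, rules = default_gene_filters(),
                         scaffolds = excluded_scaffolds()) {
  sym <- annotation$symbol
  desc <- if (is.null(annotation$description)) rep("", nrow(annotation))
          else annotation$description
  desc[is.na(desc)] <- ""
  drop <- is.na(sym) | sym == ""
  # "uncharacterized LOC" only drops when it is the sole description
  unch <- grepl("^uncharacterized LOC", desc) & !grepl(";", desc)
  drop <- drop | unch
  for (i in seq_len(nrow(rules))) {
    x <- if (rules$field[i] == "symbol") sym else desc
    drop <- drop | grepl(rules$pattern[i], x, ignore.case = TRUE,
                         perl = TRUE)
  }
  drop <- drop | annotation$chromosome %in% scaffolds
  !drop
}

#' Apply the gene filter to an expression study
#' @param study an `expression_study`
#' @inheritParams filter_genes
#' @return the filtered `expression_study`
#' @export
filter_study <- function(study, rules = default_gene_filters(),
                         scaffolds = excluded_scaffolds()) {
  keep <- filter_genes(study$annotation, rules, scaffolds)
  expression_study(study$expr[keep, , drop = FALSE],
                   study$annotation[keep, , drop = FALSE],
                   study$groups)
}

#' Signed linear fold change
#'
#' The difference of group means on the log2 scale, re-expressed as a
#' linear ratio with the negative-reciprocal convention for
#' down-regulation: FC = 2^d for d > 0, FC = -2^(-d) for d < 0 (so a
#' ratio of 1/2 is reported as -2), and FC = 1 at equal means. No value
#' ever falls strictly between -1 and 1.
#'
#' @param mean_log2_tumor,mean_log2_normal group means on the log2 scale
#' @return signed linear fold change (vectorised)
#' @examples
#' linear_fc(6, 7)  # -2
#' linear_fc(8, 7)  #  2
#' @export
linear_fc <- function(mean_log2_tumor, mean_log2_normal) {
  if (any(!is.finite(mean_log2_tumor)) || any(!is.finite(mean_log2_normal)))
    stop("group means must be finite")
  d <- mean_log2_tumor - mean_log2_normal
  ifelse(d > 0, 2^d, ifelse(d < 0, -2^(-d), 1))
}

# pooled-variance F test, vectorised over matrix rows; identical to a
# two-group one-way ANOVA
.row_anova_two_group <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  df2 <- n1 + n2 - 2
  s2p <- (ss1 + ss2) / df2
  fstat <- (m1 - m2)^2 / (s2p * (1 / n1 + 1 / n2))
  p <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
  degenerate <- s2p == 0
  # zero within-group variance: identical groups are uninformative (p = 1),
  # separated constant groups are maximally informative (p -> 0)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(mean1 = m1, mean2 = m2, p = p, degenerate = degenerate)
}

#' Tumor-group versus normal contrasts
#'
#' For every gene and every tumor group present in the study: the signed
#' linear fold change between the group mean and the normal-colon mean,
#' the one-way ANOVA p-value of the two-group comparison (pooled-variance
#' F test), and the Benjamini-Hochberg adjusted p-value (adjusted across
#' all genes within each contrast).
#'
#' @param study an `expression_study` (already gene-filtered)
#' @param tumor_groups groups to contrast against Normal; defaults to the
#'   tumor groups present
#' @return data.frame: `gene`, `group`, `fc`, `p`, `fdr`, `degenerate`
#' @export
contrast_all <- function(study, tumor_groups = NULL) {
  if (is.null(tumor_groups))
    tumor_groups <- intersect(c("HB", "LB", "MSI"), unique(study$groups))
  norm <- study$expr[, study$groups == "Normal", drop = FALSE]
  if (ncol(norm) < 2L) stop("group Normal has fewer than 2 samples")
  out <- lapply(tumor_groups, function(g) {
    xg <- study$expr[, study$groups == g, drop = FALSE]
    if (ncol(xg) < 2L) stop("group ", g, " has fewer than 2 samples")
    a <- .row_anova_two_group(xg, norm)
    data.frame(gene = rownames(study$expr), group = g,
               fc = linear_fc(a$mean1, a$mean2),
               p = a$p, fdr = stats::p.adjust(a$p, method = "BH"),
               degenerate = a$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# the specific/shared threshold grids: each row is a conjunction over the
# three contrasts; "sig" = FC beyond the cut AND FDR < fdr_cut,
# "ns" = FC short of the cut AND FDR >= fdr_cut (FDR exactly at the cut is
# non-significant)
.deg_rows <- list(
  c("HB"), c("LB"), c("MSI"),
  c("HB", "LB"), c("LB", "MSI"), c("HB", "MSI"),
  c("HB", "LB", "MSI"))

#' Cross-classify DEGs as group-specific or shared
#'
#' Applies the specific/shared threshold grids literally and
#' independently for the up- and down-regulated directions. For the "up"
#' direction a gene belongs to category S (a nonempty subset of
#' \{HB, LB, MSI\}) iff every group in S has FC > `fc_cut` and
#' FDR < `fdr_cut` while every group outside S has FC < `fc_cut` and
#' FDR >= `fdr_cut`; "down" uses FC < -`fc_cut` (and FC > -`fc_cut` for
#' the complement). Genes matching no row are "unassigned". The rows are
#' mutually exclusive, so at most one category can match per direction.
#'
#' @param contrasts output of [contrast_all()] covering all three tumor
#'   groups
#' @param fc_cut linear fold-change threshold (default 2)
#' @param fdr_cut FDR significance threshold (default 0.05)
#' @return data.frame: `gene`, `direction` ("up"/"down"), `category`
#'   (e.g. "HB", "LB+MSI", "HB+LB+MSI", or "unassigned")
#' @export
classify_degs <- function(contrasts, fc_cut = 2, fdr_cut = 0.05) {
  need <- c("HB", "LB", "MSI")
  have <- split(contrasts, contrasts$group)
  if (!all(need %in% names(have)))
    stop("missing contrast(s) for group(s): ",
         paste(setdiff(need, names(have)), collapse = ", "))
  genes <- have[["HB"]]$gene
  for (g in need) {
    have[[g]] <- have[[g]][match(genes, have[[g]]$gene), ]
    if (any(is.na(have[[g]]$fc)))
      stop("missing contrast rows for group ", g)
  }
  fc <- cbind(HB = have$HB$fc, LB = have$LB$fc, MSI = have$MSI$fc)
  fdr <- cbind(HB = have$HB$fdr, LB = have$LB$fdr, MSI = have$MSI$fdr)

  one_direction <- function(sign) {
    sig <- if (sign > 0) fc > fc_cut & fdr < fdr_cut
           else fc < -fc_cut & fdr < fdr_cut
    ns <- if (sign > 0) fc < fc_cut & fdr >= fdr_cut
          else fc > -fc_cut & fdr >= fdr_cut
    cat_out <- rep("unassigned", length(genes))
    for (row in .deg_rows) {
      inside <- row
      outside <- setdiff(need, row)
      ok <- rowSums(sig[, inside, drop = FALSE]) == length(inside) &
        rowSums(ns[, outside, drop = FALSE]) == length(outside)
      cat_out[ok] <- paste(row, collapse = "+")
    }
    cat_out
  }
  rbind(data.frame(gene = genes, direction = "up",
                   category = one_direction(+1), stringsAsFactors = FALSE),
        data.frame(gene = genes, direction = "down",
                   category = one_direction(-1), stringsAsFactors = FALSE))
}

#' Top-ranked differentially expressed genes
#'
#' Significant DEGs of one contrast in one direction, ordered by fold
#' change (descending for "up", ascending for "down"), truncated to `n`.
#' Ties in FC break by smaller FDR, then lexical gene symbol.
#'
#' @param contrasts a subset of [contrast_all()] output (one group)
#' @param direction "up" or "down"
#' @param n maximum genes returned (default 30)
#' @param fc_cut,fdr_cut significance thresholds
#' @return the selected contrast rows, ordered
#' @export
top_ranked <- function(contrasts, direction = c("up", "down"), n = 30,
                       fc_cut = 2, fdr_cut = 0.05) {
  direction <- match.arg(direction)
  sig <- if (direction == "up")
    contrasts$fc > fc_cut & contrasts$fdr < fdr_cut
  else contrasts$fc < -fc_cut & contrasts$fdr < fdr_cut
  sub <- contrasts[sig, , drop = FALSE]
  ord <- order(if (direction == "up") -sub$fc else sub$fc,
               sub$fdr, sub$gene)
  utils::head(sub[ord, , drop = FALSE], n)
}

#' Group composition percentages
#'
#' Count and percentage of each label class within each group, rounded to
#' the requested number of digits (e.g. 3 mucinous of 7 LB samples is
#' 43\% at 0 digits; 5 MSI of 32 patients is 15.6\% at 1 digit).
#'
#' @param labels data.frame with a grouping column and a label column
#' @param group_col,label_col column names (defaults "group", "histology")
#' @param digits rounding digits for the percentage (default 0)
#' @return data.frame: group, label, `k`, `n`, `pct`
#' @export
composition_summary <- function(labels, group_col = "group",
                                label_col = "histology", digits = 0) {
  labels <- labels[!is.na(labels[[label_col]]), , drop = FALSE]
  rows <- list()
  for (g in unique(labels[[group_col]])) {
    sub <- labels[labels[[group_col]] == g, , drop = FALSE]
    n <- nrow(sub)
    for (l in unique(sub[[label_col]])) {
      k <- sum(sub[[label_col]] == l)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, label = l, k = k, n = n,
        pct = round(100 * k / n, digits), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
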