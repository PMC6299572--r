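anno_row <- function(symbol, description = "protein coding",
                     chromosome = "chr17") {
  data.frame(symbol = symbol, description = description,
             chromosome = chromosome, stringsAsFactors = FALSE)
}

test_that("annotation filter removes the documented gene classes", {
  anno <- rbind(
    anno_row("TP53", "tumor protein p53"),
    anno_row("GENEONSCAF", "fine gene", "chrUn_gl000211"),
    anno_row("SNORD3A", "small nucleolar RNA, C/D box 3A"),
    anno_row("OTTHUMG00000012345", "annotated novel transcript"),
    anno_row(NA, "no symbol assigned"),
    anno_row("LOC101927", "uncharacterized LOC101927"),
    anno_row("LOC2", "uncharacterized LOC2; second meaningful description"),
    anno_row("MIR21", "microRNA 21"),
    anno_row("OR4F5", "olfactory receptor, family 4, subfamily F"),
    anno_row("HIST1H1A", "histone cluster 1, H1a"),
    anno_row("RNU6-1", "RNA, U6 small nuclear 1"),
    anno_row("MT-RNR1", "mitochondrially encoded 12S RNA"),
    anno_row("SCARNA1", "small Cajal body-specific RNA 1"),
    anno_row("RNA5S1", "RNA, 5S ribosomal 1"))
  keep <- filter_genes(anno)
  expect_identical(anno$symbol[keep], c("TP53", "LOC2"))
})

test_that("signed linear fold change follows the reciprocal convention", {
  expect_equal(linear_fc(6, 7), -2)   # log2 difference -1, ratio 1/2
  expect_equal(linear_fc(8, 7), 2)
  expect_equal(linear_fc(7, 7), 1)
  expect_error(linear_fc(NA, 1), "finite")
  # antisymmetry and magnitude identity over a range of differences
  for (d in c(-3.2, -1, -0.1, 0.1, 2, 4.7)) {
    expect_equal(linear_fc(7 + d, 7), -linear_fc(7, 7 + d))
    expect_equal(abs(linear_fc(7 + d, 7)), 2^abs(d))
    expect_gte(abs(linear_fc(7 + d, 7)), 1)  # nothing in (-1, 1)
  }
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(19)
  for (i in 1:10) {
    p <- runif(sample(5:400, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bf_bh(p))
  }
})

test_that("contrasts report FC, ANOVA p and per-contrast FDR", {
  set.seed(23)
  n <- 10
  genes <- c("FLAT", "UP_HB", "CONST")
  expr <- rbind(FLAT = rnorm(4 * n, 7, 0.3),
                UP_HB = rnorm(4 * n, 7, 0.3),
                CONST = rep(5, 4 * n))
  groups <- rep(c("HB", "LB", "MSI", "Normal"), each = n)
  colnames(expr) <- paste0("s", 1:(4 * n))
  expr["UP_HB", groups == "HB"] <- expr["UP_HB", groups == "HB"] + 2
  study <- expression_study(expr, anno_row(genes),
                            setNames(groups, colnames(expr)))
  res <- contrast_all(study)
  expect_setequal(unique(res$group), c("HB", "LB", "MSI"))
  hb <- res[res$group == "HB", ]
  expect_gt(hb$fc[hb$gene == "UP_HB"], 2)
  expect_lt(hb$fdr[hb$gene == "UP_HB"], 0.05)
  # identical constant values: FC 1, degenerate flag, p = 1
  expect_equal(hb$fc[hb$gene == "CONST"], 1)
  expect_equal(hb$p[hb$gene == "CONST"], 1)
  expect_true(hb$degenerate[hb$gene == "CONST"])
  # the two-group pooled-variance F test IS one-way ANOVA
  x <- expr["FLAT", groups == "HB"]; y <- expr["FLAT", groups == "Normal"]
  ref <- oneway.test(v ~ g, data.frame(v = c(x, y),
                                       g = rep(c("a", "b"), each = n)),
                     var.equal = TRUE)$p.value
  expect_equal(hb$p[hb$gene == "FLAT"], ref)
  # groups of fewer than 2 samples are refused by name
  small <- expression_study(expr[, -(1:(n - 1)), drop = FALSE],
                            study$annotation,
                            study$groups[-(1:(n - 1))])
  expect_error(contrast_all(small), "HB")
})

test_that("implanted effects are recovered at the expected FC and FDR", {
  set.seed(29)
  n <- 10
  n_eff <- 200; n_null <- 300
  groups <- rep(c("HB", "Normal"), each = n)
  expr <- matrix(rnorm((n_eff + n_null) * 2 * n, 7, 0.3), ncol = 2 * n)
  expr[seq_len(n_eff), groups == "HB"] <-
    expr[seq_len(n_eff), groups == "HB"] + 2
  rownames(expr) <- sprintf("G%03d", seq_len(nrow(expr)))
  colnames(expr) <- paste0("s", seq_len(2 * n))
  anno <- data.frame(symbol = rownames(expr), description = "x",
                     chromosome = "chr1")
  study <- expression_study(expr, anno, setNames(groups, colnames(expr)))
  res <- contrast_all(study, tumor_groups = "HB")
  eff <- res[seq_len(n_eff), ]
  ok <- eff$fc >= 3 & eff$fc <= 5.3 & eff$fdr < 0.05
  expect_gte(mean(ok), 0.95)
})

test_that("the specific/shared grids classify the worked examples", {
  mk <- function(fc, fdr)
    data.frame(gene = "G", group = c("HB", "LB", "MSI"), fc = fc, p = fdr,
               fdr = fdr, stringsAsFactors = FALSE)
  # HB-specific up
  r <- classify_degs(mk(c(3, 1.5, 1.2), c(0.01, 0.2, 0.5)))
  expect_equal(r$category[r$direction == "up"], "HB")
  expect_equal(r$category[r$direction == "down"], "unassigned")
  # shared by all three
  r <- classify_degs(mk(c(2.5, 2.5, 2.5), c(0.01, 0.01, 0.01)))
  expect_equal(r$category[r$direction == "up"], "HB+LB+MSI")
  # LB fails both the shared row (FDR too big) and the specific row
  # (FC too big): unassigned
  r <- classify_degs(mk(c(2.5, 2.5, 1.0), c(0.01, 0.2, 0.9)))
  expect_equal(r$category[r$direction == "up"], "unassigned")
  # downregulation mirrors with the -2 bounds
  r <- classify_degs(mk(c(-3, -1.5, -1.2), c(0.01, 0.2, 0.5)))
  expect_equal(r$category[r$direction == "down"], "HB")
  expect_equal(r$category[r$direction == "up"], "unassigned")
  # missing contrast errors
  expect_error(classify_degs(mk(1, 1)[1:2, ]), "missing contrast")
})

test_that("grid rows are mutually exclusive over an exhaustive scan", {
  fcs <- c(-3, -2.5, -2, -1.5, 1, 1.5, 2, 2.5, 3)
  fdrs <- c(0.01, 0.05, 0.2)
  grid <- expand.grid(fc_HB = fcs, fc_LB = fcs, fc_MSI = fcs,
                      fdr = fdrs)
  # independent oracle: count matching rows directly
  subsets <- list("HB", "LB", "MSI", c("HB", "LB"), c("LB", "MSI"),
                  c("HB", "MSI"), c("HB", "LB", "MSI"))
  for (i in seq_len(nrow(grid))) {
    fc <- c(HB = grid$fc_HB[i], LB = grid$fc_LB[i], MSI = grid$fc_MSI[i])
    fdr <- rep(grid$fdr[i], 3); names(fdr) <- names(fc)
    n_match <- sum(vapply(subsets, function(s) {
      o <- setdiff(names(fc), s)
      all(fc[s] > 2 & fdr[s] < 0.05) && all(fc[o] < 2 & fdr[o] >= 0.05)
    }, logical(1)))
    expect_lte(n_match, 1L)
    ctr <- data.frame(gene = "G", group = names(fc), fc = unname(fc),
                      p = unname(fdr), fdr = unname(fdr))
    got <- classify_degs(ctr)
    got_up <- got$category[got$direction == "up"]
    if (n_match == 0) expect_equal(got_up, "unassigned")
    else expect_false(got_up == "unassigned")
  }
})

test_that("implanted DEG categories are recovered on a synthetic study", {
  set.seed(31)
  n <- 10
  eff <- default_expression_effects(genes_per_category = 10, n_null = 100)
  groups <- rep(c("HB", "LB", "MSI", "Normal"), each = n)
  expr <- matrix(rnorm(nrow(eff) * 4 * n, 0, 0.3), nrow = nrow(eff)) + 7
  for (g in c("HB", "LB", "MSI"))
    expr[, groups == g] <- expr[, groups == g] +
      eff[[paste0("effect_", g)]]
  rownames(expr) <- eff$gene
  colnames(expr) <- paste0("s", seq_len(4 * n))
  anno <- data.frame(symbol = eff$gene, description = "x",
                     chromosome = "chr2")
  study <- expression_study(expr, anno, setNames(groups, colnames(expr)))
  degs <- classify_degs(contrast_all(study))
  affected <- eff[eff$truth_category != "none", ]
  hit <- mapply(function(g, cat, dir) {
    any(degs$gene == g & degs$direction == dir & degs$category == cat)
  }, affected$gene, affected$truth_category, affected$truth_direction)
  expect_gte(mean(hit), 0.90)
  # null genes should essentially never land in a category
  null_genes <- eff$gene[eff$truth_category == "none"]
  fp <- degs$category[degs$gene %in% null_genes] != "unassigned"
  expect_lte(mean(fp), 0.05)
})

test_that("top-ranked lists sort by FC with FDR then symbol tie-breaks", {
  ctr <- data.frame(gene = c("A", "B", "C", "D", "E"),
                    group = "HB",
                    fc = c(5, 3, 3, 1.5, -4),
                    p = c(0.001, 0.01, 0.001, 0.2, 0.001),
                    fdr = c(0.004, 0.03, 0.004, 0.4, 0.004))
  up <- top_ranked(ctr, "up")
  expect_equal(up$gene, c("A", "C", "B"))  # 5 first; tie at 3 -> C (fdr)
  expect_equal(top_ranked(ctr, "up", n = 2)$gene, c("A", "C"))
  expect_equal(top_ranked(ctr, "down")$gene, "E")
  # exact symbol tie-break
  ctr2 <- ctr; ctr2$fdr <- 0.004
  expect_equal(top_ranked(ctr2, "up")$gene, c("A", "B", "C"))
})

test_that("composition percentages reproduce printed arithmetic", {
  lab <- data.frame(group = c(rep("LB", 7), rep("MSI", 5)),
                    histology = c(rep("mucinous", 3), rep("NOS", 4),
                                  rep("NOS", 5)))
  comp <- composition_summary(lab, digits = 0)
  muc <- comp[comp$group == "LB" & comp$label == "mucinous", ]
  expect_equal(muc$k, 3); expect_equal(muc$n, 7)
  expect_equal(muc$pct, 43)
  # 5 of 32 at one decimal
  pat <- data.frame(group = rep("all", 32),
                    histology = c(rep("MSI", 5), rep("MSS", 27)))
  comp2 <- composition_summary(pat, digits = 1)
  expect_equal(comp2$pct[comp2$label == "MSI"], 15.6)
  expect_equal(comp2$pct[comp2$label == "MSS"], 84.4)
})
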