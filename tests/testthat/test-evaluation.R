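test_that("roc_auc matches the pairwise definition and its identities", {
  expect_equal(roc_auc(c(2, 3), c(1, 2.5)), 0.75) # 3 of 4 pairs
  expect_equal(roc_auc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(roc_auc(c(1, 1), c(1, 1)), 0.5)    # all ties credit 0.5
  set.seed(31)
  for (i in 1:50) {
    pos <- sample(seq(0, 3, 0.5), sample(1:8, 1), replace = TRUE)
    neg <- sample(seq(0, 3, 0.5), sample(1:8, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg), brute_auc(pos, neg))
    # complement symmetry, exact
    expect_equal(roc_auc(pos, neg) + roc_auc(neg, pos), 1)
    # invariance under a strictly increasing transform
    f <- function(x) exp(2 * x) + x
    expect_equal(roc_auc(f(pos), f(neg)), roc_auc(pos, neg))
  }
  err <- tryCatch(roc_auc(numeric(0), 1), condition = identity)
  expect_true(is_undefined_stratum(err))
  expect_error(roc_auc(c(1, NA), 1), "finite")
})

test_that("balanced_resample keeps the minority and balances every rep", {
  labels <- c(rep("pathogenic", 3), rep("benign", 10))
  plan <- balanced_resample(labels, n_reps = 100, seed = 5)
  for (idx in plan$reps) {
    expect_length(idx, 6) # 3 pathogenic + 3 sampled benign
    expect_equal(sum(labels[idx] == "pathogenic"), 3)
    expect_false(anyDuplicated(idx) > 0) # without replacement
    expect_true(all(which(labels == "pathogenic") %in% idx))
  }
  # deterministic given the seed
  plan2 <- balanced_resample(labels, n_reps = 100, seed = 5)
  expect_identical(plan$reps, plan2$reps)
  # majority-class subsampling also covers pathogenic-dominated strata
  rev_plan <- balanced_resample(rev(labels), n_reps = 10, seed = 5)
  expect_true(all(lengths(rev_plan$reps) == 6))
  err <- tryCatch(balanced_resample(rep("benign", 5), 10, 1),
                  condition = identity)
  expect_true(is_undefined_stratum(err))
})

test_that("balanced_auc summarizes per-rep AUCs; missing removed first", {
  ds <- make_dataset(c(5, 6, 1, 2), c("pathogenic", "pathogenic",
                                      "benign", "benign"))
  s <- balanced_auc(ds, "p1", n_reps = 10, seed = 1)
  expect_equal(s$mean_auc, 1.0)
  expect_equal(s$sd_auc, 0)
  expect_equal(mean(s$per_rep), s$mean_auc)
  expect_true(all(s$per_rep >= 0 & s$per_rep <= 1))
  # NA scores drop before the plan: reps stay exactly balanced
  ds2 <- make_dataset(c(5, NA, 1, 2, 0.5), c("pathogenic", "pathogenic",
                                             "benign", "benign", "benign"))
  s2 <- balanced_auc(ds2, "p1", n_reps = 25, seed = 2)
  expect_equal(s2$n_pos, 1)
  expect_equal(s2$n_neg, 3)
  expect_true(all(s2$per_rep %in% c(0, 1))) # 1 vs 1 comparisons only
})

test_that("stratified_auc routes by gene and derives per-side seeds", {
  sim <- generate_dataset(synthetic_config(
    n_genes = c(hi = 3, ad_only = 3, ar = 0, unlisted = 0),
    variants_per_gene = 30, seed = 21))
  ds <- harmonize_signs(sim$dataset)
  flags <- annotate_inheritance(ds, sim$gene_lists$hi, sim$gene_lists$ad,
                                sim$gene_lists$ar)
  st <- stratified_auc(ds, "foldx_like", group_predicate("haploinsufficient"),
                       flags, n_reps = 20, seed = 9)
  expect_s3_class(st$group, "auc_summary")
  expect_s3_class(st$complement, "auc_summary")
  genes_in_group <- unique(ds$variants$gene[ds$variants$gene %in%
                                              sim$gene_lists$hi])
  expect_length(genes_in_group, 3)
  # the group side must equal balanced_auc run on the group subset with
  # the same derived sub-seed (independent recomputability)
  idx <- which(ds$variants$gene %in% sim$gene_lists$hi)
  direct <- balanced_auc(subset_records(ds, idx), "foldx_like", n_reps = 20,
                         seed = derive_seed(9, "haploinsufficient", "foldx_like"),
                         stratum = "haploinsufficient")
  expect_identical(st$group$per_rep, direct$per_rep)

  # degenerate predicate: complement side reported undefined, group computed
  all_pred <- group_predicate("everything", function(f) rep(TRUE, nrow(f)))
  st_all <- stratified_auc(ds, "foldx_like", all_pred, flags,
                           n_reps = 20, seed = 9)
  expect_null(st_all$complement)
  expect_match(st_all$complement_reason, "no records")
  expect_s3_class(st_all$group, "auc_summary")
})

test_that("per_gene_auc skips underpowered genes and is gene-deterministic", {
  scores <- c(5, 4, 1, 2, 3, 3.5)
  labels <- c("pathogenic", "pathogenic", "benign", "benign",
              "benign", "benign")
  v <- data.frame(variant_id = sprintf("v%d", 1:12),
                  gene = rep(c("GOOD", "ONLYB"), each = 6),
                  label = c(labels, rep("benign", 6)),
                  p1 = c(scores, scores), stringsAsFactors = FALSE)
  ds <- variant_dataset(v, predictor_panel("p1"), harmonized = TRUE)
  pg <- per_gene_auc(ds, "p1", n_reps = 10, seed = 3)
  expect_equal(pg$table$gene, "GOOD")
  expect_equal(pg$skipped$gene, "ONLYB") # zero pathogenic -> skipped
  expect_equal(pg$table$mean_auc, 1.0)   # separated classes

  # same records under two gene names, equal class sizes: identical rows
  v2 <- data.frame(variant_id = sprintf("v%d", 1:8),
                   gene = rep(c("COPY1", "COPY2"), each = 4),
                   label = rep(c("pathogenic", "pathogenic",
                                 "benign", "benign"), 2),
                   p1 = rep(c(3, 1, 2, 4), 2), stringsAsFactors = FALSE)
  ds2 <- variant_dataset(v2, predictor_panel("p1"), harmonized = TRUE)
  pg2 <- per_gene_auc(ds2, "p1", n_reps = 10, seed = 3)
  expect_equal(pg2$table$mean_auc[1], pg2$table$mean_auc[2])
  expect_equal(pg2$table$sd_auc, c(0, 0))
})

test_that("precision_curve follows its defining counts and conventions", {
  ds <- make_dataset(c(5, 4, 3, 2), c("pathogenic", "pathogenic",
                                      "benign", "benign"))
  pc <- precision_curve(ds, "p1", thresholds = c(0, 3.5), n_reps = 5, seed = 1)
  expect_equal(pc$precision, c(0.5, 1.0)) # prevalence at 0; 2/2 above 3.5
  expect_equal(pc$n_above, c(4, 2))
  # threshold bound is closed: a score exactly at t counts as above
  pc2 <- precision_curve(ds, "p1", thresholds = c(0, 4), n_reps = 5, seed = 1)
  expect_equal(pc2$precision[2], 1.0)
  expect_equal(pc2$n_above[2], 2) # scores 5 and 4 both >= 4
  # unsupported grid points are absent, not zero-filled
  pc3 <- precision_curve(ds, "p1", thresholds = c(0, 99), n_reps = 5, seed = 1)
  expect_equal(pc3$threshold, 0)
  expect_error(precision_curve(ds, "p1", thresholds = c(2, 1), 5, 1),
               "strictly increasing")
  # unbalanced mode: one pass over the full stratum
  ds_imb <- make_dataset(c(5, 1, 2, 3), c("pathogenic", rep("benign", 3)))
  pu <- precision_curve(ds_imb, "p1", thresholds = c(0, 4), seed = 1,
                        balanced = FALSE)
  expect_equal(pu$precision, c(0.25, 1.0))
})

test_that("threshold_for_precision scans the grid with support", {
  ds <- make_dataset(c(5, 4, 3, 2), c("pathogenic", "pathogenic",
                                      "benign", "benign"))
  pc <- precision_curve(ds, "p1", thresholds = c(0, 1, 3.5, 4.5),
                        n_reps = 5, seed = 1)
  hit <- threshold_for_precision(pc, 0.9)
  expect_equal(hit$threshold, 3.5)
  expect_equal(hit$precision, 1.0)
  # target below the first point: first grid threshold
  expect_equal(threshold_for_precision(pc, 0.4)$threshold, 0)
  # unreachable target: NULL, not an error
  expect_null(threshold_for_precision(pc, 0.999, min_support = 10))
  expect_error(threshold_for_precision(pc, 1.2), "between 0 and 1")
})

test_that("evaluation results are bit-reproducible given the seeds", {
  sim <- generate_dataset(synthetic_config(
    n_genes = c(hi = 2, ad_only = 2, ar = 2, unlisted = 2),
    variants_per_gene = 25, seed = 77))
  ds <- harmonize_signs(sim$dataset)
  a1 <- balanced_auc(ds, "foldx_like", n_reps = 30, seed = 12)
  a2 <- balanced_auc(ds, "foldx_like", n_reps = 30, seed = 12)
  expect_identical(a1$per_rep, a2$per_rep)
  p1 <- precision_curve(ds, "foldx_like", n_reps = 30, seed = 12)
  p2 <- precision_curve(ds, "foldx_like", n_reps = 30, seed = 12)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})
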