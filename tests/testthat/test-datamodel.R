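test_that("read_variant_table parses, normalizes and handles missing cells", {
  path <- write_tiny_table()
  ds <- read_variant_table(path, tiny_column_map())
  expect_s3_class(ds, "variant_dataset")
  expect_false(ds$harmonized)
  expect_equal(nrow(ds$variants), 4)
  expect_equal(ds$panel$name, c("foldx", "inps"))
  expect_equal(ds$variants$label, c("pathogenic", "pathogenic",
                                    "benign", "benign"))
  # whitespace + case normalization
  expect_equal(ds$variants$gene, c("BRCA1", "TP53", "PTEN", "BRCA1"))
  # empty predictor cell -> record retained, value missing
  expect_true(is.na(ds$variants$inps[2]))
  expect_equal(ds$variants$foldx, c(2.5, 1.0, -0.5, 0.0))
})

test_that("read_variant_table hard errors are specific", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("id\tsymbol\tclinvar\tfoldx",
               "v1\tA\tpathogenic\t1",
               "v1\tB\tbenign\t2"), dup)
  expect_error(read_variant_table(dup, list(
    variant_id = "id", gene = "symbol", label = "clinvar",
    predictors = "foldx")), "duplicate variant_id")

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("id\tsymbol\tclinvar\tfoldx",
               "v1\tA\tuncertain significance\t1"), bad)
  expect_error(read_variant_table(bad, list(
    variant_id = "id", gene = "symbol", label = "clinvar",
    predictors = "foldx")), "unmappable label.*uncertain")

  expect_error(read_variant_table(dup, list(
    variant_id = "id", gene = "symbol", label = "clinvar",
    predictors = "nope")), "columns absent")
  expect_error(read_variant_table(dup, list(
    variant_id = "id", gene = "symbol", label = "clinvar",
    predictors = character(0))), "at least one predictor")
})

test_that("read_gene_list skips comments/blanks, dedups and normalizes", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "genes.txt")
  writeLines(c("# curated list", "BRCA1", "", "TP53", "tp53", " PTEN "), f)
  expect_equal(read_gene_list(f), c("BRCA1", "TP53", "PTEN"))
  writeLines("# only a comment", f)
  expect_warning(g <- read_gene_list(f), "empty")
  expect_length(g, 0)
})

test_that("harmonize_signs flips negative conventions and preserves |ddG|", {
  v <- data.frame(variant_id = c("a", "b", "c"), gene = "G1",
                  label = c("pathogenic", "benign", "benign"),
                  pos_tool = c(1.3, -2.0, NA),
                  neg_tool = c(-2.5, 0.7, NA))
  panel <- predictor_panel(c("pos_tool", "neg_tool"),
                           c("positive_destabilizing", "negative_destabilizing"))
  ds <- variant_dataset(v, panel)
  h <- harmonize_signs(ds)
  expect_true(h$harmonized)
  expect_equal(h$variants$neg_tool, c(2.5, -0.7, NA))
  expect_equal(h$variants$pos_tool, c(1.3, -2.0, NA)) # identity for pos
  expect_true(all(h$panel$sign_convention == "positive_destabilizing"))
  # |ddG| preserved for every record x predictor
  for (p in c("pos_tool", "neg_tool")) {
    expect_equal(abs(h$variants[[p]]), abs(ds$variants[[p]]))
  }
  expect_error(harmonize_signs(h), "already harmonized")
  expect_error(set_conventions(h, panel), "after harmonization")
  # negation is an involution on the stored values
  expect_equal(-(-ds$variants$neg_tool), ds$variants$neg_tool)
})

test_that("convention map round-trips through YAML and applies to a panel", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "conv.yaml")
  writeLines(c("foldx: {sign: pos, cap: null}",
               "inps: {sign: neg, cap: 10}"), f)
  conv <- read_convention_map(f)
  expect_equal(conv$sign_convention,
               c("positive_destabilizing", "negative_destabilizing"))
  expect_equal(conv$cap, c(NA, 10))
  ds <- read_variant_table(write_tiny_table(dir), tiny_column_map())
  ds <- set_conventions(ds, conv)
  expect_equal(ds$panel$cap, c(NA, 10))
  h <- harmonize_signs(ds)
  expect_equal(h$variants$inps, c(3.0, NA, 0.2, -1.5))
  # the shipped default map covers the full 13-tool panel
  shipped <- read_convention_map(system.file(
    "extdata", "predictor_conventions.yaml", package = "ddgpath"))
  expect_equal(nrow(shipped), 13)
  expect_true(all(is.na(shipped$cap) | shipped$cap > 0))
})

test_that("inheritance annotation and canonical predicates route genes", {
  ds <- make_dataset(rep(1, 4), c("pathogenic", "benign", "pathogenic", "benign"),
                     genes = c("HIAD", "ARONLY", "NOWHERE", "ADONLY"))
  flags <- annotate_inheritance(ds, hi = "HIAD", ad = c("HIAD", "ADONLY"),
                                ar = "ARONLY")
  expect_equal(flags$is_hi, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags$is_ad, c(TRUE, FALSE, FALSE, TRUE))
  preds <- canonical_predicates()
  # gene in both hi and ad lists: haploinsufficient, excluded from
  # dominant_not_hi (HI takes precedence over plain dominance)
  expect_true(preds$haploinsufficient$member_test(flags)[1])
  expect_false(preds$dominant_not_hi$member_test(flags)[1])
  expect_true(preds$dominant_not_hi$member_test(flags)[4])
  expect_true(preds$recessive$member_test(flags)[2])
  # gene in no list: member of no group (only complements)
  expect_false(any(vapply(preds, function(p) p$member_test(flags)[3],
                          logical(1))))
})

test_that("haploinsufficient and dominant_not_hi are disjoint on any flags", {
  preds <- canonical_predicates()
  set.seed(42)
  for (i in 1:20) {
    flags <- data.frame(gene = paste0("G", 1:30),
                        is_hi = sample(c(TRUE, FALSE), 30, TRUE),
                        is_ad = sample(c(TRUE, FALSE), 30, TRUE),
                        is_ar = sample(c(TRUE, FALSE), 30, TRUE))
    both <- preds$haploinsufficient$member_test(flags) &
      preds$dominant_not_hi$member_test(flags)
    expect_false(any(both))
  }
})

test_that("abs_scores takes absolute values with pairwise deletion", {
  ds <- make_dataset(c(-3.2, 0, NA, 1.5),
                     c("pathogenic", "pathogenic", "benign", "benign"))
  s <- abs_scores(ds, "p1")
  expect_equal(s$pathogenic, c(3.2, 0)) # stabilizing -3.2 scores 3.2
  expect_equal(s$benign, 1.5)           # NA record excluded from both sides
  all_na <- make_dataset(c(1, NA), c("pathogenic", "benign"))
  err <- tryCatch(abs_scores(all_na, "p1"), condition = identity)
  expect_true(is_undefined_stratum(err))
  expect_error(abs_scores(ds, "ghost"), "unknown predictor")
})

test_that("variant table write/read round trip is numerically exact", {
  sim <- generate_dataset(synthetic_config(
    n_genes = c(hi = 2, ad_only = 2, ar = 2, unlisted = 2),
    variants_per_gene = 10, seed = 11))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.tsv")
  write_variant_table(sim$dataset, path)
  back <- read_variant_table(path, list(
    variant_id = "variant_id", gene = "gene", label = "label",
    predictors = predictors(sim$dataset)))
  for (p in predictors(sim$dataset)) {
    expect_identical(back$variants[[p]], sim$dataset$variants[[p]])
  }
  expect_identical(back$variants$variant_id, sim$dataset$variants$variant_id)
})
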