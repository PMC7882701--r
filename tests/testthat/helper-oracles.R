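# Independent oracles and small fixture builders shared across tests.

# Brute-force pairwise AUC: fraction of (pos, neg) pairs won, ties 0.5.
brute_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Exhaustive Mann-Whitney p by enumerating all C(n, n_a) assignments of the
# observed (tie-free) values to sample a.
enum_mw_p <- function(a, b, alternative = "two_sided") {
  vals <- c(a, b)
  n <- length(vals)
  na <- length(a)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_less <- mean(us <= u_obs)
  p_greater <- mean(us >= u_obs)
  switch(alternative,
         two_sided = min(1, 2 * min(p_less, p_greater)),
         greater = p_greater,
         less = p_less)
}

# All multisets of size k from `values` (combinations with repetition).
multisets <- function(values, k) {
  n <- length(values)
  comb <- utils::combn(n + k - 1, k)
  lapply(seq_len(ncol(comb)), function(j) {
    values[comb[, j] - seq_len(k) + 1]
  })
}

# Minimal harmonized dataset from explicit score/label vectors for one
# predictor named "p1" (single gene unless genes given).
make_dataset <- function(scores, labels, genes = "G1",
                         harmonized = TRUE, predictor = "p1") {
  v <- data.frame(
    variant_id = sprintf("v%03d", seq_along(scores)),
    gene = rep_len(genes, length(scores)),
    label = labels,
    stringsAsFactors = FALSE)
  v[[predictor]] <- scores
  variant_dataset(v, predictor_panel(predictor), harmonized = harmonized)
}

# A small raw variant table on disk; returns its path.
write_tiny_table <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "variants.tsv")
  writeLines(c(
    "id\tsymbol\tclinvar\tfoldx\tinps",
    "v1\tBRCA1\tPathogenic\t2.5\t-3.0",
    "v2\t tp53 \tLikely pathogenic\t1.0\t",
    "v3\tPTEN\tBenign\t-0.5\t-0.2",
    "v4\tBRCA1\tgnomAD\t0.0\t1.5"
  ), path)
  path
}

tiny_column_map <- function() {
  list(variant_id = "id", gene = "symbol", label = "clinvar",
       predictors = c(foldx = "foldx", inps = "inps"))
}
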