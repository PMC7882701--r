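#' ROC AUC of pathogenic versus benign scores
#'
#' The area under the ROC curve of a score for separating the two classes,
#' computed as the normalized Mann-Whitney rank-sum statistic: the fraction
#' of (pathogenic, benign) pairs in which the pathogenic variant scores
#' higher, with tied pairs credited 0.5. Higher score is taken to mean more
#' pathogenic.
#'
#' @param pos_scores,neg_scores non-empty finite numeric vectors of scores
#'   for pathogenic and benign variants.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(2, 3), c(1, 2.5)) # 3 of 4 pairs won -> 0.75
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    undefined_stratum("roc_auc: empty score vector")
  }
  if (!all(is.finite(pos_scores)) || !all(is.finite(neg_scores))) {
    stop("roc_auc: scores must be finite")
  }
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores)) # midranks handle ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Balanced resampling plan
#'
#' Removes class-imbalance bias: in each of `n_reps` replicates, every
#' record of the minority class is kept and an equal-sized subset of the
#' majority class is drawn uniformly without replacement. When the classes
#' are already equal every replicate is the full set (no sampling freedom).
#' The upstream benchmark subsampled the benign excess; subsampling the
#' majority class generalizes that to strata where pathogenic variants
#' dominate.
#'
#' @param labels character vector of `"pathogenic"`/`"benign"` labels, one
#'   per record.
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed; the plan is deterministic given it.
#' @return an object of class `resample_plan`: list with `n_reps`, `seed`,
#'   and `reps`, a list of integer index vectors into `labels`.
#' @export
balanced_resample <- function(labels, n_reps = 100, seed) {
  stopifnot(n_reps >= 1, !missing(seed))
  idx_pos <- which(labels == "pathogenic")
  idx_neg <- which(labels == "benign")
  if (length(idx_pos) == 0 || length(idx_neg) == 0) {
    undefined_stratum("balanced_resample: a class is empty")
  }
  if (length(idx_pos) <= length(idx_neg)) {
    minority <- idx_pos; majority <- idx_neg
  } else {
    minority <- idx_neg; majority <- idx_pos
  }
  k <- length(minority)
  reps <- if (length(majority) == k) {
    replicate(n_reps, c(minority, majority), simplify = FALSE)
  } else {
    with_seed(seed, replicate(
      n_reps, c(minority, sample(majority, k, replace = FALSE)),
      simplify = FALSE))
  }
  structure(list(n_reps = as.integer(n_reps), seed = seed, reps = reps),
            class = "resample_plan")
}

# Shared core: per-replicate AUCs for pre-extracted scores and labels.
auc_over_plan <- function(scores, labels, plan) {
  vapply(plan$reps, function(idx) {
    s <- scores[idx]
    l <- labels[idx]
    roc_auc(s[l == "pathogenic"], s[l == "benign"])
  }, numeric(1))
}

new_auc_summary <- function(predictor, stratum, per_rep, n_pos, n_neg) {
  structure(list(
    predictor = predictor, stratum = stratum,
    mean_auc = mean(per_rep), sd_auc = stats::sd(per_rep),
    per_rep = per_rep, n_pos = n_pos, n_neg = n_neg
  ), class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat(sprintf(
    "AUC[%s | %s] = %.4f (sd %.4f over %d balanced reps; %d pathogenic / %d benign)\n",
    x$predictor, x$stratum, x$mean_auc, x$sd_auc, length(x$per_rep),
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Balanced-resampling AUC for one predictor
#'
#' Scores are |ddG| values of the predictor. Records missing the predictor
#' are removed BEFORE the resample plan is built, so every replicate is
#' exactly balanced among scored records. Per replicate, [roc_auc()] is
#' computed on the replicate's records; the summary averages over
#' replicates.
#'
#' @param dataset a harmonized [variant_dataset()].
#' @param predictor a panel predictor name.
#' @param n_reps,seed plan parameters (ignored if `plan` given).
#' @param plan optionally a precomputed [balanced_resample()] plan over the
#'   predictor's scored records.
#' @param stratum label stored in the summary (default `"all"`).
#' @return an `auc_summary`: `predictor`, `stratum`, `mean_auc`, `sd_auc`,
#'   `per_rep`, and the pre-balancing class counts `n_pos`, `n_neg`.
#' @export
balanced_auc <- function(dataset, predictor, n_reps = 100, seed,
                         plan = NULL, stratum = "all") {
  stopifnot(inherits(dataset, "variant_dataset"))
  if (!dataset$harmonized) stop("harmonize_signs() must run before balanced_auc()")
  if (!predictor %in% dataset$panel$name) stop("unknown predictor: ", predictor)
  v <- dataset$variants[[predictor]]
  keep <- !is.na(v)
  scores <- abs(v[keep])
  labels <- dataset$variants$label[keep]
  if (is.null(plan)) plan <- balanced_resample(labels, n_reps, seed)
  per_rep <- auc_over_plan(scores, labels, plan)
  new_auc_summary(predictor, stratum, per_rep,
                  n_pos = sum(labels == "pathogenic"),
                  n_neg = sum(labels == "benign"))
}

#' Balanced AUC for a gene group and its complement
#'
#' Routes records by their gene's value under the predicate, then runs
#' [balanced_auc()] independently on the group and on its complement (all
#' records whose genes fail the predicate), each with its own derived
#' sub-seed, so either side can be recomputed in isolation with identical
#' results. A side with an empty class is reported as undefined (with the
#' condition message) while the other side is still computed.
#'
#' @param dataset a harmonized [variant_dataset()].
#' @param predictor a panel predictor name.
#' @param predicate a [group_predicate()].
#' @param flags inheritance flags table covering all dataset genes
#'   (see [annotate_inheritance()]).
#' @param n_reps,seed plan parameters; sub-seeds are derived per side.
#' @return list of class `stratified_auc` with elements `group` and
#'   `complement`, each an `auc_summary` or `NULL` (then the matching
#'   `*_reason` element explains why).
#' @export
stratified_auc <- function(dataset, predictor, predicate, flags,
                           n_reps = 100, seed) {
  stopifnot(inherits(predicate, "group_predicate"))
  uncovered <- setdiff(unique(dataset$variants$gene), flags$gene)
  if (length(uncovered)) {
    stop("flags table does not cover genes: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  }
  member_genes <- flags$gene[predicate$member_test(flags)]
  in_group <- dataset$variants$gene %in% member_genes
  side <- function(idx, label) {
    if (!any(idx)) return(list(NULL, "no records"))
    tryCatch(
      list(balanced_auc(subset_records(dataset, which(idx)), predictor,
                        n_reps = n_reps,
                        seed = derive_seed(seed, label, predictor),
                        stratum = label), NA_character_),
      ddgpath_undefined_stratum = function(e) list(NULL, conditionMessage(e)))
  }
  g <- side(in_group, predicate$group_name)
  comp_label <- paste0("not_", predicate$group_name)
  c_ <- side(!in_group, comp_label)
  structure(list(group = g[[1]], complement = c_[[1]],
                 group_reason = g[[2]], complement_reason = c_[[2]],
                 group_name = predicate$group_name, predictor = predictor),
            class = "stratified_auc")
}

#' Per-gene balanced AUC
#'
#' Applies the balanced-resampling AUC to each gene separately. Genes with
#' fewer than `min_per_class` scored records in either class are skipped
#' and listed in the skip report. Each gene gets a derived sub-seed, so the
#' result for a gene does not depend on which other genes are present.
#'
#' @param dataset a harmonized [variant_dataset()].
#' @param predictor a panel predictor name.
#' @param n_reps,seed plan parameters.
#' @param min_per_class minimum scored records per class (default 1; the
#'   upstream benchmark already required 10+ pathogenic variants per
#'   protein, which is not re-imposed here).
#' @return object of class `per_gene_auc`: `table` (`data.frame` with gene,
#'   mean_auc, sd_auc, n_pos, n_neg), `summaries` (named list of
#'   `auc_summary`), and `skipped` (`data.frame` gene/n_pos/n_neg/reason).
#' @export
per_gene_auc <- function(dataset, predictor, n_reps = 100, seed,
                         min_per_class = 1) {
  stopifnot(min_per_class >= 1)
  if (!dataset$harmonized) stop("harmonize_signs() must run before per_gene_auc()")
  genes <- sort(unique(dataset$variants$gene))
  summaries <- list()
  skipped <- list()
  for (g in genes) {
    idx <- which(dataset$variants$gene == g)
    v <- dataset$variants[[predictor]][idx]
    lab <- dataset$variants$label[idx][!is.na(v)]
    n_pos <- sum(lab == "pathogenic")
    n_neg <- sum(lab == "benign")
    if (n_pos < min_per_class || n_neg < min_per_class) {
      skipped[[g]] <- data.frame(
        gene = g, n_pos = n_pos, n_neg = n_neg,
        reason = sprintf("fewer than %d scored records in a class",
                         min_per_class),
        stringsAsFactors = FALSE)
      next
    }
    summaries[[g]] <- balanced_auc(
      subset_records(dataset, idx), predictor, n_reps = n_reps,
      seed = derive_seed(seed, "gene", g, predictor), stratum = g)
  }
  tab <- if (length(summaries)) {
    do.call(rbind, lapply(summaries, function(s) data.frame(
      gene = s$stratum, mean_auc = s$mean_auc, sd_auc = s$sd_auc,
      n_pos = s$n_pos, n_neg = s$n_neg, stringsAsFactors = FALSE)))
  } else {
    data.frame(gene = character(0), mean_auc = numeric(0),
               sd_auc = numeric(0), n_pos = integer(0), n_neg = integer(0))
  }
  rownames(tab) <- NULL
  structure(list(
    predictor = predictor, table = tab, summaries = summaries,
    skipped = if (length(skipped)) do.call(rbind, c(skipped, make.row.names = FALSE))
              else data.frame(gene = character(0), n_pos = integer(0),
                              n_neg = integer(0), reason = character(0))
  ), class = "per_gene_auc")
}

#' Precision-versus-threshold enrichment curve
#'
#' For a grid of |ddG| thresholds t, the precision (positive predictive
#' value) is the fraction of variants scoring `>= t` (closed lower bound)
#' that are truly pathogenic. By default it is averaged over balanced
#' replicates, so precision at t = 0 equals the balanced prevalence 0.5
#' exactly; `balanced = FALSE` computes a single pass over the full,
#' imbalanced stratum instead. Replicates where no record reaches t do not
#' contribute to the average; grid points unsupported in every replicate
#' are absent from the curve, not zero-filled.
#'
#' @param dataset a harmonized [variant_dataset()].
#' @param predictor a panel predictor name.
#' @param thresholds strictly increasing non-negative grid (kcal/mol);
#'   default 0 to the stratum's maximum |ddG| in steps of 0.1.
#' @param n_reps,seed plan parameters (ignored when `balanced = FALSE` or
#'   `plan` given).
#' @param plan optional precomputed [balanced_resample()] plan.
#' @param balanced average over balanced replicates (default) or use the
#'   full stratum once.
#' @param stratum label stored on the curve.
#' @return object of class `precision_curve`: a `data.frame` with columns
#'   `threshold`, `precision`, `n_above` (mean records above t per
#'   contributing replicate) and `n_reps_used`, plus attributes `predictor`
#'   and `stratum`. Empty (zero rows, with a warning) if no point has
#'   support.
#' @export
precision_curve <- function(dataset, predictor, thresholds = NULL,
                            n_reps = 100, seed, plan = NULL,
                            balanced = TRUE, stratum = "all") {
  if (!dataset$harmonized) stop("harmonize_signs() must run before precision_curve()")
  if (!predictor %in% dataset$panel$name) stop("unknown predictor: ", predictor)
  v <- dataset$variants[[predictor]]
  keep <- !is.na(v)
  scores <- abs(v[keep])
  labels <- dataset$variants$label[keep]
  if (length(scores) == 0) undefined_stratum("precision_curve: no scored records")
  if (is.null(thresholds)) {
    thresholds <- seq(0, max(scores), by = 0.1)
  }
  if (any(thresholds < 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing and non-negative")
  }
  reps <- if (balanced) {
    if (is.null(plan)) plan <- balanced_resample(labels, n_reps, seed)
    plan$reps
  } else {
    list(seq_along(scores))
  }
  nt <- length(thresholds)
  above <- matrix(0, length(reps), nt)
  path_above <- matrix(0, length(reps), nt)
  for (r in seq_along(reps)) {
    s <- scores[reps[[r]]]
    p <- s[labels[reps[[r]]] == "pathogenic"]
    above[r, ] <- vapply(thresholds, function(t) sum(s >= t), numeric(1))
    path_above[r, ] <- vapply(thresholds, function(t) sum(p >= t), numeric(1))
  }
  n_used <- colSums(above > 0)
  prec <- vapply(seq_len(nt), function(j) {
    ok <- above[, j] > 0
    if (!any(ok)) return(NA_real_)
    mean(path_above[ok, j] / above[ok, j])
  }, numeric(1))
  supp <- vapply(seq_len(nt), function(j) {
    ok <- above[, j] > 0
    if (!any(ok)) return(NA_real_)
    mean(above[ok, j])
  }, numeric(1))
  curve <- data.frame(threshold = thresholds, precision = prec,
                      n_above = supp, n_reps_used = n_used)
  curve <- curve[n_used > 0, , drop = FALSE]
  rownames(curve) <- NULL
  if (nrow(curve) == 0) {
    warning("precision curve has no supported grid point")
  }
  structure(curve, predictor = predictor, stratum = stratum,
            balanced = balanced,
            class = c("precision_curve", "data.frame"))
}

#' Smallest threshold reaching a target precision
#'
#' Scans the curve for the smallest grid threshold whose estimated
#' precision reaches `target` with mean support of at least `min_support`
#' records above the threshold.
#'
#' @param curve a [precision_curve()].
#' @param target required precision, strictly between 0 and 1.
#' @param min_support minimum mean number of records above the threshold
#'   (default 1).
#' @return `NULL` when the target is unreachable on the grid; otherwise a
#'   list with `threshold`, `precision` (achieved) and `n_above` (support).
#' @export
threshold_for_precision <- function(curve, target, min_support = 1) {
  stopifnot(inherits(curve, "precision_curve"))
  if (!is.numeric(target) || length(target) != 1 ||
      target <= 0 || target >= 1) {
    stop("target must be a number strictly between 0 and 1")
  }
  if (nrow(curve) == 0) return(NULL)
  ok <- which(curve$precision >= target & curve$n_above >= min_support)
  if (length(ok) == 0) return(NULL)
  i <- ok[1]
  list(threshold = curve$threshold[i], precision = curve$precision[i],
       n_above = curve$n_above[i])
}
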