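#' Mann-Whitney U test
#'
#' Two-sample rank test. U is computed with midranks for ties and counts,
#' for sample `a`, the number of (a, b) pairs won plus half the ties
#' (`U = n_a * n_b * AUC(a vs b)`). The p-value uses the exact permutation
#' null distribution when the combined sample size is at most 16 and there
#' are no ties, and otherwise a normal approximation with tie correction
#' and continuity correction. p is clamped into (0, 1].
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param alternative `"two_sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @return list with `u_statistic`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_a`, `n_b`, `alternative`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact two-sided p = 0.1
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("mann_whitney_u: samples must be non-empty")
  }
  na <- length(sample_a)
  nb <- length(sample_b)
  combined <- c(sample_a, sample_b)
  r <- rank(combined)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(combined) > 0
  exact <- (na + nb) <= 16 && !ties
  if (exact) {
    # exact null CDF of U (stats::pwilcox); U is integer when tie-free
    p_less <- stats::pwilcox(u, na, nb)
    p_greater <- stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_less, p_greater)),
                greater = p_greater,
                less = p_less)
    method <- "exact"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(combined)
    sigma2 <- (na * nb / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      # all observations identical: no evidence either way
      p <- 1
    } else {
      cc <- switch(alternative, # continuity correction
                   two_sided = sign(u - mu) * 0.5,
                   greater = 0.5, less = -0.5)
      z <- (u - mu - cc) / sigma
      p <- switch(alternative,
                  two_sided = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)),
                  greater = stats::pnorm(z, lower.tail = FALSE),
                  less = stats::pnorm(z))
    }
    method <- "normal_approx"
  }
  p <- min(1, max(p, .Machine$double.xmin)) # clamp into (0, 1]
  list(u_statistic = u, p_value = p, method = method,
       n_a = na, n_b = nb, alternative = alternative)
}

#' Compare a gene group against its complement
#'
#' Nonparametric comparison of predictor performance between a gene group
#' and all other genes. The default exchangeable unit is the gene: the
#' per-gene mean balanced AUCs of group genes are compared with those of
#' complement genes by a two-sided Mann-Whitney U test. The alternative
#' unit `"per_rep_auc"` compares the per-replicate AUCs of the pooled group
#' stratum against the pooled complement stratum; replicates of one pooled
#' stratum share records and are mutually dependent, so that mode is
#' anticonservative and labelled as such.
#'
#' @param per_gene a [per_gene_auc()] result (used for the per-gene unit).
#' @param predicate a [group_predicate()].
#' @param flags inheritance flags table from [annotate_inheritance()].
#' @param unit `"per_gene_mean_auc"` (default) or `"per_rep_auc"`.
#' @param stratified a [stratified_auc()] result; required for the
#'   per-replicate unit.
#' @param alternative passed to [mann_whitney_u()]; two-sided by default.
#' @return object of class `group_comparison`: `predictor`, `group_name`,
#'   `unit`, `n_group`, `n_complement`, `u_statistic`, `p_value`,
#'   `computable` and (if not computable) `reason`. Fewer than 2 genes on
#'   either side makes the per-gene comparison not-computable (reported,
#'   not raised).
#' @export
compare_group_vs_complement <- function(per_gene = NULL, predicate, flags,
                                        unit = c("per_gene_mean_auc", "per_rep_auc"),
                                        stratified = NULL,
                                        alternative = "two_sided") {
  unit <- match.arg(unit)
  stopifnot(inherits(predicate, "group_predicate"))
  not_computable <- function(predictor, reason, n_g = 0L, n_c = 0L) {
    structure(list(predictor = predictor, group_name = predicate$group_name,
                   unit = unit, n_group = n_g, n_complement = n_c,
                   u_statistic = NA_real_, p_value = NA_real_,
                   computable = FALSE, reason = reason),
              class = "group_comparison")
  }
  if (unit == "per_gene_mean_auc") {
    stopifnot(inherits(per_gene, "per_gene_auc"))
    tab <- per_gene$table
    if (nrow(tab) == 0) {
      return(not_computable(per_gene$predictor, "empty per-gene table"))
    }
    member_genes <- flags$gene[predicate$member_test(flags)]
    in_group <- tab$gene %in% member_genes
    a <- tab$mean_auc[in_group]
    b <- tab$mean_auc[!in_group]
    if (length(a) < 2 || length(b) < 2) {
      return(not_computable(per_gene$predictor,
                            "fewer than 2 genes on one side",
                            length(a), length(b)))
    }
    predictor <- per_gene$predictor
  } else {
    stopifnot(inherits(stratified, "stratified_auc"))
    if (is.null(stratified$group) || is.null(stratified$complement)) {
      return(not_computable(stratified$predictor,
                            "undefined group or complement stratum"))
    }
    a <- stratified$group$per_rep
    b <- stratified$complement$per_rep
    predictor <- stratified$predictor
  }
  mw <- mann_whitney_u(a, b, alternative = alternative)
  structure(list(predictor = predictor, group_name = predicate$group_name,
                 unit = unit, n_group = length(a), n_complement = length(b),
                 u_statistic = mw$u_statistic, p_value = mw$p_value,
                 computable = TRUE, reason = NA_character_),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!x$computable) {
    cat(sprintf("comparison[%s | %s]: not computable (%s)\n",
                x$predictor, x$group_name, x$reason))
  } else {
    cat(sprintf(
      "comparison[%s | %s vs complement, %s]: U = %g, p = %.3g (n = %d vs %d)\n",
      x$predictor, x$group_name, x$unit, x$u_statistic, x$p_value,
      x$n_group, x$n_complement))
  }
  invisible(x)
}
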