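`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a validated run configuration
#'
#' Exactly one input route must be set: either real input paths (variant
#' table + column map + gene lists, optionally a convention map) or a
#' synthetic source (a [synthetic_config()] or the string
#' `"paper_shape"` for [emulate_paper_shape()]). A seed is mandatory —
#' there is no silent nondeterminism.
#'
#' @param input list with `variant_table`, `column_map`, `gene_lists`
#'   (list with `hi`, `ad`, `ar` paths) and optional `conventions` path.
#' @param synthetic a [synthetic_config()] or `"paper_shape"`.
#' @param predictors predictors to evaluate (`NULL` = whole panel).
#' @param consensus list of character vectors, each the member set of a
#'   consensus pseudo-predictor to add.
#' @param n_reps balanced replicates (default 100).
#' @param seed master integer seed (required).
#' @param thresholds precision grid (`NULL` = 0 to stratum max by 0.1).
#' @param precision_targets precision levels the threshold finder reports.
#' @param min_support minimum mean support for a reported threshold.
#' @param comparison_unit `"per_gene_mean_auc"` or `"per_rep_auc"`.
#' @param balanced_precision average precision over balanced replicates
#'   (default) or compute it once on the imbalanced stratum.
#' @param min_per_class per-gene AUC skip threshold.
#' @param destabilizing also produce destabilizing-only analyses.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL, predictors = NULL,
                       consensus = list(), n_reps = 100, seed,
                       thresholds = NULL,
                       precision_targets = c(0.9, 0.96), min_support = 10,
                       comparison_unit = "per_gene_mean_auc",
                       balanced_precision = TRUE, min_per_class = 1,
                       destabilizing = TRUE) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of 'input' and 'synthetic' must be set")
  }
  if (!is.null(input)) {
    for (f in c("variant_table", "column_map", "gene_lists")) {
      if (is.null(input[[f]])) stop("input lacks field: ", f)
    }
  } else if (!identical(synthetic, "paper_shape") &&
             !inherits(synthetic, "synthetic_config")) {
    stop("synthetic must be a synthetic_config or \"paper_shape\"")
  }
  stopifnot(n_reps >= 1, min_support >= 0, min_per_class >= 1,
            all(precision_targets > 0 & precision_targets < 1))
  comparison_unit <- match.arg(comparison_unit,
                               c("per_gene_mean_auc", "per_rep_auc"))
  structure(list(input = input, synthetic = synthetic,
                 predictors = predictors, consensus = consensus,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 thresholds = thresholds,
                 precision_targets = precision_targets,
                 min_support = min_support,
                 comparison_unit = comparison_unit,
                 balanced_precision = isTRUE(balanced_precision),
                 min_per_class = min_per_class,
                 destabilizing = isTRUE(destabilizing)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Mirrors the [run_config()] arguments as YAML keys; a `synthetic`
#' section may be `paper_shape` or a mapping accepted by
#' [synthetic_config()].
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synthetic <- raw$synthetic
  if (!is.null(synthetic) && !identical(synthetic, "paper_shape")) {
    args <- synthetic
    for (f in c("n_genes", "delta")) {
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    }
    synthetic <- do.call(synthetic_config, args)
  }
  input <- raw$input
  if (!is.null(input$column_map$predictors)) {
    input$column_map$predictors <- unlist(input$column_map$predictors)
  }
  run_config(
    input = input, synthetic = synthetic,
    predictors = raw$predictors,
    consensus = lapply(raw$consensus, unlist),
    n_reps = raw$n_reps %||% 100, seed = raw$seed,
    thresholds = raw$thresholds,
    precision_targets = unlist(raw$precision_targets) %||% c(0.9, 0.96),
    min_support = raw$min_support %||% 10,
    comparison_unit = raw$comparison_unit %||% "per_gene_mean_auc",
    balanced_precision = raw$balanced_precision %||% TRUE,
    min_per_class = raw$min_per_class %||% 1,
    destabilizing = raw$destabilizing %||% TRUE)
}

auc_summary_row <- function(s) {
  data.frame(predictor = s$predictor, stratum = s$stratum,
             mean_auc = s$mean_auc, sd_auc = s$sd_auc,
             n_pos = s$n_pos, n_neg = s$n_neg, stringsAsFactors = FALSE)
}

# (1) Fig-1-style ranking, (2) group/complement + Mann-Whitney,
# (3) precision curves + thresholds, for one (possibly filtered) dataset.
analyse_dataset <- function(ds, preds, flags, config, tag) {
  predicates <- canonical_predicates()
  ranking <- do.call(rbind, lapply(preds, function(p) {
    s <- tryCatch(
      balanced_auc(ds, p, n_reps = config$n_reps,
                   seed = derive_seed(config$seed, tag, "all", p)),
      ddgpath_undefined_stratum = function(e) NULL)
    if (is.null(s)) return(NULL)
    auc_summary_row(s)
  }))
  group_rows <- list(); comp_rows <- list(); skip_rows <- list()
  for (p in preds) {
    pg <- per_gene_auc(ds, p, n_reps = config$n_reps,
                       seed = derive_seed(config$seed, tag, "per_gene", p),
                       min_per_class = config$min_per_class)
    if (nrow(pg$skipped)) {
      skip_rows[[p]] <- cbind(predictor = p, pg$skipped)
    }
    for (predicate in predicates) {
      st <- stratified_auc(ds, p, predicate, flags, n_reps = config$n_reps,
                           seed = derive_seed(config$seed, tag, "strata"))
      for (side in c("group", "complement")) {
        s <- st[[side]]
        row <- if (is.null(s)) {
          data.frame(predictor = p, stratum = NA_character_,
                     mean_auc = NA_real_, sd_auc = NA_real_,
                     n_pos = NA_integer_, n_neg = NA_integer_,
                     stringsAsFactors = FALSE)
        } else {
          auc_summary_row(s)
        }
        row$group <- predicate$group_name
        row$side <- side
        row$reason <- st[[paste0(side, "_reason")]]
        group_rows[[paste(p, predicate$group_name, side)]] <- row
      }
      cmp <- compare_group_vs_complement(
        per_gene = pg, predicate = predicate, flags = flags,
        unit = config$comparison_unit, stratified = st)
      comp_rows[[paste(p, predicate$group_name)]] <- data.frame(
        predictor = p, group = predicate$group_name,
        unit = cmp$unit, n_group = cmp$n_group,
        n_complement = cmp$n_complement, u_statistic = cmp$u_statistic,
        p_value = cmp$p_value, computable = cmp$computable,
        stringsAsFactors = FALSE)
    }
  }
  # precision on haploinsufficient vs non-haploinsufficient plus all
  hi_genes <- flags$gene[flags$is_hi]
  in_hi <- ds$variants$gene %in% hi_genes
  strata <- list(all = seq_len(nrow(ds$variants)))
  if (any(in_hi)) strata$haploinsufficient <- which(in_hi)
  if (any(!in_hi)) strata$not_haploinsufficient <- which(!in_hi)
  prec_rows <- list(); thr_rows <- list()
  for (p in preds) {
    for (sname in names(strata)) {
      sub <- subset_records(ds, strata[[sname]])
      curve <- tryCatch(
        suppressWarnings(precision_curve(
          sub, p, thresholds = config$thresholds, n_reps = config$n_reps,
          seed = derive_seed(config$seed, tag, "precision", sname, p),
          balanced = config$balanced_precision, stratum = sname)),
        ddgpath_undefined_stratum = function(e) NULL)
      if (is.null(curve) || nrow(curve) == 0) next
      prec_rows[[paste(p, sname)]] <- cbind(
        predictor = p, stratum = sname, as.data.frame(curve))
      for (target in config$precision_targets) {
        hit <- threshold_for_precision(curve, target, config$min_support)
        thr_rows[[paste(p, sname, target)]] <- data.frame(
          predictor = p, stratum = sname, target = target,
          threshold = hit$threshold %||% NA_real_,
          precision = hit$precision %||% NA_real_,
          n_above = hit$n_above %||% NA_real_,
          reachable = !is.null(hit), stringsAsFactors = FALSE)
      }
    }
  }
  list(ranking = ranking,
       groups = do.call(rbind, c(group_rows, make.row.names = FALSE)),
       comparisons = do.call(rbind, c(comp_rows, make.row.names = FALSE)),
       precision = do.call(rbind, c(prec_rows, make.row.names = FALSE)),
       thresholds = do.call(rbind, c(thr_rows, make.row.names = FALSE)),
       skipped = if (length(skip_rows))
         do.call(rbind, c(skip_rows, make.row.names = FALSE)) else NULL)
}

#' Run the full evaluation pipeline
#'
#' Loads (or simulates) the variant data, harmonizes signs, adds consensus
#' pseudo-predictors, and produces: a predictor ranking by balanced AUC;
#' group-versus-complement AUCs with Mann-Whitney comparisons for the
#' three canonical inheritance-mode groups; precision curves and
#' target-precision thresholds for the haploinsufficient split;
#' destabilizing-only variants of all three; and a run manifest. Re-running
#' with the same config reproduces every number exactly.
#'
#' @param config a [run_config()].
#' @return object of class `report_bundle`: `tables` (named list of
#'   `data.frame`s), `manifest` (list), and `dataset` (the harmonized
#'   [variant_dataset()] actually analysed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$synthetic)) {
    sim <- if (identical(config$synthetic, "paper_shape")) {
      emulate_paper_shape(config$seed)
    } else {
      generate_dataset(config$synthetic)
    }
    ds <- sim$dataset
    gene_lists <- sim$gene_lists
    source_desc <- "synthetic"
  } else {
    ds <- read_variant_table(config$input$variant_table,
                             config$input$column_map)
    if (!is.null(config$input$conventions)) {
      ds <- set_conventions(ds, read_convention_map(config$input$conventions))
    }
    gene_lists <- lapply(config$input$gene_lists, read_gene_list)
    source_desc <- config$input$variant_table
  }
  ds <- harmonize_signs(ds)
  for (members in config$consensus) {
    ds <- add_consensus(ds, consensus_spec(members))
  }
  preds <- config$predictors %||% predictors(ds)
  unknown <- setdiff(preds, predictors(ds))
  if (length(unknown)) stop("unknown predictors requested: ",
                            paste(unknown, collapse = ", "))
  flags <- annotate_inheritance(ds, gene_lists$hi, gene_lists$ad,
                                gene_lists$ar)
  main <- analyse_dataset(ds, preds, flags, config, tag = "main")
  tables <- list(ranking = main$ranking, group_auc = main$groups,
                 group_comparisons = main$comparisons,
                 precision_points = main$precision,
                 precision_thresholds = main$thresholds)
  destab_skipped <- NULL
  if (config$destabilizing) {
    dest_rows <- list()
    for (p in preds) {
      sub <- tryCatch(destabilizing_subset(ds, p),
                      ddgpath_undefined_stratum = function(e) NULL)
      if (is.null(sub)) next
      one <- analyse_dataset(sub, p, flags, config,
                             tag = paste0("destab_", p))
      dest_rows[[p]] <- one
    }
    bindpart <- function(part) {
      parts <- Filter(Negate(is.null), lapply(dest_rows, `[[`, part))
      if (length(parts)) do.call(rbind, c(parts, make.row.names = FALSE))
      else NULL
    }
    tables$destab_ranking <- bindpart("ranking")
    tables$destab_group_auc <- bindpart("groups")
    tables$destab_group_comparisons <- bindpart("comparisons")
    tables$destab_precision_points <- bindpart("precision")
    tables$destab_precision_thresholds <- bindpart("thresholds")
    destab_skipped <- bindpart("skipped")
  }
  n <- nrow(ds$variants)
  n_pos <- sum(ds$variants$label == "pathogenic")
  manifest <- list(
    source = source_desc,
    n_variants = n, n_pathogenic = n_pos, n_benign = n - n_pos,
    n_genes = length(unique(ds$variants$gene)),
    predictors = preds,
    consensus = lapply(config$consensus, paste, collapse = ","),
    n_reps = config$n_reps, seed = config$seed,
    comparison_unit = config$comparison_unit,
    balanced_precision = config$balanced_precision,
    precision_targets = config$precision_targets,
    min_support = config$min_support,
    min_per_class = config$min_per_class,
    n_comparisons = if (!is.null(main$comparisons)) nrow(main$comparisons) else 0L,
    per_gene_skips = main$skipped,
    destab_per_gene_skips = destab_skipped,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ddgpath")))
  structure(list(tables = tables, manifest = manifest, dataset = ds),
            class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' One TSV per table plus a YAML manifest; output is byte-stable under
#' re-runs with the same config.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_report_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(bundle$tables)) {
    tab <- bundle$tables[[nm]]
    if (is.null(tab)) next
    path <- file.path(outdir, paste0(nm, ".tsv"))
    data.table::fwrite(tab, path, sep = "\t", na = "NA")
    paths[nm] <- path
  }
  manifest <- bundle$manifest
  for (nm in c("per_gene_skips", "destab_per_gene_skips")) {
    if (!is.null(manifest[[nm]])) {
      manifest[[nm]] <- as.list(as.data.frame(manifest[[nm]]))
    }
  }
  paths["manifest"] <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

#' Render report figures
#'
#' Visual analogues of the three report tables: a bar chart of mean AUC
#' per predictor, a grouped bar panel per inheritance split with the
#' Mann-Whitney p-values in the strip, and precision-versus-threshold
#' lines with solid/dashed styling for haploinsufficient versus
#' non-haploinsufficient strata. Figures whose table is missing are
#' skipped with a warning.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory.
#' @param format `"png"`, `"pdf"` or `"svg"`.
#' @return named vector of written figure paths, invisibly.
#' @export
render_figures <- function(bundle, outdir, format = "png") {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_fig <- function(plot, name, width = 7, height = 5) {
    path <- file.path(outdir, paste0(name, ".", format))
    ggplot2::ggsave(path, plot, width = width, height = height)
    paths[name] <<- path
  }
  tabs <- bundle$tables
  if (!is.null(tabs$ranking) && nrow(tabs$ranking)) {
    d <- tabs$ranking
    save_fig(
      ggplot2::ggplot(d, ggplot2::aes(
        x = stats::reorder(predictor, -mean_auc), y = mean_auc)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_auc - sd_auc,
                                            ymax = mean_auc + sd_auc),
                               width = 0.2) +
        ggplot2::labs(x = NULL, y = "mean balanced AUC",
                      title = "Predictor ranking (|ddG| scores)") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)),
      "ranking")
  } else {
    warning("ranking table missing; figure skipped")
  }
  if (!is.null(tabs$group_auc) && nrow(tabs$group_auc)) {
    d <- tabs$group_auc[!is.na(tabs$group_auc$mean_auc), ]
    p_lab <- NULL
    if (!is.null(tabs$group_comparisons)) {
      gc <- tabs$group_comparisons
      p_lab <- stats::aggregate(p_value ~ group, gc, function(p)
        paste(signif(p, 2), collapse = ", "))
    }
    plt <- ggplot2::ggplot(d, ggplot2::aes(x = predictor, y = mean_auc,
                                           fill = side)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(x = NULL, y = "mean balanced AUC",
                    title = "Inheritance-mode groups vs complements",
                    caption = if (!is.null(p_lab))
                      paste0("Mann-Whitney p (", paste0(
                        p_lab$group, ": ", p_lab$p_value, collapse = "; "), ")")
                    else NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    save_fig(plt, "group_auc", width = 9)
  } else {
    warning("group AUC table missing; figure skipped")
  }
  if (!is.null(tabs$precision_points) && nrow(tabs$precision_points)) {
    d <- tabs$precision_points
    d <- d[d$stratum != "all", ]
    if (nrow(d)) {
      save_fig(
        ggplot2::ggplot(d, ggplot2::aes(x = threshold, y = precision,
                                        colour = predictor,
                                        linetype = stratum)) +
          ggplot2::geom_line() +
          ggplot2::scale_linetype_manual(values = c(
            haploinsufficient = "solid", not_haploinsufficient = "dashed")) +
          ggplot2::labs(x = "|ddG| threshold (kcal/mol)",
                        y = "precision (PPV)",
                        title = "Enrichment of pathogenic variants above |ddG| thresholds") +
          ggplot2::theme_minimal(),
        "precision", width = 8)
    }
  } else {
    warning("precision table missing; figure skipped")
  }
  invisible(paths)
}
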