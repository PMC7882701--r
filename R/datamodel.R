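#' Predictor panel constructor
#'
#' A panel describes the stability predictors attached to a dataset: the
#' sign convention each tool uses to report destabilization and an optional
#' hard cap on reported |ddG| (some tools truncate their output scale).
#'
#' @param name character vector of unique predictor identifiers.
#' @param sign_convention `"positive_destabilizing"` or
#'   `"negative_destabilizing"`, recycled to `length(name)`.
#' @param cap optional positive |ddG| cap in kcal/mol (`NA` = uncapped),
#'   recycled.
#' @return a `data.frame` with columns `name`, `sign_convention`, `cap`.
#' @export
predictor_panel <- function(name,
                            sign_convention = "positive_destabilizing",
                            cap = NA_real_) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("predictor names must be unique within a panel: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  sign_convention <- rep_len(as.character(sign_convention), length(name))
  bad <- !sign_convention %in%
    c("positive_destabilizing", "negative_destabilizing")
  if (any(bad)) {
    stop("unknown sign convention: ", paste(sign_convention[bad], collapse = ", "))
  }
  cap <- rep_len(as.numeric(cap), length(name))
  if (any(!is.na(cap) & cap <= 0)) stop("predictor cap must be > 0")
  data.frame(name = name, sign_convention = sign_convention, cap = cap,
             stringsAsFactors = FALSE)
}

#' Variant dataset constructor
#'
#' The central container: one row per missense variant (opaque `variant_id`,
#' normalized `gene`, `label` in \{pathogenic, benign\}, one numeric ddG
#' column per predictor, kcal/mol, `NA` = missing) plus the predictor panel
#' and a flag recording whether sign conventions have been harmonized.
#'
#' @param variants `data.frame` with columns `variant_id`, `gene`, `label`
#'   and one numeric column per panel predictor.
#' @param panel a panel from [predictor_panel()].
#' @param harmonized logical; `TRUE` once [harmonize_signs()] has run.
#' @return an object of class `variant_dataset`.
#' @export
variant_dataset <- function(variants, panel, harmonized = FALSE) {
  stopifnot(is.data.frame(variants), is.data.frame(panel))
  required <- c("variant_id", "gene", "label")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variants is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$variant_id <- as.character(variants$variant_id)
  variants$gene <- normalize_gene(variants$gene)
  variants$label <- as.character(variants$label)
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant_id: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  }
  bad_label <- !variants$label %in% c("pathogenic", "benign")
  if (any(bad_label)) {
    stop("labels must be 'pathogenic' or 'benign'; offending rows: ",
         paste(utils::head(which(bad_label), 10), collapse = ", "))
  }
  absent <- setdiff(panel$name, names(variants))
  if (length(absent)) {
    stop("panel predictors without a data column: ",
         paste(absent, collapse = ", "))
  }
  for (p in panel$name) variants[[p]] <- as.numeric(variants[[p]])
  if (isTRUE(harmonized) &&
      any(panel$sign_convention != "positive_destabilizing")) {
    stop("a harmonized dataset must store positive_destabilizing conventions")
  }
  structure(
    list(variants = variants, panel = panel, harmonized = isTRUE(harmonized)),
    class = "variant_dataset"
  )
}

#' @export
print.variant_dataset <- function(x, ...) {
  n <- nrow(x$variants)
  npos <- sum(x$variants$label == "pathogenic")
  cat(sprintf(
    "variant_dataset: %d variants (%d pathogenic / %d benign), %d genes\n",
    n, npos, n - npos, length(unique(x$variants$gene))
  ))
  cat(sprintf("predictors (%s): %s\n",
              if (x$harmonized) "harmonized" else "raw signs",
              paste(x$panel$name, collapse = ", ")))
  invisible(x)
}

#' List the predictors of a dataset
#' @param dataset a [variant_dataset()].
#' @return character vector of predictor names.
#' @export
predictors <- function(dataset) dataset$panel$name

#' Subset a dataset by record index
#'
#' Keeps the panel and harmonization state; useful for building custom
#' strata before calling the evaluation functions.
#'
#' @param dataset a [variant_dataset()].
#' @param idx integer or logical row index into the variant table.
#' @return the restricted `variant_dataset`.
#' @export
subset_records <- function(dataset, idx) {
  variant_dataset(dataset$variants[idx, , drop = FALSE], dataset$panel,
                  harmonized = dataset$harmonized)
}

#' Default label vocabulary
#'
#' Maps raw label strings (lowercased, trimmed) onto the two classes.
#' ClinVar-style "likely pathogenic" folds into pathogenic; gnomAD-sourced
#' variants are treated as putatively benign.
#'
#' @return named character vector: raw value -> `"pathogenic"`/`"benign"`.
#' @export
default_label_vocabulary <- function() {
  c("pathogenic" = "pathogenic",
    "likely pathogenic" = "pathogenic",
    "p" = "pathogenic",
    "benign" = "benign",
    "likely benign" = "benign",
    "putatively benign" = "benign",
    "gnomad" = "benign",
    "b" = "benign")
}

#' Read a variant table
#'
#' Parses a TSV/CSV file (header required; delimiter auto-detected from the
#' extension, `.csv` = comma, otherwise tab) into an unharmonized
#' [variant_dataset()]. Empty or NA predictor cells become missing values;
#' gene symbols are normalized; row order is preserved.
#'
#' @param path path to the table.
#' @param column_map list with entries `variant_id`, `gene`, `label` (column
#'   names) and `predictors`: a character vector of predictor column names,
#'   optionally named to rename them (`c(foldx = "FoldX5.0_col")`).
#' @param label_map named character vector mapping raw label values
#'   (matched lowercased and trimmed) onto `"pathogenic"`/`"benign"`.
#' @return an unharmonized `variant_dataset` (all conventions default to
#'   positive_destabilizing until [set_conventions()] is applied).
#' @export
read_variant_table <- function(path, column_map,
                               label_map = default_label_vocabulary()) {
  if (!file.exists(path)) stop("no such file: ", path)
  for (role in c("variant_id", "gene", "label")) {
    if (is.null(column_map[[role]])) stop("column_map lacks role: ", role)
  }
  pred_cols <- column_map$predictors
  if (is.null(pred_cols) || length(pred_cols) < 1) {
    stop("column_map must name at least one predictor column")
  }
  pred_names <- if (is.null(names(pred_cols))) {
    as.character(pred_cols)
  } else {
    ifelse(names(pred_cols) == "", as.character(pred_cols), names(pred_cols))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.table::fread(path, sep = sep, header = TRUE,
                           data.table = FALSE, na.strings = c("", "NA"),
                           colClasses = "character")
  needed <- c(column_map$variant_id, column_map$gene, column_map$label,
              as.character(pred_cols))
  absent <- setdiff(needed, names(tab))
  if (length(absent)) {
    stop("columns absent from ", path, ": ", paste(absent, collapse = ", "))
  }
  raw_label <- tolower(trimws(tab[[column_map$label]]))
  mapped <- unname(label_map[raw_label])
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))
    stop("unmappable label values (rows ",
         paste(utils::head(bad, 10), collapse = ", "), "): ",
         paste(unique(raw_label[bad]), collapse = ", "))
  }
  variants <- data.frame(
    variant_id = tab[[column_map$variant_id]],
    gene = tab[[column_map$gene]],
    label = mapped,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(pred_cols)) {
    variants[[pred_names[i]]] <-
      suppressWarnings(as.numeric(tab[[as.character(pred_cols)[i]]]))
  }
  variant_dataset(variants, predictor_panel(pred_names), harmonized = FALSE)
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: writes the variant rows as TSV with
#' full numeric precision, so a read/write round trip reproduces finite
#' ddG values bit-exactly.
#'
#' @param dataset a [variant_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(dataset, path) {
  out <- dataset$variants
  for (p in dataset$panel$name) {
    out[[p]] <- vapply(out[[p]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17)
    }, character(1))
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a gene list
#'
#' Plain text, one symbol per line (MacArthur-lab list format). Blank lines
#' and `#` comments are skipped; symbols are normalized and deduplicated.
#'
#' @param path path to the list.
#' @return character vector of unique normalized symbols. An empty result
#'   is legal (warned, not an error): it yields an empty gene group.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(normalize_gene(lines))
  if (length(genes) == 0) warning("gene list is empty: ", path)
  genes
}

#' Read a predictor sign-convention map
#'
#' YAML with one entry per predictor: `name: {sign: pos|neg, cap: number}`
#' (`cap` optional or `null` = uncapped). Predictors absent from the map
#' keep the positive_destabilizing default.
#'
#' @param path path to the YAML file. The package ships a default map for
#'   the 13 tools of the benchmark under
#'   `system.file("extdata", "predictor_conventions.yaml", package = "ddgpath")`;
#'   its sign and cap values are editable placeholders, not published
#'   constants.
#' @return a panel-shaped `data.frame` (`name`, `sign_convention`, `cap`).
#' @export
read_convention_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) return(predictor_panel(character(0)))
  sign <- vapply(raw, function(e) {
    s <- if (is.null(e$sign)) "pos" else as.character(e$sign)
    switch(s,
           pos = "positive_destabilizing",
           neg = "negative_destabilizing",
           stop("sign must be 'pos' or 'neg', got: ", s))
  }, character(1))
  cap <- vapply(raw, function(e) {
    if (is.null(e$cap)) NA_real_ else as.numeric(e$cap)
  }, numeric(1))
  predictor_panel(names(raw), sign, cap)
}

#' Apply a convention map to a dataset's panel
#'
#' Overwrites sign convention and cap for every panel predictor present in
#' the map. Must run before [harmonize_signs()].
#'
#' @param dataset an unharmonized [variant_dataset()].
#' @param conventions a panel-shaped `data.frame`, e.g. from
#'   [read_convention_map()].
#' @return the dataset with an updated panel.
#' @export
set_conventions <- function(dataset, conventions) {
  if (dataset$harmonized) {
    stop("cannot change conventions after harmonization")
  }
  idx <- match(dataset$panel$name, conventions$name)
  hit <- !is.na(idx)
  dataset$panel$sign_convention[hit] <- conventions$sign_convention[idx[hit]]
  dataset$panel$cap[hit] <- conventions$cap[idx[hit]]
  variant_dataset(dataset$variants, dataset$panel, harmonized = FALSE)
}

#' Harmonize predictor sign conventions
#'
#' Negates every value of negative_destabilizing predictors so that, for
#' all predictors, positive harmonized ddG means destabilizing. |ddG| is
#' unchanged for every record and predictor; missing stays missing.
#' Calling it twice is a hard error (prevents silent double negation).
#'
#' @param dataset an unharmonized [variant_dataset()].
#' @return the harmonized dataset.
#' @export
harmonize_signs <- function(dataset) {
  stopifnot(inherits(dataset, "variant_dataset"))
  if (dataset$harmonized) stop("dataset is already harmonized")
  flip <- dataset$panel$name[
    dataset$panel$sign_convention == "negative_destabilizing"]
  for (p in flip) dataset$variants[[p]] <- -dataset$variants[[p]]
  dataset$panel$sign_convention <- "positive_destabilizing"
  variant_dataset(dataset$variants, dataset$panel, harmonized = TRUE)
}

#' Annotate dataset genes with inheritance-mode flags
#'
#' Every gene occurring in the dataset gets one row of boolean flags from
#' membership in the three curated lists. A gene absent from all lists has
#' all-false flags and belongs only to group complements. A gene may carry
#' several flags (e.g. haploinsufficient genes are typically also on the
#' dominant list); group resolution happens later in [group_predicate()].
#'
#' @param dataset a [variant_dataset()].
#' @param hi,ad,ar character vectors of normalized gene symbols
#'   (haploinsufficient / autosomal dominant / autosomal recessive).
#' @return `data.frame` with columns `gene`, `is_hi`, `is_ad`, `is_ar`.
#' @export
annotate_inheritance <- function(dataset, hi = character(0),
                                 ad = character(0), ar = character(0)) {
  genes <- unique(dataset$variants$gene)
  data.frame(
    gene = genes,
    is_hi = genes %in% normalize_gene(hi),
    is_ad = genes %in% normalize_gene(ad),
    is_ar = genes %in% normalize_gene(ar),
    stringsAsFactors = FALSE
  )
}

#' Build a gene-group predicate
#'
#' A predicate maps inheritance flags to group membership. The three
#' canonical groups follow the usual stratification:
#' `haploinsufficient` = `is_hi`; `dominant_not_hi` = `is_ad & !is_hi`
#' (haploinsufficiency takes precedence over plain dominance, making the
#' two groups disjoint by construction); `recessive` = `is_ar`.
#'
#' @param group_name one of the canonical names above, or a custom label
#'   (then `member_test` is required).
#' @param member_test for custom groups: `function(flags)` returning a
#'   logical vector over the rows of a flags table.
#' @return an object of class `group_predicate`.
#' @export
group_predicate <- function(group_name, member_test = NULL) {
  if (is.null(member_test)) {
    member_test <- switch(
      group_name,
      haploinsufficient = function(flags) flags$is_hi,
      dominant_not_hi   = function(flags) flags$is_ad & !flags$is_hi,
      recessive         = function(flags) flags$is_ar,
      stop("no built-in rule for group '", group_name,
           "'; supply member_test")
    )
  }
  structure(list(group_name = group_name, member_test = member_test),
            class = "group_predicate")
}

#' The three canonical inheritance-mode predicates
#' @return named list of [group_predicate()] objects.
#' @export
canonical_predicates <- function() {
  nm <- c("haploinsufficient", "dominant_not_hi", "recessive")
  stats::setNames(lapply(nm, group_predicate), nm)
}

#' Class-wise |ddG| score vectors for one predictor
#'
#' AUC and precision are always computed on absolute ddG: the stability
#' *perturbation*, irrespective of whether the variant is predicted to
#' destabilize or stabilize. Records missing this predictor are excluded
#' (pairwise deletion).
#'
#' @param dataset a [variant_dataset()].
#' @param predictor a panel predictor name.
#' @return list with non-negative numeric vectors `pathogenic`, `benign`.
#'   Signals an undefined-stratum condition if either class has no usable
#'   record (see [is_undefined_stratum()]).
#' @export
abs_scores <- function(dataset, predictor) {
  if (!predictor %in% dataset$panel$name) {
    stop("unknown predictor: ", predictor)
  }
  v <- dataset$variants[[predictor]]
  keep <- !is.na(v)
  s <- abs(v[keep])
  lab <- dataset$variants$label[keep]
  out <- list(pathogenic = s[lab == "pathogenic"],
              benign = s[lab == "benign"])
  if (length(out$pathogenic) == 0 || length(out$benign) == 0) {
    undefined_stratum(sprintf(
      "predictor %s: no usable records in one class (%d pathogenic, %d benign)",
      predictor, length(out$pathogenic), length(out$benign)))
  }
  out
}
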