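#' Consensus predictor specification
#'
#' A consensus pseudo-predictor averages the |ddG| values of its member
#' predictors (the aggregate used for the FoldX + INPS3D consensus). The
#' default averages absolute values, so the result is invariant to member
#' sign conventions; `signed = TRUE` averages harmonized signed values
#' instead and is provided for sensitivity analysis only.
#'
#' @param members character vector (length >= 1) of member predictor names.
#' @param output_name name of the resulting pseudo-predictor; default
#'   `"mean(a,b,...)"`.
#' @param signed average signed harmonized ddG instead of |ddG|.
#' @return an object of class `consensus_spec`.
#' @export
consensus_spec <- function(members,
                           output_name = paste0("mean(", paste(members, collapse = ","), ")"),
                           signed = FALSE) {
  members <- as.character(members)
  stopifnot(length(members) >= 1, !anyDuplicated(members))
  structure(list(members = members, output_name = output_name,
                 signed = isTRUE(signed)),
            class = "consensus_spec")
}

#' Add a consensus pseudo-predictor to a dataset
#'
#' Per record, the consensus value is the arithmetic mean of the member
#' |ddG| values (or signed values if the spec says so). It is missing if
#' ANY member is missing — the all-members rule keeps the effective
#' predictor's composition constant across records, so its AUC is
#' comparable to the members'. Stored positive_destabilizing, uncapped.
#'
#' @param dataset a harmonized [variant_dataset()].
#' @param spec a [consensus_spec()].
#' @return the dataset with one added predictor column and panel row.
#' @export
add_consensus <- function(dataset, spec) {
  stopifnot(inherits(dataset, "variant_dataset"),
            inherits(spec, "consensus_spec"))
  if (!dataset$harmonized) stop("harmonize_signs() must run before add_consensus()")
  unknown <- setdiff(spec$members, dataset$panel$name)
  if (length(unknown)) stop("unknown member predictor: ",
                            paste(unknown, collapse = ", "))
  if (spec$output_name %in% dataset$panel$name) {
    stop("output_name already in panel: ", spec$output_name)
  }
  cols <- dataset$variants[spec$members]
  if (!spec$signed) cols <- abs(cols)
  vals <- rowMeans(cols) # NA whenever any member is NA
  dataset$variants[[spec$output_name]] <- vals
  dataset$panel <- rbind(dataset$panel,
                         predictor_panel(spec$output_name))
  variant_dataset(dataset$variants, dataset$panel, harmonized = TRUE)
}

#' All consensus combinations of given sizes
#'
#' Enumerates every subset of `names` whose size is in `sizes`, in
#' deterministic lexicographic order (names sorted, sizes ascending).
#'
#' @param names character vector of predictor names.
#' @param sizes integer vector of subset sizes (each in `1..length(names)`).
#' @param signed passed through to [consensus_spec()].
#' @return list of [consensus_spec()] objects (empty if `names` is empty).
#' @export
predictor_combinations <- function(names, sizes, signed = FALSE) {
  if (length(names) == 0) return(list())
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1 | sizes > length(names))) {
    stop("sizes must lie in 1..length(names)")
  }
  names <- sort(names)
  specs <- list()
  for (k in sizes) {
    comb <- utils::combn(names, k)
    for (i in seq_len(ncol(comb))) {
      specs[[length(specs) + 1L]] <- consensus_spec(comb[, i], signed = signed)
    }
  }
  specs
}

#' Restrict a dataset to predicted destabilizing variants
#'
#' Keeps records with strictly positive harmonized ddG for the given
#' predictor (a harmonized value of exactly 0 counts as non-destabilizing);
#' records missing the predictor are dropped. Labels and other predictor
#' columns are untouched. Idempotent.
#'
#' @param dataset a harmonized [variant_dataset()].
#' @param predictor predictor whose sign defines "destabilizing".
#' @return the restricted `variant_dataset`. Signals an undefined-stratum
#'   condition when no record survives.
#' @export
destabilizing_subset <- function(dataset, predictor) {
  stopifnot(inherits(dataset, "variant_dataset"))
  if (!dataset$harmonized) stop("harmonize_signs() must run before destabilizing_subset()")
  if (!predictor %in% dataset$panel$name) stop("unknown predictor: ", predictor)
  v <- dataset$variants[[predictor]]
  keep <- !is.na(v) & v > 0
  if (!any(keep)) {
    undefined_stratum(sprintf("no destabilizing records for predictor %s",
                              predictor))
  }
  subset_records(dataset, which(keep))
}
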