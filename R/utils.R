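#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted: symbols are compared verbatim after this normalization.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_gene(c(" tp53 ", "Brca1"))
normalize_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Deterministic polynomial hash of the master seed and the labels, reduced
#' modulo 2^31 - 1. Used so that strata, genes and predictors each get an
#' independent, recomputable random substream: re-evaluating one stratum in
#' isolation reproduces exactly the numbers obtained inside a full run.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the substream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- as.numeric(master) %% m
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(lab)))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Signal that a stratum has no usable records in one class: callers such as
# stratified_auc() catch this and report the side as undefined instead of
# aborting the whole analysis.
undefined_stratum <- function(msg) {
  stop(structure(
    class = c("ddgpath_undefined_stratum", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Test whether a condition signals an undefined stratum
#'
#' @param cond a condition object.
#' @return logical.
#' @export
is_undefined_stratum <- function(cond) {
  inherits(cond, "ddgpath_undefined_stratum")
}
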