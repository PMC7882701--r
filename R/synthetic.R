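#' Synthetic dataset configuration
#'
#' Describes the generative world the pipeline is tested against: genes
#' carry an inheritance mode; each variant draws a latent true stability
#' perturbation |ddG| from a non-negative class law, with the pathogenic
#' scale inflated by a mode-specific effect size; each predictor observes
#' the shared latent signal through its own noise, sign convention, output
#' cap and missingness.
#'
#' Class laws: benign |ddG| ~ Gamma(shape, scale) (default shape 1,
#' scale 1 kcal/mol, i.e. Exponential(1)); pathogenic uses the same family
#' with scale multiplied by `1 + delta[mode]`. With exponential laws this
#' gives the closed-form population AUC
#' `scale_path / (scale_path + scale_benign)`, used as an analytic oracle.
#'
#' @param n_genes named integer vector: gene counts for modes `hi`,
#'   `ad_only`, `ar`, `unlisted`.
#' @param variants_per_gene single integer, or length-2 range sampled
#'   uniformly per gene.
#' @param pathogenic_fraction per-variant probability of the pathogenic
#'   label.
#' @param benign_law list: `family` (`"exponential"` with `rate`, or
#'   `"gamma"` with `shape` and `scale`).
#' @param delta named numeric vector of pathogenic scale multipliers minus
#'   one (effect sizes) per mode. Defaults reflect a world where stability
#'   perturbation separates classes strongly in haploinsufficient genes
#'   (`delta = 2`, population exponential AUC 0.75) and weakly elsewhere
#'   (`delta = 0.5`, AUC 0.6).
#' @param predictors named list; each element a list with `noise_sd`
#'   (kcal/mol), `signal_weight` in `[0, 1]` (weight of the shared latent
#'   signal versus an independent same-law draw; 1 = pure shared signal,
#'   which drives inter-predictor correlation), `sign` (`"pos"`/`"neg"`
#'   reporting convention), `cap` (`NA` = uncapped) and `missing_rate` in
#'   `[0, 1)`.
#' @param stabilizing_prob probability that a variant is reported with
#'   stabilizing (negative harmonized) sign; most variants are predicted
#'   destabilizing, so the default is small.
#' @param seed master integer seed. Gene-level draws and each predictor's
#'   observation stream use sub-seeds derived from it, so adding a
#'   predictor never perturbs existing columns.
#' @return validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genes = c(hi = 10, ad_only = 10, ar = 10, unlisted = 10),
    variants_per_gene = 40,
    pathogenic_fraction = 0.3,
    benign_law = list(family = "gamma", shape = 1, scale = 1),
    delta = c(hi = 2, ad_only = 0.5, ar = 0.5, unlisted = 0.5),
    predictors = list(
      foldx_like = list(noise_sd = 0.8, signal_weight = 0.8, sign = "pos",
                        cap = NA, missing_rate = 0.02),
      inps_like = list(noise_sd = 1.0, signal_weight = 0.7, sign = "neg",
                       cap = 10, missing_rate = 0.02)
    ),
    stabilizing_prob = 0.1,
    seed = 1) {
  modes <- c("hi", "ad_only", "ar", "unlisted")
  stopifnot(all(modes %in% names(n_genes)), all(n_genes >= 0),
            all(modes %in% names(delta)), all(delta >= 0),
            pathogenic_fraction >= 0, pathogenic_fraction <= 1,
            stabilizing_prob >= 0, stabilizing_prob <= 1,
            length(variants_per_gene) %in% 1:2, all(variants_per_gene >= 1),
            length(predictors) >= 1, !is.null(names(predictors)))
  if (sum(n_genes) < 1) stop("config must define at least one gene")
  benign_law$family <- match.arg(benign_law$family, c("exponential", "gamma"))
  if (benign_law$family == "exponential") {
    stopifnot(benign_law$rate > 0)
  } else {
    stopifnot(benign_law$shape > 0, benign_law$scale > 0)
  }
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    stopifnot(p$noise_sd >= 0,
              p$signal_weight >= 0, p$signal_weight <= 1,
              p$sign %in% c("pos", "neg"),
              is.na(p$cap) || p$cap > 0,
              p$missing_rate >= 0, p$missing_rate < 1)
  }
  structure(list(n_genes = n_genes[modes], variants_per_gene = variants_per_gene,
                 pathogenic_fraction = pathogenic_fraction,
                 benign_law = benign_law, delta = delta[modes],
                 predictors = predictors,
                 stabilizing_prob = stabilizing_prob, seed = seed),
            class = "synthetic_config")
}

# Scale of the class law for a mode/label ("benign" multiplier is 1).
law_scale <- function(law, mult = 1) {
  if (law$family == "exponential") mult / law$rate else mult * law$scale
}

# Draw n latent |ddG| values for given per-draw scale multipliers.
draw_latent <- function(n, law, mult) {
  if (law$family == "exponential") {
    stats::rexp(n, rate = 1) * (mult / law$rate)
  } else {
    stats::rgamma(n, shape = law$shape, scale = 1) * (mult * law$scale)
  }
}

#' Generate a synthetic dataset from an explicit gene plan
#'
#' Lower-level entry point taking exact per-gene variant counts; used by
#' [generate_dataset()] (which draws the counts) and by
#' [emulate_paper_shape()] (which fixes them to published marginals).
#'
#' @param gene_plan `data.frame` with columns `gene`, `mode` (one of hi /
#'   ad_only / ar / unlisted), `n_path`, `n_benign`.
#' @param config a [synthetic_config()] (its `n_genes`,
#'   `variants_per_gene` and `pathogenic_fraction` are ignored in favour of
#'   the plan).
#' @return list of class `synthetic_dataset`: `dataset` (unharmonized
#'   [variant_dataset()] with the configured conventions and caps),
#'   `truth` (`data.frame` variant_id / gene / mode / label / true_ddg /
#'   sign), `gene_lists` (`hi`, `ad`, `ar`; the dominant list includes the
#'   haploinsufficient genes, as curated dominance lists do), and `config`.
#' @export
generate_from_plan <- function(gene_plan, config) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("gene", "mode", "n_path", "n_benign") %in% names(gene_plan)))
  if (sum(gene_plan$n_path + gene_plan$n_benign) < 1) {
    stop("gene plan contains no variants")
  }
  seed <- config$seed
  # gene-level stream: latent |ddG|, labels (ordering), reported sign
  rows <- vector("list", nrow(gene_plan))
  for (i in seq_len(nrow(gene_plan))) {
    g <- gene_plan$gene[i]
    mode <- gene_plan$mode[i]
    n <- gene_plan$n_path[i] + gene_plan$n_benign[i]
    if (n == 0) next
    label <- c(rep("pathogenic", gene_plan$n_path[i]),
               rep("benign", gene_plan$n_benign[i]))
    rows[[i]] <- with_seed(derive_seed(seed, "gene", g), {
      mult <- ifelse(label == "pathogenic", 1 + config$delta[[mode]], 1)
      data.frame(
        variant_id = sprintf("%s_v%04d", g, seq_len(n)),
        gene = g, mode = mode, label = label,
        true_ddg = draw_latent(n, config$benign_law, mult),
        sign = ifelse(stats::runif(n) < config$stabilizing_prob, -1, 1),
        stringsAsFactors = FALSE)
    })
  }
  truth <- do.call(rbind, c(rows, make.row.names = FALSE))
  n_total <- nrow(truth)
  variants <- truth[c("variant_id", "gene", "label")]
  # per-predictor observation streams, independent of panel composition
  for (nm in names(config$predictors)) {
    p <- config$predictors[[nm]]
    variants[[nm]] <- with_seed(derive_seed(seed, "predictor", nm), {
      mult <- ifelse(truth$label == "pathogenic",
                     1 + unname(config$delta[truth$mode]), 1)
      indep <- draw_latent(n_total, config$benign_law, mult)
      mag <- p$signal_weight * truth$true_ddg +
        (1 - p$signal_weight) * indep +
        stats::rnorm(n_total, sd = p$noise_sd)
      mag <- pmax(mag, 0)
      if (!is.na(p$cap)) mag <- pmin(mag, p$cap)
      val <- truth$sign * mag * (if (p$sign == "neg") -1 else 1)
      val[stats::runif(n_total) < p$missing_rate] <- NA_real_
      val
    })
  }
  panel <- predictor_panel(
    names(config$predictors),
    sign_convention = vapply(config$predictors, function(p) {
      if (p$sign == "neg") "negative_destabilizing" else "positive_destabilizing"
    }, character(1)),
    cap = vapply(config$predictors, function(p) as.numeric(p$cap), numeric(1))
  )
  hi_genes <- gene_plan$gene[gene_plan$mode == "hi"]
  structure(list(
    dataset = variant_dataset(variants, panel, harmonized = FALSE),
    truth = truth,
    gene_lists = list(
      hi = hi_genes,
      ad = c(hi_genes, gene_plan$gene[gene_plan$mode == "ad_only"]),
      ar = gene_plan$gene[gene_plan$mode == "ar"]
    ),
    config = config
  ), class = "synthetic_dataset")
}

#' Generate a synthetic variant dataset
#'
#' Draws per-gene variant counts and labels from the config, then latent
#' perturbations and predictor observations (see [synthetic_config()] for
#' the generative model). Fully deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list; see [generate_from_plan()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  modes <- names(config$n_genes)
  genes <- unlist(lapply(modes, function(m) {
    k <- config$n_genes[[m]]
    if (k == 0) return(character(0))
    sprintf("%s%03d", toupper(sub("_only", "", m)), seq_len(k))
  }))
  mode_of <- rep(modes, times = config$n_genes)
  plan <- do.call(rbind, lapply(seq_along(genes), function(i) {
    with_seed(derive_seed(config$seed, "plan", genes[i]), {
      n <- if (length(config$variants_per_gene) == 2) {
        sample(config$variants_per_gene[1]:config$variants_per_gene[2], 1)
      } else {
        config$variants_per_gene
      }
      n_path <- stats::rbinom(1, n, config$pathogenic_fraction)
      data.frame(gene = genes[i], mode = mode_of[i],
                 n_path = n_path, n_benign = n - n_path,
                 stringsAsFactors = FALSE)
    })
  }))
  generate_from_plan(plan, config)
}

# Split total count T over k genes as evenly as possible (first genes get
# the remainder).
split_count <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1, extra), rep(0, k - extra))
}

#' Synthetic fixture with the benchmark's marginal counts
#'
#' Builds a dataset whose marginal counts match the published benchmark
#' exactly — 13,508 variants over 100 genes, 3,338 pathogenic / 10,170
#' benign, with per-mode pathogenic/benign splits 1,217/1,252
#' (haploinsufficient), 753/1,819 (dominant), 635/4,253 (recessive) and
#' the 733/2,846 remainder on unlisted genes — while all score values are
#' synthetic draws from the default generative model. Useful for
#' end-to-end pipeline runs at realistic scale without the external data.
#'
#' @param seed integer master seed.
#' @param predictors optional predictor model list (default: four
#'   correlated tools with mixed sign conventions and two capped outputs).
#' @return a `synthetic_dataset` list; see [generate_from_plan()].
#' @export
emulate_paper_shape <- function(seed = 1, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- list(
      FoldX5 = list(noise_sd = 0.8, signal_weight = 0.85, sign = "pos",
                    cap = NA, missing_rate = 0),
      INPS3D = list(noise_sd = 1.0, signal_weight = 0.75, sign = "neg",
                    cap = 10, missing_rate = 0),
      Rosetta = list(noise_sd = 1.4, signal_weight = 0.65, sign = "pos",
                     cap = NA, missing_rate = 0),
      PoPMuSiC = list(noise_sd = 1.2, signal_weight = 0.6, sign = "neg",
                      cap = 7, missing_rate = 0)
    )
  }
  counts <- list( # mode -> c(genes, pathogenic, benign)
    hi = c(25, 1217, 1252),
    ad_only = c(20, 753, 1819),
    ar = c(30, 635, 4253),
    unlisted = c(25, 733, 2846)
  )
  plan <- do.call(rbind, lapply(names(counts), function(m) {
    k <- counts[[m]][1]
    data.frame(
      gene = sprintf("%s%03d", toupper(sub("_only", "", m)), seq_len(k)),
      mode = m,
      n_path = split_count(counts[[m]][2], k),
      n_benign = split_count(counts[[m]][3], k),
      stringsAsFactors = FALSE)
  }))
  cfg <- synthetic_config(
    n_genes = c(hi = 25, ad_only = 20, ar = 30, unlisted = 25),
    predictors = predictors, seed = seed)
  generate_from_plan(plan, cfg)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the readers consume: the variant table as TSV,
#' the three gene lists as plain text, the ground-truth sidecar as TSV and
#' the config echo as YAML.
#'
#' @param x a `synthetic_dataset` from [generate_dataset()] or
#'   [emulate_paper_shape()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    hi = file.path(dir, "genes_hi.txt"),
    ad = file.path(dir, "genes_ad.txt"),
    ar = file.path(dir, "genes_ar.txt"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_variant_table(x$dataset, paths[["variants"]])
  writeLines(x$gene_lists$hi, paths[["hi"]])
  writeLines(x$gene_lists$ad, paths[["ad"]])
  writeLines(x$gene_lists$ar, paths[["ar"]])
  data.table::fwrite(x$truth, paths[["truth"]], sep = "\t")
  cfg <- x$config
  cfg_list <- list(
    n_genes = as.list(cfg$n_genes), variants_per_gene = cfg$variants_per_gene,
    pathogenic_fraction = cfg$pathogenic_fraction, benign_law = cfg$benign_law,
    delta = as.list(cfg$delta), predictors = cfg$predictors,
    stabilizing_prob = cfg$stabilizing_prob, seed = cfg$seed)
  yaml::write_yaml(cfg_list, paths[["config"]])
  invisible(paths)
}
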