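# End-to-end orchestration on a synthetic two-species design: simulate,
# preprocess, build per-species and consensus networks, eigengenes and
# trait associations, module preservation (with the gold sham module),
# eigengene-network comparison, and module-based classification.  A single
# global seed fans out deterministically to per-stage seeds.

#' Pipeline configuration
#'
#' Defaults follow the analysis parameters of the method: soft threshold
#' `beta = 7`, `deep_split = 1`, merge `cut_height = 0.25`, minimum module
#' size 30, variance threshold 0.3, 10-fold CV, 10 randomized splits, a
#' 100-gene gold module, and 200 permutations for preservation.
#'
#' @param design a [synthetic_design()] describing the input meta-sets.
#' @param beta,deep_split,min_module_size,cut_height network parameters.
#' @param signed signed network (default FALSE).
#' @param variance_threshold variance filter cutoff.
#' @param n_perm preservation permutations.
#' @param gold_size gold sham module size.
#' @param k_folds,n_splits classifier cross-validation settings.
#' @param meta_cut_height eigengene meta-module cut height.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(design = synthetic_design(),
                            beta = 7, deep_split = 1, min_module_size = 30,
                            cut_height = 0.25, signed = FALSE,
                            variance_threshold = 0.3, n_perm = 200,
                            gold_size = 100, k_folds = 10, n_splits = 10,
                            meta_cut_height = 0.5, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full cross-species co-expression pipeline
#'
#' Executes: synthetic generation, per-study Z-score merging, ortholog
#' harmonization, variance filtering, per-species module detection,
#' consensus module detection, eigengene and trait analysis, permutation
#' module preservation including the gold sham module, eigengene-network
#' comparison (preservation matrix, scaled connectivity, density D,
#' meta-modules), and nearest-shrunken-centroid classification on the
#' trait-linked consensus module.  Optionally writes TSV artifacts and a
#' JSON summary to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return list with all stage results and a `summary` list (the content of
#'   the JSON summary).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  # seed fan-out: fixed offsets from the global seed, kept below 2^31
  sd0 <- as.integer(config$seed) %% 1000000L
  seeds <- list(sim = sd0 * 10L + 1L, pres = sd0 * 10L + 2L,
                clf = sd0 * 10L + 3L, mds = sd0 * 10L + 4L)

  design <- config$design
  design$seed <- seeds$sim
  sim <- simulate_meta_set(design)

  # per-study Z-score merge, then variance filter, per species
  merge_species <- function(sp) {
    studies <- lapply(unique(sim$study[[sp]]), function(st)
      sim$expr[[sp]][, sim$study[[sp]] == st, drop = FALSE])
    variance_filter(zscore_merge(studies), config$variance_threshold)
  }
  expr_a <- merge_species("a")
  expr_b <- merge_species("b")

  # ortholog harmonization onto species-A identifiers
  expr_b_mapped <- map_orthologs(expr_b, sim$truth$ortholog_table)
  shared <- intersect_genes(list(expr_a, expr_b_mapped))
  expr_a_shared <- shared[[1]]
  expr_b_shared <- shared[[2]]

  # single-species networks on each species' full filtered gene set
  mods_a <- network_modules(expr_a, config$beta, config$signed,
                            config$deep_split, config$min_module_size,
                            config$cut_height)
  mods_b <- network_modules(expr_b, config$beta, config$signed,
                            config$deep_split, config$min_module_size,
                            config$cut_height)
  cons <- consensus_modules(expr_a_shared, expr_b_shared,
                            beta = config$beta, signed = config$signed,
                            deep_split = config$deep_split,
                            min_module_size = config$min_module_size,
                            cut_height = config$cut_height)

  me_a <- module_eigengenes(expr_a, mods_a)
  traits_a <- sim$truth$trait_table$a[colnames(expr_a), , drop = FALSE]
  trait_cor <- if (ncol(traits_a) > 0) module_trait_cor(me_a, traits_a)

  pres <- module_preservation(expr_a_shared, expr_b_shared,
                              cons, n_perm = config$n_perm,
                              beta = config$beta, signed = config$signed,
                              seed = seeds$pres,
                              gold_size = config$gold_size)

  # eigengene networks over the consensus modules, one per species
  me_cons_a <- module_eigengenes(expr_a_shared, cons)
  me_cons_b <- module_eigengenes(expr_b_shared, cons)
  eignet <- compare_eigengene_networks(me_cons_a, me_cons_b,
                                       config$meta_cut_height)

  # classification cohort: species-A samples, labels from the trait link
  clf <- NULL
  if (!is.null(sim$truth$class_labels)) {
    y <- sim$truth$class_labels[colnames(expr_a)]
    feature_mod <- consensus_feature_module(cons, trait_cor, me_cons_a,
                                            traits_a)
    feats <- list(names(cons)[cons == feature_mod])
    names(feats) <- feature_mod
    clf <- repeated_split_eval(expr_a_shared, y, feats,
                               n_splits = config$n_splits,
                               k_folds = config$k_folds,
                               seed = seeds$clf)[[1]]
  }

  summary <- list(
    n_genes = list(a = nrow(expr_a), b = nrow(expr_b),
                   shared = nrow(expr_a_shared)),
    n_modules = list(a = length(setdiff(unique(mods_a), UNASSIGNED)),
                     b = length(setdiff(unique(mods_b), UNASSIGNED)),
                     consensus = length(setdiff(unique(cons), UNASSIGNED))),
    preservation = pres[, c("module", "size", "Z_density",
                            "Z_connectivity", "Z_summary",
                            "median_log_p", "band")],
    eigengene_density = eignet$density,
    meta_module_ari = eignet$meta_modules$ari,
    auroc = if (!is.null(clf)) clf$splits$auroc,
    top_gene = if (!is.null(clf)) clf$top_gene,
    seed = config$seed)

  if (!is.null(out_dir)) write_pipeline_artifacts(out_dir, list(
    modules_a = mods_a, modules_b = mods_b, consensus = cons,
    eigengenes_a = me_a, preservation = pres, summary = summary))

  list(sim = sim, expr = list(a = expr_a, b = expr_b,
                              a_shared = expr_a_shared,
                              b_shared = expr_b_shared),
       modules = list(a = mods_a, b = mods_b, consensus = cons),
       eigengenes = list(a = me_a, cons_a = me_cons_a, cons_b = me_cons_b),
       trait_cor = trait_cor, preservation = pres, eigengene_networks = eignet,
       classification = clf, summary = summary)
}

# pick the consensus module most correlated with the first trait column
consensus_feature_module <- function(cons, trait_cor, me_cons_a, traits_a) {
  mods <- setdiff(unique(cons), UNASSIGNED)
  if (length(mods) == 1) return(mods)
  tc <- module_trait_cor(me_cons_a, traits_a)
  mods[which.max(abs(tc$cor[mods, 1L]))]
}

write_pipeline_artifacts <- function(out_dir, artifacts) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_labels <- function(x, file)
    utils::write.table(data.frame(gene = names(x), module = unname(x)),
                       file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_labels(artifacts$modules_a, "modules_species_a.tsv")
  write_labels(artifacts$modules_b, "modules_species_b.tsv")
  write_labels(artifacts$consensus, "modules_consensus.tsv")
  utils::write.table(artifacts$preservation,
                     file.path(out_dir, "preservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  me <- artifacts$eigengenes_a
  utils::write.table(data.frame(module = rownames(me), me,
                                check.names = FALSE),
                     file.path(out_dir, "eigengenes_species_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(artifacts$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
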