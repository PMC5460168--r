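# Probe collapse, per-study Z-score merging, gene intersection, ortholog
# harmonization and variance filtering.  The fixed order of these steps —
# collapse, Z-score within study, concatenate, intersect, ortholog-map,
# variance filter — matters: standardizing per gene within each study is
# what removes additive batch offsets before studies are pooled.

#' Collapse probe-level rows to one row per gene (maximum mean rule)
#'
#' For every gene, retains the probe whose mean expression across all
#' samples is largest; ties are broken by the lexicographically smallest
#' probe identifier.  Probes without a gene mapping are dropped (count
#' reported via `message()`).
#'
#' @param probe_values probes x samples numeric matrix with probe rownames.
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`.
#' @return genes x samples matrix, rows sorted by gene id.
#' @export
collapse_probes <- function(probe_values, probe_to_gene) {
  if (is.null(rownames(probe_values)))
    stop("probe_values must have probe rownames")
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_to_gene)))
  keep <- rownames(probe_values) %in% probe_to_gene$probe_id
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("no probes in common between probe_values and probe_to_gene")
  if (n_dropped > 0)
    message(n_dropped, " unmapped probe(s) dropped")
  pv <- probe_values[keep, , drop = FALSE]
  map <- probe_to_gene[match(rownames(pv), probe_to_gene$probe_id), ]
  means <- rowMeans(pv)
  # winner per gene: max mean, then smallest probe id
  ord <- order(map$gene_id, -means, map$probe_id)
  winner <- ord[!duplicated(map$gene_id[ord])]
  out <- pv[winner, , drop = FALSE]
  rownames(out) <- map$gene_id[winner]
  out[order(rownames(out)), , drop = FALSE]
}

#' Z-score standardize each study and concatenate into a meta-set
#'
#' Within each study, every gene row is centred and scaled to sample
#' standard deviation 1 (denominator n - 1); the standardized studies are
#' then column-bound.  A gene that is constant within a study is set to all
#' zeros for that study, with a warning.
#'
#' @param studies list of genes x samples matrices over the same gene set.
#' @return single genes x samples meta-set matrix.
#' @export
zscore_merge <- function(studies) {
  if (!is.list(studies) || length(studies) == 0)
    stop("studies must be a non-empty list of matrices")
  genes <- rownames(studies[[1]])
  for (s in studies) {
    .check_expression_matrix(s)
    if (!identical(rownames(s), genes))
      stop("all studies must share the same gene universe; ",
           "apply intersect_genes() first")
  }
  scaled <- lapply(studies, function(s) {
    sds <- apply(s, 1L, stats::sd)
    if (any(sds == 0))
      warning(sum(sds == 0), " constant gene row(s) set to zero in a study")
    .standardize_rows(s)
  })
  do.call(cbind, scaled)
}

#' Reduce matrices to their common, sorted gene index
#'
#' @param matrices list of >= 2 genes x samples matrices.
#' @return list of matrices sharing an identical sorted gene index.
#' @export
intersect_genes <- function(matrices) {
  if (length(matrices) < 2) stop("need at least two matrices")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) stop("empty gene intersection")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Remove genes with low global variance
#'
#' Retains genes whose sample variance (denominator n - 1) across all
#' meta-set samples is at least `threshold`; variance strictly below the
#' threshold is removed.
#'
#' @param expr genes x samples matrix.
#' @param threshold variance cutoff (default 0.3).
#' @return filtered matrix.
#' @export
variance_filter <- function(expr, threshold = 0.3) {
  .check_expression_matrix(expr)
  if (threshold < 0) stop("threshold must be >= 0")
  v <- apply(expr, 1L, stats::var)
  keep <- v >= threshold
  if (!any(keep))
    stop("variance filter at threshold ", threshold, " removed every gene")
  expr[keep, , drop = FALSE]
}

#' Relabel one species' genes with the other species' ortholog identifiers
#'
#' Rows of the ortholog table involved in many-to-many mappings are dropped
#' first so the applied map is strictly one-to-one; genes of `expr_b`
#' without a surviving ortholog are dropped (count reported).
#'
#' @param expr_b genes x samples matrix of the species to be relabeled.
#' @param ortholog_table data.frame with columns `species_a`, `species_b`.
#' @return matrix with species-A identifiers as rownames, sorted.
#' @export
map_orthologs <- function(expr_b, ortholog_table) {
  .check_expression_matrix(expr_b, "expr_b")
  stopifnot(all(c("species_a", "species_b") %in% names(ortholog_table)))
  tab <- ortholog_table
  ok <- !(tab$species_a %in% tab$species_a[duplicated(tab$species_a)]) &
        !(tab$species_b %in% tab$species_b[duplicated(tab$species_b)])
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0)
    stop("ortholog table contains no one-to-one mappings")
  hit <- rownames(expr_b) %in% tab$species_b
  if (sum(!hit) > 0)
    message(sum(!hit), " gene(s) without a one-to-one ortholog dropped")
  if (!any(hit)) stop("no genes of expr_b covered by the ortholog table")
  out <- expr_b[hit, , drop = FALSE]
  rownames(out) <- tab$species_a[match(rownames(out), tab$species_b)]
  out[order(rownames(out)), , drop = FALSE]
}
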