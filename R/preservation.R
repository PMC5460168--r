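# Permutation-based module preservation between a reference and a test
# expression set sharing a gene index.  For each reference module, density
# statistics (mean within-module correlation and adjacency, measured in the
# test data) and connectivity statistics (cross-set correlation of
# intramodular connectivity kIM and of module membership kME over the
# module's genes) are converted to Z scores against a null in which module
# labels are randomly permuted across genes; the composite
# Z_summary = (Z_density + Z_connectivity) / 2.

#' Random "gold" sham module
#'
#' Uniformly samples `size` genes without replacement; used as a negative
#' control whose preservation Z should hover around zero.
#'
#' @param gene_ids gene universe.
#' @param size module size (default 100).
#' @param seed seed.
#' @return character vector of sampled gene ids.
#' @export
gold_module <- function(gene_ids, size = 100, seed = 1) {
  if (size > length(gene_ids))
    stop("gold module size exceeds the number of genes")
  set.seed(seed)
  sort(sample(gene_ids, size))
}

#' Preservation interpretation band for a Z_summary value
#'
#' `> 10` high, `5 < Z <= 10` moderate, otherwise low/none.
#'
#' @param z_summary numeric vector.
#' @return character vector of band labels.
#' @export
preservation_band <- function(z_summary) {
  ifelse(is.na(z_summary), NA_character_,
         ifelse(z_summary > 10, "high",
                ifelse(z_summary > 5, "moderate", "low")))
}

#' Permutation module preservation statistics
#'
#' @param ref_expr,test_expr genes x samples matrices with an identical
#'   gene index (samples may differ).
#' @param ref_modules named gene -> label vector of reference modules;
#'   `"unassigned"` is skipped, modules with fewer than 3 genes are skipped
#'   with a warning.
#' @param n_perm number of label permutations (>= 50; default 200).
#' @param beta soft-threshold power for the adjacency-based statistics.
#' @param signed signed adjacency (default FALSE).
#' @param seed seed controlling the permutations and the gold module draw.
#' @param gold_size if non-`NULL`, a random sham module of this size is
#'   added under the label `"gold"` (default 100).
#' @return data.frame with one row per module: `module`, `size`,
#'   `Z_density`, `Z_connectivity`, `Z_summary`, `median_log_p`, `band`;
#'   attributes `n_perm` and `seed`.
#' @export
module_preservation <- function(ref_expr, test_expr, ref_modules,
                                n_perm = 200, beta = 7, signed = FALSE,
                                seed = 1, gold_size = 100) {
  .check_expression_matrix(ref_expr, "ref_expr")
  .check_expression_matrix(test_expr, "test_expr")
  if (!identical(rownames(ref_expr), rownames(test_expr)))
    stop("ref_expr and test_expr must share an identical gene index")
  if (n_perm < 50) stop("n_perm must be >= 50")
  genes <- rownames(ref_expr)
  n <- length(genes)

  set.seed(seed)
  module_sets <- split(names(ref_modules)[names(ref_modules) %in% genes],
                       ref_modules[names(ref_modules) %in% genes])
  module_sets <- module_sets[setdiff(names(module_sets), UNASSIGNED)]
  if (!is.null(gold_size))
    module_sets$gold <- gold_module(genes, gold_size,
                                    seed = sample.int(.Machine$integer.max, 1))
  small <- vapply(module_sets, length, integer(1)) < 3
  if (any(small)) {
    warning("module(s) with < 3 genes skipped: ",
            paste(names(module_sets)[small], collapse = ", "))
    module_sets <- module_sets[!small]
  }
  if (length(module_sets) == 0) stop("no usable modules")

  cor_ref <- stats::cor(t(ref_expr))
  cor_test <- stats::cor(t(test_expr))
  adj_ref <- cor_to_adjacency(cor_ref, beta, signed)
  adj_test <- cor_to_adjacency(cor_test, beta, signed)

  # the four preservation statistics for an index set of genes
  stat_vec <- function(idx) {
    ct <- cor_test[idx, idx]
    at <- adj_test[idx, idx]
    ar <- adj_ref[idx, idx]
    kim_ref <- rowSums(ar) - 1
    kim_test <- rowSums(at) - 1
    kme_ref <- kme_within(ref_expr, idx)
    kme_test <- kme_within(test_expr, idx)
    c(mean_cor = .offdiag_mean(ct),
      mean_adj = .offdiag_mean(at),
      cor_kim = suppressWarnings(stats::cor(kim_ref, kim_test)),
      cor_kme = suppressWarnings(stats::cor(kme_ref, kme_test)))
  }

  res <- lapply(names(module_sets), function(lab) {
    idx <- match(module_sets[[lab]], genes)
    obs <- stat_vec(idx)
    perm <- matrix(NA_real_, n_perm, 4L)
    for (p in seq_len(n_perm))
      perm[p, ] <- stat_vec(sample.int(n, length(idx)))
    mu <- colMeans(perm)
    sdv <- apply(perm, 2L, stats::sd)
    z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
    pval <- (1 + colSums(sweep(perm, 2L, obs, ">="))) / (n_perm + 1)
    data.frame(module = lab, size = length(idx),
               Z_density = stats::median(z[1:2]),
               Z_connectivity = stats::median(z[3:4]),
               median_log_p = stats::median(log10(pval)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$Z_summary <- (out$Z_density + out$Z_connectivity) / 2
  out$band <- preservation_band(out$Z_summary)
  out <- out[, c("module", "size", "Z_density", "Z_connectivity",
                 "Z_summary", "median_log_p", "band")]
  rownames(out) <- NULL
  structure(out, n_perm = n_perm, seed = seed)
}

# kME of a gene set against its own eigengene within one data set
kme_within <- function(expr, idx) {
  block <- .standardize_rows(expr[idx, , drop = FALSE])
  sv <- svd(block, nu = 0, nv = 1)
  v <- sv$v[, 1L]
  if (stats::cor(v, colMeans(block)) < 0) v <- -v
  as.vector(stats::cor(t(expr[idx, , drop = FALSE]), v))
}
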