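# Weighted co-expression networks: soft-thresholded adjacency, topological
# overlap, module detection by adaptive pruning of the average-linkage
# dendrogram, eigengene-based module merging, and the cross-species
# consensus network built from a weighted average of correlation matrices.

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^beta`; signed:
#' `a_ij = ((1 + cor)/2)^beta`, Pearson correlation across samples.  The
#' diagonal is forced to 1.
#'
#' @param expr genes x samples matrix (>= 3 samples, no constant genes).
#' @param beta soft-threshold power (default 7).
#' @param signed use the signed transform (default FALSE, unsigned).
#' @return symmetric adjacency matrix in \[0, 1\] with attributes `beta`
#'   and `signed`.
#' @export
coexpression_adjacency <- function(expr, beta = 7, signed = FALSE) {
  .check_expression_matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  a <- cor_to_adjacency(stats::cor(t(expr)), beta, signed)
  structure(a, beta = beta, signed = signed)
}

cor_to_adjacency <- function(cmat, beta, signed = FALSE) {
  a <- if (signed) ((1 + cmat) / 2)^beta else abs(cmat)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a network's connectivity distribution
#'
#' Bins the connectivities `k_i = sum_{j != i} a_ij` into equal-width bins,
#' regresses `log10 p(k)` on `log10 mean(k)` over occupied bins, and returns
#' the R-squared signed by the slope (negative slope, the scale-free case,
#' gives a positive value).
#'
#' @param adjacency symmetric adjacency matrix.
#' @param n_bins number of connectivity bins (default 10).
#' @return signed R-squared, with attributes `slope` and `n_bins_used`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- colSums(adjacency) - diag(adjacency)
  if (diff(range(k)) == 0)
    stop("all nodes have identical connectivity; cannot bin degrees")
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  counts <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  occupied <- !is.na(counts) & counts > 0 & kmean > 0
  if (sum(occupied) < 2) stop("fewer than two occupied degree bins")
  p <- counts[occupied] / length(k)
  fit <- stats::lm(log10(p) ~ log10(kmean[occupied]))
  slope <- stats::coef(fit)[2L]
  r2 <- summary(fit)$r.squared
  structure(sign(slope) * -r2, slope = unname(slope),
            n_bins_used = sum(occupied))
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for i != j, where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`; the
#' diagonal is 1.  `1 - w` is the clustering dissimilarity.
#'
#' @param adjacency symmetric adjacency in \[0, 1\].
#' @return symmetric TOM in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unclass(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a0 <- adjacency
  diag(a0) <- 0
  l <- a0 %*% a0           # (l)_ij = sum_{u != i, j} a_iu a_uj since diag 0
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  w <- (l + a0) / denom
  diag(w) <- 1
  dimnames(w) <- dimnames(adjacency)
  w
}

#' Detect modules by adaptive pruning of the average-linkage dendrogram
#'
#' Genes are clustered by average linkage on the dissimilarity (typically
#' `1 - TOM`).  The dendrogram is then pruned top-down: a branch is accepted
#' as a module when it is *tight* relative to its surroundings — the ratio
#' of its mean internal dissimilarity to its mean dissimilarity to all other
#' genes is at most a cutoff — unless its two children are themselves
#' mutually distinct by the same ratio criterion, in which case the search
#' descends.  Branches that never satisfy the criterion fragment until their
#' pieces fall below `min_module_size` and are labeled `"unassigned"`.
#'
#' `deep_split` (0-4) relaxes the tightness cutoff
#' (`0.85 + 0.02 * deep_split`), producing more and finer modules at higher
#' values.  Accepted branches are then trimmed gene-wise: a member whose
#' mean dissimilarity to the rest of the branch is not clearly smaller than
#' its mean dissimilarity to the branch's complement (ratio > 0.95) is
#' released to `"unassigned"` — this strips weakly attached stragglers that
#' average linkage hangs onto an otherwise tight branch.  Labels are
#' `"M1", "M2", ...` in order of decreasing module size.
#'
#' @param dissimilarity square symmetric matrix in \[0, 1\] with gene
#'   dimnames.
#' @param deep_split split sensitivity, 0-4 (default 1).
#' @param min_module_size smallest reportable module (default 30).
#' @return named character vector: gene -> module label.
#' @export
detect_modules <- function(dissimilarity, deep_split = 1, min_module_size = 30) {
  d <- unclass(dissimilarity)
  if (!isSymmetric(d, tol = 1e-8)) stop("dissimilarity must be symmetric")
  if (is.null(rownames(d))) stop("dissimilarity needs gene dimnames")
  if (deep_split < 0 || deep_split > 4) stop("deep_split must be in 0..4")
  n <- nrow(d)
  genes <- rownames(d)
  labels <- stats::setNames(rep(UNASSIGNED, n), genes)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(labels)
  }
  cutoff <- min(0.85 + 0.02 * deep_split, 0.98)
  hc <- stats::hclust(stats::as.dist(d), method = "average")

  # leaf index sets per internal node
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- hc$merge[i, ]
    left <- if (m[1] < 0) -m[1] else members[[m[1]]]
    right <- if (m[2] < 0) -m[2] else members[[m[2]]]
    members[[i]] <- c(left, right)
  }
  node_members <- function(node) if (node < 0) -node else members[[node]]

  mean_between <- function(i, j) mean(d[i, j, drop = FALSE])
  mean_within <- function(i) {
    if (length(i) < 2) return(0)
    .offdiag_mean(d[i, i, drop = FALSE])
  }
  tight <- function(mem) {
    comp <- setdiff(seq_len(n), mem)
    if (length(comp) == 0) return(FALSE)   # the root is always considered for splitting
    bet <- mean_between(mem, comp)
    if (bet <= 0) return(FALSE)
    (mean_within(mem) / bet) <= cutoff
  }
  children_distinct <- function(li, ri) {
    pool_within <- c(d[li, li][upper.tri(diag(length(li)))],
                     d[ri, ri][upper.tri(diag(length(ri)))])
    w <- if (length(pool_within)) mean(pool_within) else 0
    bet <- mean_between(li, ri)
    bet > 0 && (w / bet) <= cutoff
  }

  trim_cutoff <- 0.95
  trim_members <- function(mem) {
    comp <- setdiff(seq_len(n), mem)
    if (length(comp) == 0) return(mem)
    repeat {
      if (length(mem) < 2) break
      to_comp <- rowMeans(d[mem, comp, drop = FALSE])
      within <- rowSums(d[mem, mem, drop = FALSE]) / (length(mem) - 1)
      keep <- to_comp > 0 & (within / to_comp) <= trim_cutoff
      if (all(keep)) break
      mem <- mem[keep]
    }
    mem
  }
  next_id <- 0L
  assign_module <- function(mem) {
    core <- trim_members(mem)
    if (length(core) < min_module_size) return(FALSE)
    next_id <<- next_id + 1L
    labels[core] <<- sprintf("tmp%04d", next_id)
    TRUE
  }
  cut_node <- function(node) {
    mem <- node_members(node)
    if (length(mem) < min_module_size) return(FALSE)  # stays unassigned
    if (node < 0) return(FALSE)
    m <- hc$merge[node, ]
    li <- node_members(m[1]); ri <- node_members(m[2])
    if (tight(mem)) {
      both_big <- length(li) >= min_module_size && length(ri) >= min_module_size
      if (both_big && children_distinct(li, ri)) {
        okl <- cut_node(m[1]); okr <- cut_node(m[2])
        if (okl || okr) return(TRUE)
      }
      return(assign_module(mem))
    }
    # not tight: descend into sizeable children, small ones stay unassigned
    any(c(if (length(li) >= min_module_size) cut_node(m[1]) else FALSE,
          if (length(ri) >= min_module_size) cut_node(m[2]) else FALSE))
  }
  found <- cut_node(n - 1L)
  if (!found)
    warning("no distinct module structure detected; all genes unassigned")
  relabel_by_size(labels)
}

relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), UNASSIGNED)
  if (length(mods) == 0) return(labels)
  sizes <- table(labels[labels != UNASSIGNED])
  ord <- names(sizes)[order(-as.integer(sizes), names(sizes))]  # size, then name
  new <- stats::setNames(sprintf("M%d", seq_along(ord)), ord)
  out <- labels
  out[labels != UNASSIGNED] <- new[labels[labels != UNASSIGNED]]
  out
}

#' Merge modules with highly correlated eigengenes
#'
#' Computes module eigengenes, clusters them by average linkage on
#' `1 - cor`, and merges every group of modules joined below `cut_height`;
#' eigengenes are recomputed and the procedure repeated until no pair
#' remains below the cut.  With `expr_b` supplied (consensus mode), the
#' eigengene dissimilarity is `1 -` the weighted average of the two species'
#' eigengene correlations.
#'
#' @param expr genes x samples matrix.
#' @param modules named gene -> label vector (from [detect_modules()]).
#' @param cut_height merge threshold on eigengene dissimilarity
#'   (default 0.25).
#' @param expr_b optional second-species matrix over the same genes.
#' @param weights two nonnegative weights summing to 1 (consensus mode).
#' @return merged module assignment, relabeled by size.
#' @export
merge_close_modules <- function(expr, modules, cut_height = 0.25,
                                expr_b = NULL, weights = c(0.5, 0.5)) {
  labels <- modules
  for (pass in 1:20) {
    mods <- setdiff(unique(labels), UNASSIGNED)
    if (length(mods) < 2) break
    me_cor <- consensus_eigengene_cor(expr, labels, expr_b, weights)
    dis <- 1 - me_cor
    hc <- stats::hclust(stats::as.dist(dis), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    if (max(grp) == length(mods)) break  # nothing below the cut
    # merge each group into its largest member's label
    for (g in unique(grp)) {
      inside <- names(grp)[grp == g]
      if (length(inside) < 2) next
      sizes <- vapply(inside, function(l) sum(labels == l), integer(1))
      target <- inside[which.max(sizes)]
      labels[labels %in% inside] <- target
    }
  }
  relabel_by_size(labels)
}

consensus_eigengene_cor <- function(expr, labels, expr_b = NULL,
                                    weights = c(0.5, 0.5)) {
  me_a <- module_eigengenes(expr, labels)
  c_a <- stats::cor(t(me_a))
  if (is.null(expr_b)) return(c_a)
  me_b <- module_eigengenes(expr_b, labels)
  c_b <- stats::cor(t(me_b))
  weights[1] * c_a + weights[2] * c_b
}

#' Detect consensus modules across two species
#'
#' The consensus correlation is the weighted average of the two species'
#' Pearson correlation matrices over a shared gene index; adjacency, TOM,
#' dendrogram pruning and eigengene merging are then applied to it with the
#' same parameters as for single-species networks.
#'
#' @param expr_a,expr_b genes x samples matrices with an identical gene
#'   index (species B already ortholog-mapped to species A identifiers).
#' @param weights nonnegative weights for the two correlation matrices,
#'   summing to 1 (default equal).
#' @param beta soft-threshold power (default 7).
#' @param signed signed network (default FALSE).
#' @param deep_split,min_module_size,cut_height as in [detect_modules()] and
#'   [merge_close_modules()].
#' @return named gene -> consensus module label vector.
#' @export
consensus_modules <- function(expr_a, expr_b, weights = c(0.5, 0.5),
                              beta = 7, signed = FALSE, deep_split = 1,
                              min_module_size = 30, cut_height = 0.25) {
  .check_expression_matrix(expr_a, "expr_a")
  .check_expression_matrix(expr_b, "expr_b")
  if (!identical(rownames(expr_a), rownames(expr_b)))
    stop("expr_a and expr_b must share an identical gene index")
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must be nonnegative and sum to 1")
  cons_cor <- weights[1] * stats::cor(t(expr_a)) +
              weights[2] * stats::cor(t(expr_b))
  adj <- cor_to_adjacency(cons_cor, beta, signed)
  tomd <- 1 - topological_overlap(adj)
  labels <- detect_modules(tomd, deep_split, min_module_size)
  if (length(setdiff(unique(labels), UNASSIGNED)) >= 2)
    labels <- merge_close_modules(expr_a, labels, cut_height,
                                  expr_b = expr_b, weights = weights)
  labels
}

#' Single-species network module detection pipeline
#'
#' Convenience wrapper chaining [coexpression_adjacency()],
#' [topological_overlap()], [detect_modules()] and
#' [merge_close_modules()].
#'
#' @inheritParams consensus_modules
#' @param expr genes x samples matrix.
#' @return named gene -> module label vector.
#' @export
network_modules <- function(expr, beta = 7, signed = FALSE, deep_split = 1,
                            min_module_size = 30, cut_height = 0.25) {
  adj <- coexpression_adjacency(expr, beta, signed)
  tomd <- 1 - topological_overlap(adj)
  labels <- detect_modules(tomd, deep_split, min_module_size)
  if (length(setdiff(unique(labels), UNASSIGNED)) >= 2)
    labels <- merge_close_modules(expr, labels, cut_height)
  labels
}
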