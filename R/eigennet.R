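# Differential eigengene network analysis: eigengene adjacency, the
# pairwise preservation network between two species' eigengene networks,
# scaled connectivity, density, and meta-module detection.

#' Eigengene network adjacency
#'
#' `a_IJ = (1 + cor(E_I, E_J)) / 2` with Pearson correlation; diagonal 1.
#'
#' @param eigengenes modules x samples matrix.
#' @return symmetric modules x modules adjacency in \[0, 1\].
#' @export
eigengene_adjacency <- function(eigengenes) {
  if (nrow(eigengenes) < 2) stop("need at least two eigengenes")
  sds <- apply(eigengenes, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant eigengene(s): ",
         paste(rownames(eigengenes)[sds == 0], collapse = ", "))
  a <- (1 + stats::cor(t(eigengenes))) / 2
  diag(a) <- 1
  a
}

.check_cor_pair <- function(cor_a, cor_b) {
  if (!identical(dim(cor_a), dim(cor_b)) ||
      !identical(dimnames(cor_a), dimnames(cor_b)))
    stop("cor_a and cor_b must share the same module index")
  if (nrow(cor_a) < 2) stop("need at least two modules")
  invisible(NULL)
}

#' Pairwise preservation network between two eigengene networks
#'
#' `Preserv_IJ = 1 - |cor_a(E_I, E_J) - cor_b(E_I, E_J)| / 2`; diagonal 1.
#'
#' @param cor_a,cor_b module x module eigengene correlation matrices over
#'   the same (consensus) module index.
#' @return symmetric preservation matrix in \[0, 1\].
#' @export
preservation_network <- function(cor_a, cor_b) {
  .check_cor_pair(cor_a, cor_b)
  p <- 1 - abs(cor_a - cor_b) / 2
  diag(p) <- 1
  p
}

#' Scaled connectivity of the preservation network
#'
#' `C_I = 1 - sum_{J != I} |cor_a(E_I, E_J) - cor_b(E_I, E_J)| / (2 (N - 1))`,
#' the mean preservation-network adjacency of module I with all others.
#'
#' @inheritParams preservation_network
#' @return named numeric vector of per-module scaled connectivities.
#' @export
eigengene_scaled_connectivity <- function(cor_a, cor_b) {
  .check_cor_pair(cor_a, cor_b)
  n <- nrow(cor_a)
  dif <- abs(cor_a - cor_b)
  diag(dif) <- 0
  stats::setNames(1 - rowSums(dif) / (2 * (n - 1)), rownames(cor_a))
}

#' Density of the preservation network
#'
#' `D = 1 - sum_I sum_{J != I} |cor_a - cor_b| / (2 N (N - 1))`, the mean
#' scaled connectivity; 1 means the eigengene correlation structure is
#' perfectly preserved across the two networks.
#'
#' @inheritParams preservation_network
#' @return scalar in \[0, 1\].
#' @export
eigengene_density <- function(cor_a, cor_b) {
  .check_cor_pair(cor_a, cor_b)
  n <- nrow(cor_a)
  dif <- abs(cor_a - cor_b)
  diag(dif) <- 0
  1 - sum(dif) / (2 * n * (n - 1))
}

#' Meta-modules of highly positively correlated eigengenes
#'
#' For each species, eigengenes are clustered by average linkage on
#' `1 - cor` and the tree is cut at `cut_height`; the agreement of the two
#' species' meta-module partitions is reported as an adjusted Rand index.
#'
#' @param eigengenes_a,eigengenes_b modules x samples matrices over the
#'   same (consensus) module labels.
#' @param cut_height tree-cut height on `1 - cor` (default 0.5).
#' @return list: `labels_a`, `labels_b` (named integer meta-module labels)
#'   and `ari`.
#' @export
meta_modules <- function(eigengenes_a, eigengenes_b, cut_height = 0.5) {
  if (!identical(rownames(eigengenes_a), rownames(eigengenes_b)))
    stop("the two eigengene sets must cover the same modules")
  one <- function(me) {
    if (nrow(me) < 2) stop("need at least two eigengenes")
    dis <- 1 - stats::cor(t(me))
    hc <- stats::hclust(stats::as.dist(dis), method = "average")
    stats::cutree(hc, h = cut_height)
  }
  la <- one(eigengenes_a)
  lb <- one(eigengenes_b)
  list(labels_a = la, labels_b = lb,
       ari = adjusted_rand_index(la, lb))
}

#' Compare two species' eigengene networks
#'
#' Wrapper computing both eigengene adjacencies, the preservation network,
#' per-module scaled connectivity, density D, and meta-modules.
#'
#' @inheritParams meta_modules
#' @return list with `adjacency_a`, `adjacency_b`, `preservation`,
#'   `scaled_connectivity`, `density`, `meta_modules`, `n_modules`.
#' @export
compare_eigengene_networks <- function(eigengenes_a, eigengenes_b,
                                       cut_height = 0.5) {
  cor_a <- stats::cor(t(eigengenes_a))
  cor_b <- stats::cor(t(eigengenes_b))
  list(adjacency_a = eigengene_adjacency(eigengenes_a),
       adjacency_b = eigengene_adjacency(eigengenes_b),
       preservation = preservation_network(cor_a, cor_b),
       scaled_connectivity = eigengene_scaled_connectivity(cor_a, cor_b),
       density = eigengene_density(cor_a, cor_b),
       meta_modules = meta_modules(eigengenes_a, eigengenes_b, cut_height),
       n_modules = nrow(cor_a))
}
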