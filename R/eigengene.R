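# Module eigengenes (first right-singular vectors of standardized module
# blocks), module membership (kME), module-trait association, Kruskal-Wallis
# eigengene tests and MDS-based sample regrouping.

#' Module eigengenes
#'
#' For each module (the `"unassigned"` label is skipped), gene rows are
#' standardized to mean 0, sd 1 and the eigengene is the first
#' right-singular vector of the standardized genes x samples block.  The
#' sign is oriented so that the eigengene correlates nonnegatively with the
#' module's mean standardized expression profile.  A single-gene module's
#' eigengene is the standardized gene itself (with a warning).
#'
#' @param expr genes x samples matrix.
#' @param modules named gene -> label vector covering `rownames(expr)`.
#' @return modules x samples matrix with attribute `variance_explained`
#'   (named numeric: fraction of the block's variance carried by the first
#'   singular component).
#' @export
module_eigengenes <- function(expr, modules) {
  .check_expression_matrix(expr)
  missing <- setdiff(rownames(expr), names(modules))
  if (length(missing)) stop("modules does not label every gene of expr")
  labs <- setdiff(unique(modules[rownames(expr)]), UNASSIGNED)
  labs <- labs[order(labs)]
  if (length(labs) == 0) stop("no modules besides 'unassigned'")
  me <- matrix(NA_real_, length(labs), ncol(expr),
               dimnames = list(labs, colnames(expr)))
  varex <- stats::setNames(numeric(length(labs)), labs)
  for (l in labs) {
    genes <- rownames(expr)[modules[rownames(expr)] == l]
    block <- .standardize_rows(expr[genes, , drop = FALSE])
    if (length(genes) == 1L) {
      warning("module '", l, "' has a single gene; eigengene equals it")
      me[l, ] <- block[1L, ] / sqrt(sum(block[1L, ]^2))
      varex[l] <- 1
      next
    }
    sv <- svd(block, nu = 0, nv = 1)
    v <- sv$v[, 1L]
    if (stats::cor(v, colMeans(block)) < 0) v <- -v
    me[l, ] <- v
    varex[l] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(me, variance_explained = varex)
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's expression profile with every module
#' eigengene.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes modules x samples matrix from [module_eigengenes()].
#' @return genes x modules correlation matrix in \[-1, 1\].
#' @export
module_membership <- function(expr, eigengenes) {
  if (!identical(colnames(expr), colnames(eigengenes)))
    stop("expr and eigengenes must share the same sample index")
  stats::cor(t(expr), t(eigengenes))
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each binary trait
#' column, with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom.  A constant trait column yields `NA` with a warning.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits samples x traits matrix of 0/1 membership codes.
#' @return list with matrices `cor` and `p` (modules x traits).
#' @export
module_trait_cor <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (!identical(colnames(eigengenes), rownames(traits)))
    stop("eigengenes and traits must share the same samples")
  if (!all(traits %in% c(0, 1)))
    stop("traits must be binary 0/1 membership codes")
  n <- ncol(eigengenes)
  const <- apply(traits, 2L, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning("constant trait column(s): ",
            paste(colnames(traits)[const], collapse = ", "))
  }
  r <- matrix(NA_real_, nrow(eigengenes), ncol(traits),
              dimnames = list(rownames(eigengenes), colnames(traits)))
  if (any(!const))
    r[, !const] <- stats::cor(t(eigengenes), traits[, !const, drop = FALSE])
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(cor = r, p = p)
}

#' Kruskal-Wallis test of an eigengene across sample groups
#'
#' Rank-based one-way analysis of variance with tie correction; the H
#' statistic is referred to a chi-square distribution with
#' (number of groups - 1) degrees of freedom.
#'
#' @param eigengene numeric vector of one eigengene across samples.
#' @param groups categorical group labels, >= 2 groups.
#' @return named numeric: `statistic` (H) and `p.value`.
#' @export
kruskal_wallis_me <- function(eigengene, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two groups")
  if (stats::var(eigengene) == 0)  # all ranks tied: no evidence, H = 0
    return(c(statistic = 0, p.value = 1))
  kt <- stats::kruskal.test(eigengene, groups)
  c(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Regroup samples by multidimensional scaling
#'
#' Classical (Torgerson) MDS of the Euclidean distances between sample
#' expression profiles; the first two coordinates are partitioned into `k`
#' groups by k-means (fixed seed, 25 restarts).
#'
#' @param expr genes x samples matrix.
#' @param sample_subset sample ids to regroup (default all).
#' @param k number of groups (>= 2, < subset size).
#' @param seed seed for the k-means restarts.
#' @return named integer vector: sample -> group label, plus attribute
#'   `coordinates` (samples x 2 MDS coordinates).
#' @export
mds_regroup <- function(expr, sample_subset = colnames(expr), k = 2,
                        seed = 1) {
  .check_expression_matrix(expr)
  if (k < 2) stop("k must be >= 2")
  if (k >= length(sample_subset)) stop("k must be smaller than the subset")
  x <- t(expr[, sample_subset, drop = FALSE])
  dd <- stats::dist(x)
  n_coord <- min(2L, length(sample_subset) - 1L)
  coords <- stats::cmdscale(dd, k = n_coord)
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = 25)
  structure(stats::setNames(km$cluster, sample_subset),
            coordinates = coords)
}
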