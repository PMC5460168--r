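#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Standardize the rows of a matrix
#'
#' Each row is centred to mean 0 and scaled to sample standard deviation 1
#' (denominator n - 1).  Constant rows are returned as all zeros.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape.
#' @keywords internal
.standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  out <- (x - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

.check_expression_matrix <- function(x, name = "expr") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(name, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop(name, " has duplicated gene identifiers")
  if (any(!is.finite(x)))
    stop(name, " contains non-finite values")
  invisible(x)
}

.offdiag_mean <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  (sum(m) - sum(diag(m))) / (n * (n - 1L))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expected value under independent
#' random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# label reserved for genes belonging to no module (WGCNA's "grey")
UNASSIGNED <- "unassigned"
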