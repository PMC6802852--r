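#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-rank handling of ties; the exact null distribution is used when the
#' pooled sample size is at most 16 and there are no ties, otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction. The returned statistic is the Mann-Whitney U for the first
#' sample.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return A list with \code{statistic} and \code{p} (two-sided, clamped to
#'   (0, 1]).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1 || length(b) < 1)
    stop("both samples must be non-empty")
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stop("samples must be numeric with no missing values")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b) <= 16) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  p <- res$p.value
  if (!is.finite(p)) p <- 1    # degenerate: zero rank variance (all tied)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(statistic = unname(res$statistic), p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment:
#' \code{q_i = min over j with p_j >= p_i of (m * p_j / rank_j)}, clamped
#' to at most 1; order-preserving.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing an overlap of at least \code{k} between a query
#' set of size \code{n} and a marker set of size \code{K} drawn from a
#' universe of \code{M} genes: \code{P(X >= k)} for
#' \code{X ~ Hypergeometric(M, K, n)}. Computed through the distribution
#' function, which works in log space internally, so extreme tails are
#' stable.
#'
#' @param M Universe size.
#' @param K Marker-set size within the universe.
#' @param n Query-set size within the universe.
#' @param k Observed overlap.
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeom_upper_tail <- function(M, K, n, k) {
  for (v in list(M, K, n, k))
    if (!is.numeric(v) || length(v) != 1 || v != round(v))
      stop("M, K, n, k must be single integers")
  if (K > M || n > M || K < 0 || n < 0 || M < 0)
    stop("require 0 <= K <= M and 0 <= n <= M")
  if (k < max(0, n + K - M) || k > min(n, K))
    stop("overlap k = ", k, " impossible for M=", M, ", K=", K, ", n=", n)
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Marker-set enrichment of a query gene set
#'
#' Convenience wrapper assembling the contingency quantities and calling
#' \code{\link{hypergeom_upper_tail}}. The universe defaults to all genes
#' tested in the differential-expression step that produced the query; pass
#' it explicitly to override.
#'
#' @param query Character vector or \code{\link{gene_set}} of query genes
#'   (e.g. cluster-specific genes).
#' @param markers Character vector or \code{gene_set} of marker genes.
#' @param universe Character vector of all genes considered.
#' @return A one-row data frame of class \code{enrichment_result} with
#'   columns \code{set}, \code{M}, \code{K}, \code{n}, \code{k},
#'   \code{p_upper}.
#' @export
marker_enrichment <- function(query, markers, universe) {
  qname <- if (inherits(query, "gene_set")) query$name else "query"
  mname <- if (inherits(markers, "gene_set")) markers$name else "markers"
  if (inherits(query, "gene_set")) query <- query$genes
  if (inherits(markers, "gene_set")) markers <- markers$genes
  universe <- unique(as.character(universe))
  q <- intersect(query, universe)
  m <- intersect(markers, universe)
  k <- length(intersect(q, m))
  out <- data.frame(set = paste(qname, "vs", mname),
                    M = length(universe), K = length(m),
                    n = length(q), k = k,
                    p_upper = hypergeom_upper_tail(length(universe),
                                                   length(m), length(q), k),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Per-gene Wilcoxon one-vs-rest / A-vs-B scan. Returns the DE table shared
# by cluster_specific_genes and the branch screen. Means are of lognorm
# values; the fold change de-logs them with a pseudocount of 1.
de_scan <- function(norm, idx_a, idx_b) {
  va <- unclass(norm)[idx_a, , drop = FALSE]
  vb <- unclass(norm)[idx_b, , drop = FALSE]
  mean_a <- colMeans(va)
  mean_b <- colMeans(vb)
  lfc <- log2((expm1(mean_a) + 1) / (expm1(mean_b) + 1))
  stat <- numeric(ncol(norm))
  p <- numeric(ncol(norm))
  for (j in seq_len(ncol(norm))) {
    w <- wilcoxon_rank_sum(va[, j], vb[, j])
    stat[j] <- w$statistic
    p[j] <- w$p
  }
  q <- bh_adjust(p)
  data.frame(gene = colnames(norm), mean_a = mean_a, mean_b = mean_b,
             log2fc = lfc, statistic = stat, p = p, q = q,
             direction = ifelse(lfc > 0, "A>B",
                                ifelse(lfc < 0, "B>A", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes specifically expressed in one cluster
#'
#' One-vs-rest Wilcoxon rank-sum test per gene, Benjamini-Hochberg
#' adjusted across genes; a gene is flagged specific when it is
#' significantly higher in the target cluster than in the rest and its
#' absolute log2 fold change passes \code{min_lfc}.
#'
#' @param norm An \code{\link{expr_matrix}} with unit \code{lognorm}.
#' @param labels Cluster label per cell (length \code{nrow(norm)}).
#' @param target The cluster of interest.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_lfc Minimum log2 fold change (default 0.25).
#' @return A data frame of class \code{de_table}: per gene the group means,
#'   log2 fold change, statistic, p, q, direction and logical
#'   \code{specific}.
#' @export
cluster_specific_genes <- function(norm, labels, target, alpha = 0.05,
                                   min_lfc = 0.25) {
  stopifnot(inherits(norm, "expr_matrix"))
  if (expr_unit(norm) != "lognorm")
    stop("cluster_specific_genes expects unit 'lognorm'")
  labels <- as.character(labels)
  if (length(labels) != nrow(norm))
    stop("labels must have one entry per cell")
  if (!target %in% labels) stop("target cluster '", target, "' not found")
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  idx_a <- which(labels == target)
  if (length(idx_a) == 1)
    warning("singleton target cluster; normal approximation only")
  tab <- de_scan(norm, idx_a, which(labels != target))
  tab$specific <- tab$q < alpha & tab$direction == "A>B" &
    abs(tab$log2fc) >= min_lfc
  class(tab) <- c("de_table", "data.frame")
  tab
}
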