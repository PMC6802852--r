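# Cells of each branch at each post-bifurcation timepoint. Branch
# membership is every cell in any tree descendant of the child node.
branch_cells_by_timepoint <- function(tree, bif, children) {
  tp_of <- stats::setNames(tree$nodes$timepoint, tree$nodes$node_id)
  lapply(children, function(ch) {
    desc <- tree_descendants(tree, ch)
    split(unlist(tree$cells[desc], use.names = FALSE),
          rep(tp_of[desc], lengths(tree$cells[desc])))
  })
}

#' Pre-bifurcation expression variability
#'
#' Scores every gene for variability among the cells of the bifurcation's
#' parent node only — the population "right before" the split — using the
#' same bin-standardized dispersion as \code{\link{select_hvg}}: dispersion
#' is variance/mean of the log-normalized values, standardized within
#' equal-frequency mean bins. Rank 1 is the most variable gene. A gene that
#' acts as an upstream switch is typically bimodal here, which inflates its
#' dispersion far beyond its expression-matched peers.
#'
#' @param norm An \code{\link{expr_matrix}} with unit \code{lognorm}
#'   covering the tree's cells.
#' @param tree A \code{\link{build_tree}} result.
#' @param bif A \code{\link{detect_bifurcations}} event from that tree.
#' @param nbin Number of mean bins (default 20).
#' @return A data frame of class \code{variability_table}: gene, mean,
#'   dispersion, z, bin, var_rank. Ranks are a permutation of 1..G; ties in
#'   z break by gene id.
#' @export
prebifurcation_variability <- function(norm, tree, bif, nbin = 20) {
  stopifnot(inherits(tree, "lineage_tree"),
            inherits(bif, "bifurcation_event"))
  if (expr_unit(norm) != "lognorm")
    stop("prebifurcation_variability expects unit 'lognorm'")
  if (!bif$parent %in% tree$nodes$node_id)
    stop("bifurcation parent not found in tree")
  cells <- tree$cells[[bif$parent]]
  if (length(cells) < 3)
    stop("parent node has fewer than 3 cells; variability is not useful")
  if (!all(cells %in% rownames(norm)))
    stop("parent cells missing from the expression matrix")
  tab <- dispersion_table(norm[cells, , drop = FALSE], nbin = nbin)
  tab$var_rank <- order(order(-tab$z, tab$gene))
  class(tab) <- c("variability_table", "data.frame")
  tab
}

#' Consistent differential expression between branches after a bifurcation
#'
#' For every timepoint after the split that both branches reach, tests each
#' gene between the two branches' cells (Wilcoxon rank-sum,
#' Benjamini-Hochberg across genes within the timepoint). A gene is
#' \emph{consistent} when it is significant at every shared timepoint with
#' the same fold-change direction. The DE rank orders genes by their worst
#' (largest) adjusted p across timepoints, breaking ties by the smallest
#' absolute log2 fold change (larger is better), then gene id — rewarding
#' genes that are strong at all timepoints.
#'
#' @inheritParams prebifurcation_variability
#' @param alpha Adjusted-p cutoff used for the consistent flag (default
#'   0.05). The per-timepoint q-values are returned, so the flag can be
#'   recomputed under another alpha by \code{\link{screen_regulators}}.
#' @param children For events with more than two children, the pair of
#'   child node ids to compare; defaults to the event's children when there
#'   are exactly two.
#' @return A data frame of class \code{branch_de_table}: gene, max_q,
#'   min_abs_lfc, direction, same_direction, consistent, de_rank; the
#'   \code{"per_timepoint"} attribute holds the full per-timepoint DE
#'   tables, and \code{"skipped_timepoints"} any timepoint one branch did
#'   not reach.
#' @export
branch_consistent_de <- function(norm, tree, bif, alpha = 0.05,
                                 children = NULL) {
  stopifnot(inherits(tree, "lineage_tree"),
            inherits(bif, "bifurcation_event"))
  if (expr_unit(norm) != "lognorm")
    stop("branch_consistent_de expects unit 'lognorm'")
  if (is.null(children)) {
    if (length(bif$children) != 2)
      stop("event has ", length(bif$children),
           " children; pass `children` to pick the pair to screen")
    children <- bif$children
  }
  if (length(children) != 2 || !all(children %in% bif$children))
    stop("`children` must be two child nodes of the event")
  bc <- branch_cells_by_timepoint(tree, bif, children)
  tps <- tree$timepoints
  it <- match(bif$timepoint, tps)
  if (it >= length(tps))
    stop("no timepoint after the bifurcation")
  post <- tps[(it + 1):length(tps)]
  shared <- character(0); skipped <- character(0)
  for (tp in post) {
    na <- length(bc[[1]][[tp]]); nb <- length(bc[[2]][[tp]])
    if (is.null(bc[[1]][[tp]]) || is.null(bc[[2]][[tp]]) ||
        na == 0 || nb == 0) {
      skipped <- c(skipped, tp)
      warning("branch extinct at timepoint ", tp, "; timepoint skipped")
    } else if (na < 2 || nb < 2) {
      stop("branch with fewer than 2 cells at shared timepoint ", tp)
    } else shared <- c(shared, tp)
  }
  if (!length(shared))
    stop("no shared post-bifurcation timepoint between the branches")
  per_tp <- lapply(shared, function(tp)
    de_scan(norm, match(bc[[1]][[tp]], rownames(norm)),
            match(bc[[2]][[tp]], rownames(norm))))
  names(per_tp) <- shared
  qs <- sapply(per_tp, `[[`, "q")
  lfcs <- sapply(per_tp, `[[`, "log2fc")
  qs <- matrix(qs, ncol = length(shared))
  lfcs <- matrix(lfcs, ncol = length(shared))
  max_q <- apply(qs, 1, max)
  min_abs_lfc <- apply(abs(lfcs), 1, min)
  same_dir <- apply(lfcs, 1, function(v) all(v > 0) || all(v < 0))
  direction <- ifelse(!same_dir, "none",
                      ifelse(lfcs[, 1] > 0, "A>B", "B>A"))
  consistent <- same_dir & max_q < alpha
  genes <- per_tp[[1]]$gene
  out <- data.frame(gene = genes, max_q = max_q,
                    min_abs_lfc = min_abs_lfc, direction = direction,
                    same_direction = same_dir, consistent = consistent,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$de_rank <- order(order(out$max_q, -out$min_abs_lfc, out$gene))
  attr(out, "per_timepoint") <- per_tp
  attr(out, "skipped_timepoints") <- skipped
  attr(out, "children") <- children
  attr(out, "alpha") <- alpha
  class(out) <- c("branch_de_table", "data.frame")
  out
}

#' Screen for upstream regulators of a bifurcation
#'
#' Combines the two regulator criteria: a putative upstream regulator must
#' (1) be consistently differentially expressed between the two branches
#' after the bifurcation and (2) be highly variably expressed in the
#' parent population right before it. Criterion (2) passes genes whose
#' variability rank falls in the top \code{var_quantile} fraction;
#' criterion (1) passes genes whose per-timepoint adjusted p stays below
#' \code{alpha} with a stable direction. The combined rank of a gene is
#' the worse (max) of its variability and DE ranks; ties break by rank
#' sum, then gene id.
#'
#' @param varrecs A \code{\link{prebifurcation_variability}} table.
#' @param derecs A \code{\link{branch_consistent_de}} table over the same
#'   gene universe.
#' @param tf_list Optional \code{\link{gene_set}} of transcription
#'   factors; adds a TF flag and a TF-only view of the regulator list.
#' @param var_quantile Fraction of most-variable genes passing criterion
#'   (2) (default 0.10).
#' @param alpha Adjusted-p cutoff for criterion (1) (default 0.05).
#' @return An object of class \code{regulator_screen}: \code{table} (all
#'   genes, ordered by combined rank, with pass flags), \code{regulators}
#'   (the rows passing both criteria), and \code{tf_regulators} when a TF
#'   list was given.
#' @export
screen_regulators <- function(varrecs, derecs, tf_list = NULL,
                              var_quantile = 0.10, alpha = 0.05) {
  stopifnot(inherits(varrecs, "variability_table"),
            inherits(derecs, "branch_de_table"))
  common <- intersect(varrecs$gene, derecs$gene)
  if (!length(common))
    stop("variability and DE tables share no genes")
  v <- varrecs[match(common, varrecs$gene), ]
  d <- derecs[match(common, derecs$gene), ]
  g <- length(common)
  pass_var <- v$var_rank <= ceiling(var_quantile * g)
  pass_de <- d$same_direction & d$max_q < alpha
  tab <- data.frame(gene = common,
                    var_rank = v$var_rank, z = v$z,
                    de_rank = d$de_rank, max_q = d$max_q,
                    min_abs_lfc = d$min_abs_lfc, direction = d$direction,
                    pass_variability = pass_var, pass_de = pass_de,
                    regulator = pass_var & pass_de,
                    combined_rank = pmax(v$var_rank, d$de_rank),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(tf_list)) {
    stopifnot(inherits(tf_list, "gene_set"))
    tab$is_tf <- tab$gene %in% tf_list$genes
  }
  tab <- tab[order(tab$combined_rank, tab$var_rank + tab$de_rank,
                   tab$gene), ]
  rownames(tab) <- NULL
  out <- list(table = tab,
              regulators = tab[tab$regulator, , drop = FALSE],
              var_quantile = var_quantile, alpha = alpha)
  if (!is.null(tf_list))
    out$tf_regulators <- tab[tab$regulator & tab$is_tf, , drop = FALSE]
  class(out) <- "regulator_screen"
  out
}

#' @export
print.regulator_screen <- function(x, ...) {
  cat(sprintf(
    "regulator_screen: %d/%d genes pass both criteria (top %.0f%% variability, alpha %.3g)\n",
    nrow(x$regulators), nrow(x$table), 100 * x$var_quantile, x$alpha))
  if (nrow(x$regulators))
    print(utils::head(x$regulators[, c("gene", "var_rank", "de_rank",
                                       "combined_rank")], 10),
          row.names = FALSE)
  if (!is.null(x$tf_regulators)) {
    cat("transcription factors among regulators: ",
        if (nrow(x$tf_regulators)) paste(x$tf_regulators$gene,
                                         collapse = ", ") else "none",
        "\n", sep = "")
  }
  invisible(x)
}
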