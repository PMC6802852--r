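#' Single-cell bifurcation analysis using variance of gene expression
#'
#' The full pipeline in one call: log-normalize the counts, pick highly
#' variable genes, embed all cells jointly by PCA (keeping the smallest
#' number of components that capture \code{var_threshold} of the total
#' variation), choose the number of clusters at every timepoint with the
#' Gap statistic, partition with K-means, link clusters across consecutive
#' timepoints by centroid correlation into a lineage tree, detect
#' bifurcations, and screen every bifurcation for upstream regulators —
#' genes highly variable in the parent population right before the split
#' and consistently differentially expressed between the branches after
#' it.
#'
#' When marker sets are supplied, cells are first assigned to lineages by
#' \code{\link{assign_lineages}} and the trajectory is reconstructed
#' within one lineage only (by default the most abundant one), mirroring
#' the usual workflow in which contaminating lineages are identified and
#' set aside before trajectory reconstruction.
#'
#' @param counts An \code{\link{expr_matrix}} of raw counts.
#' @param annotation A \code{\link{cell_annotation}} covering every cell.
#' @param markers Optional list of \code{\link{gene_set}}s for lineage
#'   assignment (e.g. TE / EPI / PE marker lists).
#' @param lineage Lineage to reconstruct the trajectory in when
#'   \code{markers} are given; default \code{NULL} means the most abundant
#'   assigned lineage.
#' @param tf_list Optional \code{gene_set} of transcription factors for
#'   the regulator screen.
#' @param scale_factor Library-size target of the log-normalization
#'   (default 10,000).
#' @param n_hvg Number of highly variable genes for the embedding.
#'   Default \code{NULL} means the top decile of genes, capped at 2000
#'   (which reduces to the field-standard 2000 on a whole-transcriptome
#'   matrix); always clamped to the number of genes with positive mean.
#' @param hvg_nbin Mean-expression bins for dispersion standardization
#'   (default 20).
#' @param var_threshold PCA explained-variance threshold (default 0.40).
#' @param kmax,B Gap-statistic search limit and reference count (defaults
#'   6 and 50).
#' @param alpha Adjusted-p cutoff of the DE criterion (default 0.05).
#' @param var_quantile Variability-quantile cutoff of the regulator screen
#'   (default 0.10).
#' @param nbin,nctrl Module-score binning and control-set size (defaults
#'   25, 100).
#' @param seed Seed for every stochastic step (default 1).
#' @return An object of class \code{scbav}: list with \code{norm},
#'   \code{hvg}, \code{embedding}, \code{clustering}, \code{tree},
#'   \code{bifurcations}, \code{screens} (one \code{regulator_screen} per
#'   bifurcation, or per child pair for multifurcations),
#'   \code{lineage_calls} (when markers were given), \code{cells_used},
#'   and \code{config}.
#' @examples
#' \donttest{
#' sim <- simulate_bifurcation(simulation_params(seed = 7))
#' fit <- scbav(sim$counts, sim$annotation, markers = sim$truth$markers,
#'              seed = 7)
#' print(fit)
#' }
#' @export
scbav <- function(counts, annotation, markers = NULL, lineage = NULL,
                  tf_list = NULL, scale_factor = 1e4, n_hvg = NULL,
                  hvg_nbin = 20, var_threshold = 0.40, kmax = 6, B = 50,
                  alpha = 0.05, var_quantile = 0.10, nbin = 25,
                  nctrl = 100, seed = 1) {
  stopifnot(inherits(counts, "expr_matrix"))
  annotation <- align_annotation(counts, annotation)
  config <- list(scale_factor = scale_factor, n_hvg = n_hvg,
                 hvg_nbin = hvg_nbin, var_threshold = var_threshold,
                 kmax = kmax, B = B, alpha = alpha,
                 var_quantile = var_quantile, nbin = nbin, nctrl = nctrl,
                 seed = seed)
  norm_all <- normalize_log(counts, scale_factor)
  lineage_calls <- NULL
  keep <- rownames(counts)
  if (!is.null(markers)) {
    lineage_calls <- assign_lineages(norm_all, markers, nbin = nbin,
                                     nctrl = nctrl, seed = seed)
    if (is.null(lineage))
      lineage <- names(sort(table(lineage_calls$lineage),
                            decreasing = TRUE))[1]
    keep <- lineage_calls$cell_id[lineage_calls$lineage == lineage]
    if (length(keep) < 4)
      stop("fewer than 4 cells assigned to lineage '", lineage, "'")
  }
  norm <- norm_all[keep, , drop = FALSE]
  ann <- annotation[match(keep, annotation$cell_id), , drop = FALSE]
  if (is.null(n_hvg)) n_hvg <- min(2000, ceiling(ncol(norm) / 10))
  config$n_hvg <- n_hvg
  hv <- select_hvg(norm, n_top = min(n_hvg, sum(colMeans(norm) > 0)),
                   nbin = hvg_nbin)
  emb <- embed_pca(norm, hv$genes, var_threshold = var_threshold)
  clust <- cluster_timepoints(emb, ann, kmax = kmax, B = B, seed = seed)
  tree <- build_tree(clust)
  bifs <- detect_bifurcations(tree)
  screens <- list()
  for (bif in bifs) {
    pairs <- utils::combn(bif$children, 2, simplify = FALSE)
    for (pr in pairs) {
      sc <- tryCatch({
        vr <- prebifurcation_variability(norm, tree, bif, nbin = hvg_nbin)
        de <- branch_consistent_de(norm, tree, bif, alpha = alpha,
                                   children = pr)
        screen_regulators(vr, de, tf_list = tf_list,
                          var_quantile = var_quantile, alpha = alpha)
      }, error = function(e) {
        warning("screen of ", bif$parent, " pair ",
                paste(pr, collapse = "|"), " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(sc)) next
      sc$bifurcation <- bif
      sc$children <- pr
      screens[[paste(bif$parent, paste(pr, collapse = "|"),
                     sep = " -> ")]] <- sc
    }
  }
  structure(list(norm = norm, hvg = hv, embedding = emb,
                 clustering = clust, tree = tree, bifurcations = bifs,
                 screens = screens, lineage_calls = lineage_calls,
                 cells_used = keep, lineage = lineage, config = config),
            class = "scbav")
}

#' @export
print.scbav <- function(x, ...) {
  cat("Single-cell bifurcation analysis (scbav)\n")
  cat(sprintf("  cells analysed: %d%s\n", length(x$cells_used),
              if (!is.null(x$lineage))
                paste0(" (lineage ", x$lineage, ")") else ""))
  cat(sprintf("  embedding: %d components (>= %.0f%% of variance)\n",
              x$embedding$n_components, 100 * x$config$var_threshold))
  k_per_tp <- vapply(x$clustering$clusters, `[[`, integer(1), "k")
  cat("  clusters per timepoint: ",
      paste(sprintf("%s=%d", names(k_per_tp), k_per_tp), collapse = ", "),
      "\n", sep = "")
  if (length(x$bifurcations)) {
    for (b in x$bifurcations)
      cat(sprintf("  bifurcation after %s: %s -> %s\n", b$timepoint,
                  b$parent, paste(b$children, collapse = ", ")))
  } else cat("  no bifurcation detected (linear trajectory)\n")
  for (nm in names(x$screens)) {
    sc <- x$screens[[nm]]
    cat(sprintf("  screen %s: %d putative regulator(s)\n", nm,
                nrow(sc$regulators)))
  }
  invisible(x)
}

#' @export
summary.scbav <- function(object, ...) {
  print(object)
  for (nm in names(object$screens)) {
    cat("\nTop of screen ", nm, ":\n", sep = "")
    print(utils::head(object$screens[[nm]]$table[, c(
      "gene", "var_rank", "de_rank", "combined_rank", "regulator")], 10),
      row.names = FALSE)
  }
  invisible(object)
}

#' Plot an scbav trajectory
#'
#' Base-graphics diagnostic: cells in the first two embedding components,
#' colored by timepoint, with cluster centroids and the lineage-tree edges
#' drawn on top.
#'
#' @param x An \code{\link{scbav}} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.scbav <- function(x, ...) {
  co <- x$embedding$coords
  if (ncol(co) < 2) co <- cbind(co, 0)
  cells <- rownames(co)
  tp <- rep(NA_character_, length(cells))
  for (t in x$clustering$timepoints) {
    lb <- x$clustering$clusters[[t]]$labels
    tp[match(names(lb), cells)] <- t
  }
  tps <- x$clustering$timepoints
  cols <- grDevices::hcl.colors(max(3, length(tps)), "Dark 3")
  graphics::plot(co[, 1], co[, 2], col = cols[match(tp, tps)], pch = 16,
                 cex = 0.6, xlab = "PC1", ylab = "PC2",
                 main = "scbav trajectory", ...)
  cents <- do.call(rbind, lapply(tps, function(t) {
    ce <- x$clustering$clusters[[t]]$centers
    data.frame(node = paste0(t, ":", seq_len(nrow(ce))),
               x = ce[, 1], y = if (ncol(ce) > 1) ce[, 2] else 0)
  }))
  for (i in seq_len(nrow(x$tree$edges))) {
    a <- cents[match(x$tree$edges$parent[i], cents$node), ]
    b <- cents[match(x$tree$edges$child[i], cents$node), ]
    graphics::segments(a$x, a$y, b$x, b$y, lwd = 2)
  }
  graphics::points(cents$x, cents$y, pch = 21, bg = "white", cex = 1.6)
  graphics::legend("topright", legend = tps,
                   col = cols[seq_along(tps)], pch = 16, bty = "n")
  invisible(x)
}
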