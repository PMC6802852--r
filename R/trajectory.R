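#' PCA embedding capturing a fixed fraction of total variation
#'
#' Restricts the matrix to the supplied variable genes, centers and
#' unit-scales each gene (clipping scaled values at \code{scale_max}
#' standard deviations, the standard guard against single-cell outliers
#' dominating a component), and runs principal component analysis on all
#' cells from all timepoints jointly. The embedding keeps the smallest
#' number of leading components whose cumulative explained-variance
#' fraction reaches \code{var_threshold} (default 0.40).
#'
#' @param norm An \code{\link{expr_matrix}} with unit \code{lognorm}.
#' @param hvg A \code{\link{gene_set}} of genes to embed (at least 2
#'   present in the matrix). Genes with zero variance are dropped with a
#'   warning before scaling.
#' @param var_threshold Fraction of total variation to capture, in (0, 1).
#' @param scale_max Clip scaled values to [-scale_max, scale_max]
#'   (default 10); \code{Inf} disables clipping.
#' @return An object of class \code{scbav_embedding}: list with
#'   \code{coords} (cells x N score matrix), \code{explained} (variance
#'   fraction of every component), \code{n_components} and
#'   \code{var_threshold}.
#' @export
embed_pca <- function(norm, hvg, var_threshold = 0.40, scale_max = 10) {
  stopifnot(inherits(norm, "expr_matrix"), inherits(hvg, "gene_set"))
  if (expr_unit(norm) != "lognorm")
    stop("embed_pca expects unit 'lognorm'")
  if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold >= 1)
    stop("`var_threshold` must lie in (0, 1)")
  genes <- intersect(hvg$genes, colnames(norm))
  if (length(genes) < length(hvg$genes))
    stop("hvg contains genes absent from the matrix")
  if (length(genes) < 2)
    stop("need at least 2 genes to embed")
  x <- unclass(norm)[, genes, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped before scaling")
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 non-constant genes")
  }
  x <- scale(x)
  x[x > scale_max] <- scale_max
  x[x < -scale_max] <- -scale_max
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  n <- which(cumsum(explained) >= var_threshold)[1]
  structure(list(coords = pc$x[, seq_len(n), drop = FALSE],
                 explained = explained,
                 n_components = n,
                 var_threshold = var_threshold),
            class = "scbav_embedding")
}

#' @export
print.scbav_embedding <- function(x, ...) {
  cat(sprintf(
    "scbav_embedding: %d cells, %d components (%.1f%% of variance, threshold %.0f%%)\n",
    nrow(x$coords), x$n_components,
    100 * sum(x$explained[seq_len(x$n_components)]),
    100 * x$var_threshold))
  invisible(x)
}

# Pooled within-cluster dispersion W_k for a given labeling:
# sum over clusters of within-cluster sum of squared distances to the
# centroid (equals kmeans tot.withinss).
within_dispersion <- function(points, labels) {
  sum(vapply(split(seq_len(nrow(points)), labels), function(ix) {
    p <- points[ix, , drop = FALSE]
    sum(sweep(p, 2, colMeans(p))^2)
  }, numeric(1)))
}

# Seeded k-means with multiple restarts; k = 1 short-circuits to the
# global centroid. Caller is responsible for the RNG state.
kmeans_fit <- function(points, k, nstart = 25, iter_max = 300) {
  if (k == 1) {
    return(list(cluster = rep(1L, nrow(points)),
                centers = matrix(colMeans(points), nrow = 1),
                tot.withinss = within_dispersion(points,
                                                 rep(1L, nrow(points)))))
  }
  k <- min(k, nrow(unique(points)))
  if (k == 1)
    return(kmeans_fit(points, 1))
  if (k >= nrow(points)) {
    # one point per cluster (Hartigan-Wong rejects k = n)
    return(list(cluster = seq_len(nrow(points)), centers = points,
                tot.withinss = 0))
  }
  stats::kmeans(points, centers = k, nstart = nstart, iter.max = iter_max)
}

#' Gap statistic for choosing the number of clusters
#'
#' Tibshirani's gap statistic with reference datasets drawn uniformly over
#' the per-coordinate bounding box of the observed points. For each
#' \code{k} up to \code{kmax}, K-means (25 restarts) gives the pooled
#' within-cluster dispersion \code{W_k};
#' \code{gap(k) = mean_b log W*_kb - log W_k} over \code{B} reference
#' draws, with standard error \code{s_k = sd_b(log W*_kb) sqrt(1 + 1/B)}.
#' The chosen \code{k*} is the smallest \code{k} with
#' \code{gap(k) >= gap(k+1) - s_{k+1}}, falling back to \code{kmax}.
#'
#' @param points Numeric n x d matrix of coordinates (n >= 2).
#' @param kmax Largest k considered (lowered to n with a warning if
#'   needed).
#' @param B Number of reference datasets (default 50).
#' @param seed RNG seed; the computation is deterministic given it.
#' @return An object of class \code{gap_result}: \code{k_star} and a
#'   per-k table with \code{logW}, \code{gap}, \code{s}.
#' @export
gap_statistic <- function(points, kmax = 6, B = 50, seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  if (kmax < 1 || B < 1) stop("kmax and B must be >= 1")
  if (kmax > nrow(points)) {
    warning("kmax lowered to the number of points (", nrow(points), ")")
    kmax <- nrow(points)
  }
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  n <- nrow(points); d <- ncol(points)
  res <- with_seed(seed, {
    # W can hit 0 exactly (k = number of distinct points); clamp before log
    logW <- vapply(seq_len(kmax), function(k)
      log(max(kmeans_fit(points, k)$tot.withinss, 1e-300)), numeric(1))
    logWstar <- matrix(NA_real_, nrow = B, ncol = kmax)
    for (b in seq_len(B)) {
      ref <- matrix(stats::runif(n * d), nrow = n)
      ref <- sweep(sweep(ref, 2, hi - lo, `*`), 2, lo, `+`)
      for (k in seq_len(kmax))
        logWstar[b, k] <- log(max(kmeans_fit(ref, k)$tot.withinss, 1e-300))
    }
    list(logW = logW, logWstar = logWstar)
  })
  gap <- colMeans(res$logWstar) - res$logW
  s <- apply(res$logWstar, 2, stats::sd) * sqrt(1 + 1 / B)
  k_star <- kmax
  if (kmax > 1) {
    ok <- which(gap[-kmax] >= gap[-1] - s[-1])
    if (length(ok)) k_star <- min(ok)
  } else k_star <- 1L
  structure(list(k_star = as.integer(k_star),
                 table = data.frame(k = seq_len(kmax), logW = res$logW,
                                    gap = gap, s = s),
                 kmax = kmax, B = B, seed = seed),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("gap_result: k* = %d (kmax %d, B %d)\n", x$k_star, x$kmax,
              x$B))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Canonical cluster labels: relabel 1..k by lexicographic order of the
# centroid coordinates, so labelings do not depend on k-means
# initialization order.
canonicalize_clusters <- function(labels, centers) {
  ord <- do.call(order, as.data.frame(centers))
  remap <- integer(nrow(centers))
  remap[ord] <- seq_len(nrow(centers))
  list(labels = remap[labels],
       centers = centers[ord, , drop = FALSE])
}

#' Cluster each timepoint with Gap-selected K-means
#'
#' Within the joint embedding, picks the number of clusters at every
#' timepoint with \code{\link{gap_statistic}} and partitions that
#' timepoint's cells with seeded K-means (25 restarts). Timepoints with
#' fewer than 2 cells become a single cluster with a warning. Cluster ids
#' within a timepoint are canonical (ordered by centroid coordinates), so
#' the labeling does not depend on cell order.
#'
#' @param emb An \code{\link{embed_pca}} result covering all cells.
#' @param ann \code{\link{cell_annotation}} for the embedded cells.
#' @param kmax,B,seed Passed to \code{\link{gap_statistic}}; the seed for
#'   timepoint i is \code{seed + i}.
#' @return An object of class \code{timepoint_clustering}: per timepoint a
#'   list with \code{labels} (named integer vector), \code{centers}
#'   (k x N), \code{k}, \code{gap} (the \code{gap_result}).
#' @export
cluster_timepoints <- function(emb, ann, kmax = 6, B = 50, seed = 1) {
  stopifnot(inherits(emb, "scbav_embedding"))
  cells <- rownames(emb$coords)
  idx <- match(cells, ann$cell_id)
  if (anyNA(idx)) stop("embedded cell(s) missing from annotation")
  tp <- ann$timepoint[idx]
  tps <- levels(tp)[table(tp) > 0]
  out <- vector("list", length(tps))
  names(out) <- tps
  for (i in seq_along(tps)) {
    sel <- which(tp == tps[i])
    pts <- emb$coords[sel, , drop = FALSE]
    if (length(sel) < 2) {
      warning("timepoint ", tps[i], " has fewer than 2 cells; one cluster")
      out[[i]] <- list(labels = stats::setNames(rep(1L, length(sel)),
                                                cells[sel]),
                       centers = matrix(colMeans(pts), nrow = 1),
                       k = 1L, gap = NULL)
      next
    }
    gp <- gap_statistic(pts, kmax = min(kmax, length(sel)), B = B,
                        seed = seed + i)
    km <- with_seed(seed + i, kmeans_fit(pts, gp$k_star))
    cc <- canonicalize_clusters(km$cluster, km$centers)
    out[[i]] <- list(labels = stats::setNames(as.integer(cc$labels),
                                              cells[sel]),
                     centers = cc$centers, k = gp$k_star, gap = gp)
  }
  structure(list(timepoints = tps, clusters = out,
                 n_components = emb$n_components),
            class = "timepoint_clustering")
}

#' Link clusters across timepoints into a lineage tree
#'
#' Every cluster at timepoint t+1 is attached to the cluster at timepoint
#' t whose centroid is the most similar to its own, iterating over
#' consecutive timepoints until every cluster belongs to the lineage
#' forest. Similarity is the Pearson correlation of centroid coordinate
#' vectors; with an embedding of 2 or fewer components a correlation is
#' unstable, so similarity falls back to negative Euclidean distance (and
#' does so per-pair when a centroid is constant across components).
#' Correlation ties attach the child to the lowest-id parent, with a
#' message.
#'
#' @param clust A \code{\link{cluster_timepoints}} result with at least 2
#'   timepoints.
#' @return An object of class \code{lineage_tree}: \code{nodes} (data
#'   frame: node_id, timepoint, cluster, n_cells), \code{cells} (named
#'   list of member cell ids per node), \code{edges} (data frame: parent,
#'   child, similarity, method).
#' @export
build_tree <- function(clust) {
  stopifnot(inherits(clust, "timepoint_clustering"))
  tps <- clust$timepoints
  if (length(tps) < 2) stop("need at least 2 clustered timepoints")
  node_id <- function(tp, k) paste0(tp, ":", k)
  nodes <- do.call(rbind, lapply(tps, function(tp) {
    cl <- clust$clusters[[tp]]
    data.frame(node_id = node_id(tp, seq_len(cl$k)), timepoint = tp,
               cluster = seq_len(cl$k),
               n_cells = as.integer(table(factor(cl$labels,
                                                 levels = seq_len(cl$k)))),
               stringsAsFactors = FALSE)
  }))
  cells <- list()
  for (tp in tps) {
    cl <- clust$clusters[[tp]]
    for (k in seq_len(cl$k))
      cells[[node_id(tp, k)]] <- names(cl$labels)[cl$labels == k]
  }
  use_distance_global <- clust$n_components <= 2
  if (use_distance_global)
    warning("embedding has <= 2 components; ",
            "linking by negative Euclidean distance instead of correlation")
  edges <- NULL
  for (i in seq_len(length(tps) - 1)) {
    par_c <- clust$clusters[[tps[i]]]$centers
    chi_c <- clust$clusters[[tps[i + 1]]]$centers
    for (ch in seq_len(nrow(chi_c))) {
      sims <- numeric(nrow(par_c))
      meth <- character(nrow(par_c))
      for (pa in seq_len(nrow(par_c))) {
        a <- par_c[pa, ]; b <- chi_c[ch, ]
        if (use_distance_global || stats::sd(a) == 0 || stats::sd(b) == 0) {
          if (!use_distance_global)
            warning("constant centroid; using negative distance for one pair")
          sims[pa] <- -sqrt(sum((a - b)^2))
          meth[pa] <- "neg_distance"
        } else {
          sims[pa] <- stats::cor(a, b)
          meth[pa] <- "pearson"
        }
      }
      best <- which(sims == max(sims))
      if (length(best) > 1)
        message("linking tie at ", tps[i + 1], ":", ch,
                "; attaching to lowest-id parent")
      best <- min(best)
      edges <- rbind(edges, data.frame(
        parent = node_id(tps[i], best), child = node_id(tps[i + 1], ch),
        similarity = sims[best], method = meth[best],
        stringsAsFactors = FALSE))
    }
  }
  structure(list(nodes = nodes, cells = cells, edges = edges,
                 timepoints = tps),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d nodes over %d timepoints, %d edges\n",
              nrow(x$nodes), length(x$timepoints), nrow(x$edges)))
  k_per_tp <- table(factor(x$nodes$timepoint, levels = x$timepoints))
  cat("clusters per timepoint: ",
      paste(sprintf("%s=%d", names(k_per_tp), k_per_tp), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# All descendant node ids of `node` (inclusive).
tree_descendants <- function(tree, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    nxt <- tree$edges$child[tree$edges$parent %in% frontier]
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Detect bifurcation events in a lineage tree
#'
#' A bifurcation is a node with two or more children; it marks a cell-fate
#' segregation event right after the parent's timepoint. A node with three
#' children is one event with three children, not three events.
#'
#' @param tree A \code{\link{build_tree}} result.
#' @return A list of \code{bifurcation_event} objects (possibly empty),
#'   ordered by timepoint; each has \code{parent}, \code{children} and
#'   \code{timepoint} (the parent's).
#' @export
detect_bifurcations <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  kids <- split(tree$edges$child, tree$edges$parent)
  parents <- names(kids)[lengths(kids) >= 2]
  if (!length(parents)) return(list())
  tp_of <- stats::setNames(tree$nodes$timepoint, tree$nodes$node_id)
  ord <- order(match(tp_of[parents], tree$timepoints), parents)
  lapply(parents[ord], function(p)
    structure(list(parent = p, children = sort(kids[[p]]),
                   timepoint = tp_of[[p]]),
              class = "bifurcation_event"))
}

#' @export
print.bifurcation_event <- function(x, ...) {
  cat(sprintf("bifurcation at %s: %s -> %s\n", x$timepoint, x$parent,
              paste(x$children, collapse = ", ")))
  invisible(x)
}
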