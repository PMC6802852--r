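test_that("embedding keeps the minimal component count for the variance threshold", {
  # rank-1 data: cells on a line in gene space -> N = 1
  t_pos <- seq(-2, 2, length.out = 30)
  load <- runif(8, 0.5, 2)
  v <- outer(t_pos, load)
  dimnames(v) <- list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:8))
  emb <- embed_pca(expr_matrix(v, "lognorm"),
                   gene_set("all", colnames(v)), 0.4)
  expect_equal(emb$n_components, 1)
  expect_gte(emb$explained[1], 0.999)

  # isotropic noise: N agrees with the cumulative eigenvalue oracle
  for (s in 1:10) {
    norm <- random_lognorm(40, 10, seed = 60 + s)
    emb <- embed_pca(norm, gene_set("all", colnames(norm)), 0.4,
                     scale_max = Inf)
    ev <- eigen(stats::cov(scale(unclass(norm))),
                symmetric = TRUE)$values
    frac <- cumsum(ev) / sum(ev)
    expect_equal(emb$n_components, which(frac >= 0.4)[1])
    # minimality: one fewer component falls below the threshold
    if (emb$n_components > 1)
      expect_lt(sum(emb$explained[seq_len(emb$n_components - 1)]), 0.4)
  }

  # near-1 threshold on full-rank data -> all informative components
  norm <- random_lognorm(20, 50, seed = 71)
  emb <- embed_pca(norm, gene_set("all", colnames(norm)), 0.999999)
  expect_equal(emb$n_components, 19)   # cells - 1 (centered rank)

  expect_error(embed_pca(norm, gene_set("one", colnames(norm)[1]), 0.4),
               "2 genes")
  expect_error(embed_pca(norm, gene_set("all", colnames(norm)), 1.2),
               "var_threshold")
})

test_that("gap statistic picks one cluster for a blob and survives degenerate input", {
  pts <- scbav:::with_seed(80, matrix(rnorm(120), ncol = 2))
  g <- gap_statistic(pts, kmax = 5, B = 20, seed = 1)
  expect_equal(g$k_star, 1L)
  expect_equal(nrow(g$table), 5)
  expect_true(all(is.finite(g$table$gap)) && all(is.finite(g$table$s)))

  # n = 2 distinct points, kmax clamped with a warning; no crash
  two <- matrix(c(0, 0, 5, 5), nrow = 2, byrow = TRUE)
  expect_warning(g2 <- gap_statistic(two, kmax = 4, B = 5, seed = 1),
                 "lowered")
  expect_true(g2$k_star %in% 1:2)
  expect_true(all(is.finite(g2$table$gap)))

  expect_error(gap_statistic(matrix(1, 1, 2), 2, 5, 1), "2 points")
})

test_that("gap statistic agrees with the reference implementation's squared-distance mode", {
  skip_if_not_installed("cluster")
  pts <- scbav:::with_seed(81, rbind(matrix(rnorm(100), ncol = 2),
                                     matrix(rnorm(100, 8), ncol = 2)))
  mine <- gap_statistic(pts, kmax = 4, B = 50, seed = 3)
  set.seed(3)
  ref <- cluster::clusGap(pts, FUN = function(x, k)
    stats::kmeans(x, k, nstart = 25, iter.max = 300),
    K.max = 4, B = 50, d.power = 2, spaceH0 = "original",
    verbose = FALSE)
  k_ref <- cluster::maxSE(ref$Tab[, "gap"], ref$Tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  expect_equal(mine$k_star, as.integer(k_ref))
  # clusGap's W is half the k-means within-SS, so logW differs by ln 2
  expect_equal(mine$table$logW, unname(ref$Tab[, "logW"]) + log(2),
               tolerance = 1e-8)
})

test_that("per-timepoint clustering is canonical and order-invariant", {
  # two timepoints: a blob, then two separated blobs
  set.seed(90)
  pts_t1 <- matrix(rnorm(80), ncol = 2)
  pts_t2 <- rbind(matrix(rnorm(40), ncol = 2),
                  matrix(rnorm(40, mean = 12), ncol = 2))
  coords <- rbind(pts_t1, pts_t2)
  rownames(coords) <- sprintf("c%03d", 1:80)
  emb <- structure(list(coords = coords, explained = c(0.5, 0.5),
                        n_components = 2, var_threshold = 0.4),
                   class = "scbav_embedding")
  ann <- cell_annotation(data.frame(
    cell_id = rownames(coords),
    timepoint = rep(c("t1", "t2"), each = 40)), c("t1", "t2"))
  cl <- cluster_timepoints(emb, ann, kmax = 4, B = 20, seed = 7)
  expect_equal(cl$clusters[["t1"]]$k, 1L)
  expect_equal(cl$clusters[["t2"]]$k, 2L)
  expect_equal(unname(cl$clusters[["t1"]]$centers[1, ]),
               unname(colMeans(pts_t1)))

  # permuted cell order: identical partition after canonical relabeling
  perm <- sample(nrow(coords))
  emb2 <- emb; emb2$coords <- coords[perm, ]
  cl2 <- cluster_timepoints(emb2, ann, kmax = 4, B = 20, seed = 7)
  for (tp in c("t1", "t2")) {
    l1 <- cl$clusters[[tp]]$labels
    l2 <- cl2$clusters[[tp]]$labels
    expect_equal(l1[names(l2)], l2)
  }
})

test_that("tree linking attaches children to the most correlated parent", {
  mk_clust <- function(centers_by_tp, cells_by_tp) {
    tps <- names(centers_by_tp)
    clusters <- lapply(tps, function(tp) {
      ce <- centers_by_tp[[tp]]
      labs <- rep(seq_len(nrow(ce)), lengths(cells_by_tp[[tp]]))
      names(labs) <- unlist(cells_by_tp[[tp]])
      list(labels = labs, centers = ce, k = nrow(ce), gap = NULL)
    })
    names(clusters) <- tps
    structure(list(timepoints = tps, clusters = clusters,
                   n_components = ncol(centers_by_tp[[1]])),
              class = "timepoint_clustering")
  }

  # identical clusterings -> identity linking with correlation 1
  ce <- rbind(c(1, 2, 3), c(3, 1, 0))
  cl <- mk_clust(list(t1 = ce, t2 = ce),
                 list(t1 = list(c("a", "b"), c("c")),
                      t2 = list(c("d"), c("e", "f"))))
  tree <- build_tree(cl)
  expect_equal(tree$edges$parent, c("t1:1", "t1:2"))
  expect_equal(tree$edges$child, c("t2:1", "t2:2"))
  expect_equal(tree$edges$similarity, c(1, 1))

  # hand-computed 3-component toy: both children correlate best with
  # the single parent (r = 0.9966 and 0.9819), so both attach to it
  par_c <- matrix(c(0, 1, 2), nrow = 1)
  kid_c <- rbind(c(0, 1.2, 2.1), c(0.4, 1, 2.2))
  r1 <- cor(par_c[1, ], kid_c[1, ]); r2 <- cor(par_c[1, ], kid_c[2, ])
  cl2 <- mk_clust(list(t1 = par_c, t2 = kid_c),
                  list(t1 = list(c("a", "b")),
                       t2 = list(c("c"), c("d"))))
  tree2 <- build_tree(cl2)
  expect_equal(tree2$edges$parent, c("t1:1", "t1:1"))
  expect_equal(tree2$edges$similarity, c(r1, r2))

  # correlation tie -> lowest-id parent, with a message
  tie_par <- rbind(c(0, 1, 2), c(0, 2, 4))     # collinear: both r = 1
  cl3 <- mk_clust(list(t1 = tie_par, t2 = matrix(c(0, 3, 6), nrow = 1)),
                  list(t1 = list("a", "b"), t2 = list("c")))
  expect_message(tree3 <- build_tree(cl3), "tie")
  expect_equal(tree3$edges$parent, "t1:1")

  # cell partition preserved per timepoint
  cells_t2 <- unlist(tree$cells[c("t2:1", "t2:2")])
  expect_setequal(cells_t2, c("d", "e", "f"))
})

test_that("bifurcation detection finds multi-child nodes only", {
  path_edges <- data.frame(parent = c("t1:1", "t2:1"),
                           child = c("t2:1", "t3:1"),
                           similarity = 1, method = "pearson")
  mk_tree <- function(edges, tps) {
    ids <- unique(c(edges$parent, edges$child))
    tpv <- sub(":.*", "", ids)
    structure(list(
      nodes = data.frame(node_id = ids, timepoint = tpv,
                         cluster = as.integer(sub(".*:", "", ids)),
                         n_cells = 1L),
      cells = stats::setNames(as.list(ids), ids),
      edges = edges, timepoints = tps), class = "lineage_tree")
  }
  expect_length(detect_bifurcations(mk_tree(path_edges,
                                            c("t1", "t2", "t3"))), 0)

  tri <- data.frame(parent = "t1:1", child = c("t2:1", "t2:2", "t2:3"),
                    similarity = 1, method = "pearson")
  ev <- detect_bifurcations(mk_tree(tri, c("t1", "t2")))
  expect_length(ev, 1)
  expect_length(ev[[1]]$children, 3)
  expect_equal(ev[[1]]$timepoint, "t1")
})
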