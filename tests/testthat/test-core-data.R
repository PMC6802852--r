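test_that("expression containers validate ids, units and values", {
  m <- matrix(1:12, nrow = 3,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  em <- expr_matrix(m, "counts")
  expect_s3_class(em, "expr_matrix")
  expect_equal(expr_unit(em), "counts")
  expect_equal(dim(em[1:2, 1:2]), c(2L, 2L))

  expect_error(expr_matrix(unname(m), "counts"), "ids")
  m2 <- m; rownames(m2) <- c("c1", "c1", "c3")
  expect_error(expr_matrix(m2, "counts"), "duplicate cell ids")
  m3 <- m; m3[1, 1] <- -1
  expect_error(expr_matrix(m3, "counts"), "negative")
  m4 <- m; m4[1, 1] <- NA
  expect_error(expr_matrix(m4, "counts"), "finite")

  ann <- cell_annotation(data.frame(cell_id = paste0("c", 1:3),
                                    timepoint = c("d7", "d6", "d6")),
                         timepoint_levels = c("d6", "d7"))
  expect_true(is.ordered(ann$timepoint))
  expect_error(cell_annotation(data.frame(cell_id = c("a", "a"),
                                          timepoint = "d6")),
               "duplicate")
  expect_error(gene_set("x", character(0)), "empty")
})

test_that("tsv and mtx readers round-trip and reject corrupt inputs", {
  m <- matrix(rpois(12, 5), nrow = 3,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(cell_id = rownames(m), m, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  em <- read_expression(tsv, "tsv", "counts")
  expect_equal(unclass(em), m, ignore_attr = TRUE)
  expect_equal(rownames(em), rownames(m))
  expect_equal(colnames(em), colnames(m))

  # full generator round-trip through MatrixMarket
  sim <- tiny_sim(seed = 3)
  dir <- tempfile()
  write_dataset(sim, dir)
  back <- read_expression(dir, "mtx", "counts")
  expect_identical(unclass(back), unclass(sim$counts))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$cell_id, sim$annotation$cell_id)

  # corrupt sidecars
  writeLines(rep("gene0001", ncol(sim$counts)),
             file.path(dir, "genes.txt"))
  expect_error(read_expression(dir, "mtx"), "duplicate gene ids")
  writeLines(paste0("g", 1:3), file.path(dir, "genes.txt"))
  expect_error(read_expression(dir, "mtx"), "sidecars")
  writeLines("not a matrix market file", file.path(dir, "matrix.mtx"))
  expect_error(read_expression(dir, "mtx"), "malformed|readMM|scan")
})

test_that("log-normalization matches hand arithmetic and its algebraic identity", {
  m <- matrix(c(10, 0, 90), nrow = 1,
              dimnames = list("c1", paste0("g", 1:3)))
  norm <- normalize_log(expr_matrix(m, "counts"), scale_factor = 100)
  expect_equal(as.numeric(norm), c(log(11), 0, log(91)))
  expect_equal(expr_unit(norm), "lognorm")

  zz <- matrix(c(1, 0, 2, 0), nrow = 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  zz["b", ] <- 0
  expect_error(normalize_log(expr_matrix(zz, "counts")), "b")

  # per-cell exp-sum identity: sum_g (e^v - 1) = scale_factor
  set.seed(42)
  cm <- matrix(rpois(20 * 50, 3), nrow = 20,
               dimnames = list(sprintf("c%02d", 1:20),
                               sprintf("g%02d", 1:50)))
  cm[cm == 0][1] <- 1          # guard against a zero-total cell
  n2 <- normalize_log(expr_matrix(cm, "counts"), scale_factor = 1e4)
  expect_equal(rowSums(expm1(unclass(n2))), rep(1e4, 20),
               tolerance = 1e-9, ignore_attr = TRUE)

  # duplicating a cell's counts yields an identical normalized row
  cm2 <- rbind(cm, dup = cm[1, ])
  n3 <- normalize_log(expr_matrix(cm2, "counts"))
  expect_equal(unname(unclass(n3)["dup", ]), unname(unclass(n3)[1, ]))
})

test_that("highly variable gene selection ranks dispersion and recovers planted genes", {
  # dominance: one gene with 10x the variance at equal mean
  set.seed(1)
  base <- matrix(rnorm(100 * 10, mean = 5, sd = 1), 100)
  base[, 9] <- rnorm(100, mean = 5, sd = sqrt(10))
  base <- abs(base)
  dimnames(base) <- list(sprintf("c%03d", 1:100), sprintf("g%02d", 1:10))
  hv <- select_hvg(expr_matrix(base, "lognorm"), n_top = 1, nbin = 2)
  expect_equal(hv$genes$genes, "g09")

  # constant gene: dispersion 0, never selected before non-constant genes
  cst <- base; cst[, 3] <- 2
  hv2 <- select_hvg(expr_matrix(cst, "lognorm"), n_top = 9, nbin = 2)
  expect_false("g03" %in% hv2$genes$genes)

  # z is standardized within bins
  tab <- hv2$table
  for (b in unique(tab$bin)) {
    zb <- tab$z[tab$bin == b]
    if (length(zb) > 1 && sd(zb) > 0) {
      expect_equal(mean(zb), 0, tolerance = 1e-12)
      expect_equal(sd(zb), 1, tolerance = 1e-12)
    }
  }

  expect_error(select_hvg(expr_matrix(base, "lognorm"), n_top = 2,
                          nbin = 100), "nbin")

  # recovery of 50 planted high-dispersion genes among 500, 10 seeds;
  # gene means are spread so abundance carries no information about
  # which genes were planted
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    mu <- runif(500, 1, 6)
    mu[1:50] <- seq(1.05, 5.95, length.out = 50)  # 2-3 planted per bin
    v <- sapply(mu, function(m) rnorm(60, mean = m, sd = 0.4))
    v[, 1:50] <- sapply(mu[1:50], function(m) rnorm(60, mean = m,
                                                    sd = 2))
    v <- abs(v)
    dimnames(v) <- list(sprintf("c%02d", 1:60), sprintf("g%03d", 1:500))
    hv <- select_hvg(expr_matrix(v, "lognorm"), n_top = 50, nbin = 20)
    sum(hv$genes$genes %in% sprintf("g%03d", 1:50))
  })
  expect_true(all(hits >= 45))

  # order invariance: permuting gene columns gives the same set
  v <- random_lognorm(50, 80, seed = 7)
  perm <- sample(ncol(v))
  s1 <- select_hvg(v, n_top = 10, nbin = 5)$genes$genes
  s2 <- select_hvg(v[, perm], n_top = 10, nbin = 5)$genes$genes
  expect_setequal(s1, s2)
})

test_that("maintained-marker filter requires the threshold at every timepoint", {
  # 5 timepoints x 4 cells, 6 candidates built so exactly 2 pass
  day_means <- rbind(
    keep1 = c(12, 15, 11, 20, 13),
    drop1 = c(12, 9.9, 11, 20, 13),   # fails a single day
    keep2 = c(50, 40, 30, 20, 10),
    drop2 = c(9, 9, 9, 9, 9),
    drop3 = c(100, 100, 100, 100, 5),
    drop4 = c(0, 0, 0, 0, 0))
  cells_per_day <- 4
  days <- paste0("d", 6:10)
  # assemble cells x genes: rows are day-blocks of cells
  vals <- do.call(rbind, lapply(seq_along(days), function(i)
    matrix(rep(day_means[, i], each = cells_per_day), nrow = cells_per_day,
           dimnames = list(NULL, rownames(day_means)))))
  rownames(vals) <- sprintf("c%02d", seq_len(nrow(vals)))
  expr <- expr_matrix(vals, "fpkm")
  ann <- cell_annotation(data.frame(
    cell_id = rownames(vals),
    timepoint = rep(days, each = cells_per_day)), days)
  cand <- gene_set("TE_markers",
                   c(rownames(day_means), "absent_gene"))
  expect_message(
    kept <- maintained_markers(expr, ann, cand, threshold = 10),
    "absent")
  expect_setequal(kept$genes, c("keep1", "keep2"))
  expect_equal(attr(kept, "skipped"), "absent_gene")

  # monotone in threshold: raising it never adds a gene
  for (thr in c(5, 10, 15, 25, 60)) {
    lo <- maintained_markers(expr, ann, cand, threshold = thr)$genes
    hi <- maintained_markers(expr, ann, cand, threshold = thr + 5)$genes
    expect_true(all(hi %in% lo))
  }
})
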