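#' Parameters for the bifurcation simulator
#'
#' Defines the planted structure of a simulated time-series scRNA-seq
#' experiment: one lineage (TE) that splits into two branches after a
#' known timepoint, branch-specific differentially expressed genes, one
#' upstream-regulator gene that is bimodal in the parent population at the
#' timepoint right before the split and branch-differential afterwards,
#' and per-lineage marker genes for TE / EPI / PE, with a small EPI and PE
#' contingent present at every timepoint (as in a dissociated conceptus,
#' where most—but not all—cells are trophoblast).
#'
#' @param n_timepoints Number of collection timepoints (default 4, labeled
#'   t1..t4).
#' @param cells_per_timepoint Cells collected per timepoint (default 100).
#' @param n_genes Genes simulated (default 2000).
#' @param bifurcation_after Timepoint index after which the TE lineage
#'   splits (default 2: branches exist from t3 on).
#' @param n_branch_de Branch-differential genes (default 200, half up in
#'   each branch) with log2 effect \code{branch_de_lfc} (default 1.5).
#' @param branch_de_lfc Log2 fold change of the branch-DE genes.
#' @param regulator_bimodal_fraction Fraction of parent cells in the high
#'   regulator mode at the bifurcation timepoint (default 0.5).
#' @param regulator_bimodal_gap Log2 gap between the high and low
#'   regulator modes before the split (default 2).
#' @param regulator_branch_lfc Log2 shift of the regulator in each branch
#'   after the split (+ in branch A, - in branch B; default 2).
#' @param n_marker_genes Markers per lineage (default 50) with log2 effect
#'   \code{marker_lfc} (default 2) in their own lineage's cells.
#' @param marker_lfc Log2 marker elevation.
#' @param lineage_proportions Named fractions of TE / EPI / PE cells at
#'   every timepoint (default 0.8 / 0.1 / 0.1).
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters
#'   (default meanlog = ln 5000, sdlog = 0.3).
#' @param gene_mean_shape,gene_mean_scale Gamma parameters of the baseline
#'   gene means (default shape 0.6, scale 2).
#' @param nb_dispersion Negative-binomial dispersion (default 0.2, i.e.
#'   size = 5).
#' @param seed RNG seed; the simulation is fully deterministic given it.
#' @return A validated list of class \code{simulation_params}.
#' @export
simulation_params <- function(n_timepoints = 4, cells_per_timepoint = 100,
                              n_genes = 2000, bifurcation_after = 2,
                              n_branch_de = 200, branch_de_lfc = 1.5,
                              regulator_bimodal_fraction = 0.5,
                              regulator_bimodal_gap = 2.0,
                              regulator_branch_lfc = 2.0,
                              n_marker_genes = 50, marker_lfc = 2.0,
                              lineage_proportions = c(TE = 0.8, EPI = 0.1,
                                                      PE = 0.1),
                              lib_meanlog = log(5000), lib_sdlog = 0.3,
                              gene_mean_shape = 0.6, gene_mean_scale = 2,
                              nb_dispersion = 0.2, seed = 1) {
  p <- as.list(environment())
  if (p$bifurcation_after >= p$n_timepoints)
    stop("bifurcation_after must be smaller than n_timepoints")
  n_special <- p$n_branch_de + 3 * p$n_marker_genes + 1
  if (n_special > p$n_genes)
    stop("gene budget infeasible: ", n_special, " special genes but only ",
         p$n_genes, " genes")
  if (abs(sum(p$lineage_proportions) - 1) > 1e-8 ||
      is.null(names(p$lineage_proportions)))
    stop("lineage_proportions must be named and sum to 1")
  structure(p, class = "simulation_params")
}

#' Preset simulator configurations
#'
#' \code{"default"} is the full planted structure; \code{"null"} zeroes
#' every planted effect (branch DE, regulator, markers) while keeping the
#' nominal branch and lineage labels in the truth, so false-positive rates
#' can be calibrated; \code{"three-cluster"} uses equal TE/EPI/PE
#' proportions and no branch structure, so each timepoint carries three
#' marker-separated subpopulations.
#'
#' @param preset One of \code{"default"}, \code{"null"},
#'   \code{"three-cluster"}.
#' @param ... Overrides passed on to \code{\link{simulation_params}}.
#' @return A \code{simulation_params} object.
#' @export
simulation_preset <- function(preset = c("default", "null",
                                         "three-cluster"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "default" = list(),
    "null" = list(branch_de_lfc = 0, regulator_bimodal_gap = 0,
                  regulator_branch_lfc = 0, marker_lfc = 0),
    "three-cluster" = list(lineage_proportions = c(TE = 1 / 3, EPI = 1 / 3,
                                                   PE = 1 / 3),
                           branch_de_lfc = 0, regulator_bimodal_gap = 0,
                           regulator_branch_lfc = 0))
  do.call(simulation_params, utils::modifyList(base, list(...)))
}

#' Simulate a bifurcating single-cell time course
#'
#' Draws negative-binomial counts with gamma-distributed baseline gene
#' means and log-normal cell library sizes. TE cells share one mean
#' profile before the split and divide 50/50 into two branches afterwards;
#' branch-DE genes shift by \code{2^branch_de_lfc} in their branch. The
#' regulator gene is a two-component mixture among TE cells at the
#' bifurcation timepoint (high/low modes \code{2^(+/- gap/2)}); after the
#' split the bimodality resolves into the branches, each branch shifting
#' by \code{2^(+/- regulator_branch_lfc)} from baseline. Marker genes are elevated in their own
#' lineage's cells at every timepoint. Marker and regulator genes receive
#' baseline means from the upper half of the gene-mean distribution
#' (markers are, by construction, detectable genes).
#'
#' @param params A \code{\link{simulation_params}} object.
#' @return A list of class \code{scbav_simulation} with elements
#'   \code{counts} (an \code{\link{expr_matrix}} of counts),
#'   \code{annotation} (a \code{\link{cell_annotation}}) and \code{truth}
#'   (list: per-cell \code{cells} table with lineage and branch,
#'   \code{regulator}, \code{branch_de} table of gene/direction,
#'   \code{markers} list of \code{\link{gene_set}}s,
#'   \code{bifurcation_timepoint}, \code{params}).
#' @export
simulate_bifurcation <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  tps <- paste0("t", seq_len(p$n_timepoints))
  genes <- sprintf("gene%04d", seq_len(p$n_genes))
  with_seed(p$seed, {
    base_mean <- stats::rgamma(p$n_genes, shape = p$gene_mean_shape,
                               scale = p$gene_mean_scale)
    base_mean <- pmax(base_mean, 1e-3)
    names(base_mean) <- genes
    special <- sample(genes, 1 + p$n_branch_de + 3 * p$n_marker_genes)
    regulator <- special[1]
    de_genes <- special[1 + seq_len(p$n_branch_de)]
    de_up_a <- de_genes[seq_len(floor(p$n_branch_de / 2))]
    de_up_b <- setdiff(de_genes, de_up_a)
    mk <- split(special[-seq_len(1 + p$n_branch_de)],
                rep(c("TE", "EPI", "PE"), each = p$n_marker_genes))
    # detectable baselines: markers from the upper half of the mean
    # distribution, branch-DE genes from its top 30% (a planted fold
    # change on a near-zero-mean gene would not be observable in the
    # counts), the regulator a robustly expressed gene (90th percentile),
    # as a screenable transcription factor would be
    upper_pool <- base_mean[base_mean >= stats::median(base_mean)]
    de_pool <- base_mean[base_mean >= stats::quantile(base_mean, 0.7)]
    for (gn in unlist(mk))
      base_mean[gn] <- sample(upper_pool, 1)
    base_mean[de_genes] <- sample(de_pool, length(de_genes),
                                  replace = TRUE)
    base_mean[regulator] <- stats::quantile(base_mean, 0.95)

    n <- p$n_timepoints * p$cells_per_timepoint
    lin_n <- round(p$lineage_proportions * p$cells_per_timepoint)
    lin_n[1] <- p$cells_per_timepoint - sum(lin_n[-1])
    cells <- data.frame(
      cell_id = sprintf("cell%04d", seq_len(n)),
      timepoint = rep(tps, each = p$cells_per_timepoint),
      lineage = rep(rep(names(lin_n), lin_n), p$n_timepoints),
      branch = "none", stringsAsFactors = FALSE)
    post <- cells$timepoint %in% tps[-seq_len(p$bifurcation_after)] &
      cells$lineage == "TE"
    cells$branch[post] <- rep_len(c("A", "B"), sum(post))
    at_bif <- cells$timepoint == tps[p$bifurcation_after] &
      cells$lineage == "TE"
    reg_mode <- rep("none", n)
    reg_mode[at_bif] <-
      ifelse(seq_len(sum(at_bif)) <=
               round(p$regulator_bimodal_fraction * sum(at_bif)),
             "high", "low")

    libsize <- stats::rlnorm(n, p$lib_meanlog, p$lib_sdlog)
    counts <- matrix(0L, nrow = n, ncol = p$n_genes,
                     dimnames = list(cells$cell_id, genes))
    size <- 1 / p$nb_dispersion
    for (i in seq_len(n)) {
      m <- base_mean
      m[mk[[cells$lineage[i]]]] <- m[mk[[cells$lineage[i]]]] *
        2^p$marker_lfc
      if (cells$branch[i] == "A") {
        m[de_up_a] <- m[de_up_a] * 2^p$branch_de_lfc
        m[regulator] <- m[regulator] * 2^p$regulator_branch_lfc
      } else if (cells$branch[i] == "B") {
        m[de_up_b] <- m[de_up_b] * 2^p$branch_de_lfc
        m[regulator] <- m[regulator] * 2^(-p$regulator_branch_lfc)
      }
      if (reg_mode[i] == "high")
        m[regulator] <- m[regulator] * 2^(p$regulator_bimodal_gap / 2)
      else if (reg_mode[i] == "low")
        m[regulator] <- m[regulator] * 2^(-p$regulator_bimodal_gap / 2)
      mu <- libsize[i] * m / sum(m)
      counts[i, ] <- stats::rnbinom(p$n_genes, mu = mu, size = size)
    }
    truth <- list(
      cells = cells,
      regulator = regulator,
      branch_de = data.frame(gene = c(de_up_a, de_up_b),
                             direction = rep(c("A>B", "B>A"),
                                             c(length(de_up_a),
                                               length(de_up_b))),
                             stringsAsFactors = FALSE),
      markers = lapply(stats::setNames(nm = names(mk)), function(l)
        gene_set(l, mk[[l]])),
      bifurcation_timepoint = tps[p$bifurcation_after],
      library_sizes = stats::setNames(libsize, cells$cell_id),
      params = unclass(p))
    ann <- cell_annotation(
      data.frame(cell_id = cells$cell_id, timepoint = cells$timepoint,
                 condition = "simulated", lineage = cells$lineage,
                 stringsAsFactors = FALSE),
      timepoint_levels = tps)
    structure(list(counts = expr_matrix(counts, "counts"),
                   annotation = ann, truth = truth),
              class = "scbav_simulation")
  })
}

#' @export
print.scbav_simulation <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "scbav_simulation: %d cells x %d genes, %d timepoints, split after %s\n",
    nrow(x$counts), ncol(x$counts), p$n_timepoints,
    x$truth$bifurcation_timepoint))
  invisible(x)
}

#' Lineage tree of the planted truth
#'
#' Builds the \code{\link{build_tree}}-style lineage tree that the planted
#' structure of a simulation implies: one trophoblast (TE) node per
#' timepoint up to the bifurcation, then one node per branch. Useful for
#' calibrating the regulator screen against a known partition — in
#' particular on the null preset, where the trajectory correctly finds no
#' bifurcation, yet the screen's false-positive behaviour under the
#' truth-assigned (zero-effect) split is the quantity of interest.
#'
#' @param sim A \code{\link{simulate_bifurcation}} result.
#' @return A \code{lineage_tree} over the simulation's TE cells.
#' @export
truth_tree <- function(sim) {
  stopifnot(inherits(sim, "scbav_simulation"))
  tr <- sim$truth$cells
  tps <- levels(sim$annotation$timepoint)
  bif_at <- match(sim$truth$bifurcation_timepoint, tps)
  te <- tr[tr$lineage == "TE", ]
  nodes <- NULL; cells <- list(); edges <- NULL
  for (i in seq_along(tps)) {
    tp <- tps[i]
    if (i <= bif_at) {
      id <- paste0(tp, ":1")
      cells[[id]] <- te$cell_id[te$timepoint == tp]
      nodes <- rbind(nodes, data.frame(node_id = id, timepoint = tp,
                                       cluster = 1L,
                                       n_cells = length(cells[[id]]),
                                       stringsAsFactors = FALSE))
      if (i > 1)
        edges <- rbind(edges, data.frame(
          parent = paste0(tps[i - 1], ":1"), child = id, similarity = 1,
          method = "truth", stringsAsFactors = FALSE))
    } else {
      for (k in 1:2) {
        id <- paste0(tp, ":", k)
        br <- c("A", "B")[k]
        cells[[id]] <- te$cell_id[te$timepoint == tp & te$branch == br]
        nodes <- rbind(nodes, data.frame(node_id = id, timepoint = tp,
                                         cluster = k,
                                         n_cells = length(cells[[id]]),
                                         stringsAsFactors = FALSE))
        parent <- if (i == bif_at + 1) paste0(tps[i - 1], ":1")
                  else paste0(tps[i - 1], ":", k)
        edges <- rbind(edges, data.frame(parent = parent, child = id,
                                         similarity = 1, method = "truth",
                                         stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(nodes = nodes, cells = cells, edges = edges,
                 timepoints = tps),
            class = "lineage_tree")
}

#' Write a simulated dataset to disk
#'
#' Emits \code{matrix.mtx} (MatrixMarket, genes x cells) with sidecars
#' \code{genes.txt} and \code{cells.txt}, \code{annotation.tsv}, and
#' \code{truth.json}. \code{\link{read_expression}} round-trips the matrix
#' exactly.
#'
#' @param sim A \code{\link{simulate_bifurcation}} result.
#' @param dir Output directory; created if absent. A non-empty existing
#'   directory is refused unless \code{force = TRUE}.
#' @param force Overwrite an existing non-empty directory.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "scbav_simulation"))
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE))
      && !force)
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(unclass(sim$counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(sim$counts), file.path(dir, "genes.txt"))
  writeLines(rownames(sim$counts), file.path(dir, "cells.txt"))
  ann <- sim$annotation
  ann$timepoint <- as.character(ann$timepoint)
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$markers <- lapply(truth$markers, function(s) s$genes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
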