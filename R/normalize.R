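#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' \code{v(c,g) = ln(1 + scale_factor * x(c,g) / total(c))}, the standard
#' scRNA-seq normalization.
#'
#' @param counts An \code{\link{expr_matrix}} with unit \code{counts}.
#' @param scale_factor Positive target library size (default 10,000).
#' @return An \code{expr_matrix} with unit \code{lognorm}.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_unit(counts) != "counts")
    stop("normalize_log expects unit 'counts', got '",
         expr_unit(counts), "'")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0)
    stop("`scale_factor` must be a single positive number")
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(rownames(counts)[tot == 0], 5), collapse = ", "))
  v <- log1p(unclass(counts) * (scale_factor / tot))
  expr_matrix(v, "lognorm")
}

# Dispersion (var/mean on lognorm values) standardized within
# equal-frequency mean bins. Genes with zero mean get dispersion 0 by
# convention. Bins with a single member or zero spread get z = 0.
dispersion_table <- function(norm, nbin = 20) {
  g <- ncol(norm)
  if (nbin > g)
    stop("nbin (", nbin, ") exceeds the number of genes scored (", g, ")")
  mu <- colMeans(norm)
  v <- apply(unclass(norm), 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bin <- ceiling(rank(mu, ties.method = "first") * nbin / g)
  z <- numeric(g)
  for (b in unique(bin)) {
    sel <- bin == b
    if (sum(sel) > 1) {
      s <- stats::sd(disp[sel])
      if (s > 0) z[sel] <- (disp[sel] - mean(disp[sel])) / s
    }
  }
  data.frame(gene = colnames(norm), mean = mu, dispersion = disp,
             z = z, bin = bin, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select highly variable genes
#'
#' Scores every gene by the dispersion (variance/mean) of its
#' log-normalized values, standardizes the dispersion within
#' equal-frequency bins of mean expression (so that lowly and highly
#' expressed genes compete only against peers of similar abundance), and
#' returns the genes with the largest standardized dispersion.
#'
#' @param norm An \code{\link{expr_matrix}} with unit \code{lognorm}.
#' @param n_top Number of genes to select (default 2000; clamped to the
#'   number of genes available is an error, per the contract below).
#' @param nbin Number of equal-frequency mean bins (default 20).
#' @return A list with elements \code{genes} (a \code{\link{gene_set}}
#'   named \code{"hvg"}) and \code{table} (the per-gene dispersion table
#'   with columns gene, mean, dispersion, z, bin).
#' @export
select_hvg <- function(norm, n_top = 2000, nbin = 20) {
  stopifnot(inherits(norm, "expr_matrix"))
  if (expr_unit(norm) != "lognorm")
    stop("select_hvg expects unit 'lognorm', got '", expr_unit(norm), "'")
  tab <- dispersion_table(norm, nbin)
  n_pos <- sum(tab$mean > 0)
  if (n_top > n_pos)
    stop("n_top (", n_top, ") exceeds the number of genes with positive ",
         "mean (", n_pos, ")")
  ord <- order(-tab$z, tab$gene)
  sel <- tab$gene[ord][seq_len(n_top)]
  list(genes = gene_set("hvg", sel), table = tab)
}

#' Filter lineage markers maintained at every timepoint
#'
#' Keeps a candidate gene only if its mean expression among the supplied
#' cells is at least \code{threshold} at \emph{every} timepoint. The
#' threshold is applied to whatever unit the matrix carries; the default of
#' 10 matches the conventional mean-FPKM cutoff for calling a marker
#' expressed, so supply an FPKM matrix if that is the rule you want.
#'
#' @param expr An \code{\link{expr_matrix}} (fpkm or lognorm).
#' @param ann \code{\link{cell_annotation}} covering every cell of
#'   \code{expr}.
#' @param candidates A \code{\link{gene_set}} of marker candidates.
#' @param threshold Per-timepoint mean cutoff (default 10).
#' @return A \code{gene_set} of the maintained markers; candidates absent
#'   from the matrix are reported via the \code{"skipped"} attribute and a
#'   message, not an error. The \code{"per_timepoint_means"} attribute
#'   carries the gene x timepoint mean table the decision was based on.
#' @export
maintained_markers <- function(expr, ann, candidates, threshold = 10) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(candidates, "gene_set"))
  ann <- align_annotation(expr, ann)
  present <- intersect(candidates$genes, colnames(expr))
  skipped <- setdiff(candidates$genes, present)
  if (length(skipped))
    message("maintained_markers: ", length(skipped),
            " candidate(s) absent from matrix: ",
            paste(utils::head(skipped, 10), collapse = ", "))
  tps <- levels(ann$timepoint)[table(ann$timepoint) > 0]
  if (length(present) == 0) {
    out <- structure(list(name = paste0(candidates$name, "_maintained"),
                          genes = character(0)), class = "gene_set")
    attr(out, "skipped") <- skipped
    return(out)
  }
  means <- sapply(tps, function(tp) {
    colMeans(expr[ann$timepoint == tp, present, drop = FALSE])
  })
  means <- matrix(means, nrow = length(present),
                  dimnames = list(present, tps))
  keep <- present[apply(means >= threshold, 1, all)]
  out <- structure(list(name = paste0(candidates$name, "_maintained"),
                        genes = keep), class = "gene_set")
  attr(out, "skipped") <- skipped
  attr(out, "per_timepoint_means") <- means
  out
}
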