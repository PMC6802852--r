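# Evaluate `expr` under a locally-set RNG seed, restoring the caller's
# RNG state afterwards so seeded functions do not perturb the session.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gene-set module score with bin-matched control genes
#'
#' Per-cell score of a gene set against expression-matched background: all
#' genes are placed into \code{nbin} equal-frequency bins by mean
#' expression; for each set gene, \code{nctrl} control genes are sampled
#' from its bin (without replacement when the bin is large enough,
#' otherwise with replacement and a warning); the score of a cell is its
#' mean over the set genes minus its mean over the pooled control draw.
#' Control sampling is seeded, so results are reproducible.
#'
#' @param norm An \code{\link{expr_matrix}} with unit \code{lognorm}.
#' @param set A \code{\link{gene_set}}; genes absent from the matrix are
#'   reported and skipped (an error only if none remain).
#' @param nbin Number of expression bins (default 25).
#' @param nctrl Control genes sampled per set gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return A data frame of class \code{module_score} with columns
#'   \code{cell_id} and \code{score}; attributes record the set name,
#'   binning parameters, seed and skipped genes.
#' @export
module_score <- function(norm, set, nbin = 25, nctrl = 100, seed = 1) {
  stopifnot(inherits(norm, "expr_matrix"), inherits(set, "gene_set"))
  if (expr_unit(norm) != "lognorm")
    stop("module_score expects unit 'lognorm'")
  genes <- colnames(norm)
  present <- intersect(set$genes, genes)
  skipped <- setdiff(set$genes, genes)
  if (length(present) == 0)
    stop("no gene of set '", set$name, "' is present in the matrix")
  if (length(skipped))
    message("module_score: skipping ", length(skipped),
            " gene(s) of '", set$name, "' absent from the matrix")
  g <- length(genes)
  nbin <- min(nbin, g)
  mu <- colMeans(norm)
  bin <- ceiling(rank(mu, ties.method = "first") * nbin / g)
  names(bin) <- genes
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(gn) {
      pool <- genes[bin == bin[[gn]]]
      if (length(pool) >= nctrl) {
        sample(pool, nctrl, replace = FALSE)
      } else {
        warning("bin ", bin[[gn]], " has fewer than nctrl genes; ",
                "sampling with replacement", call. = FALSE)
        sample(pool, nctrl, replace = TRUE)
      }
    }), use.names = FALSE)
  })
  set_mean <- rowMeans(norm[, present, drop = FALSE])
  ctrl_mean <- rowMeans(unclass(norm)[, ctrl, drop = FALSE])
  out <- data.frame(cell_id = rownames(norm),
                    score = unname(set_mean - ctrl_mean),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "set") <- set$name
  attr(out, "nbin") <- nbin
  attr(out, "nctrl") <- nctrl
  attr(out, "seed") <- seed
  attr(out, "skipped") <- skipped
  class(out) <- c("module_score", "data.frame")
  out
}

#' Assign each cell to the lineage with the highest module score
#'
#' Computes one \code{\link{module_score}} per marker set (all sets use the
#' same control-sampling seed, so the result does not depend on the order
#' the sets are listed in) and assigns each cell to the set with the
#' largest score. Exact ties go to the first-listed tied set and raise the
#' tie flag.
#'
#' @param norm An \code{\link{expr_matrix}} with unit \code{lognorm}.
#' @param sets A list of at least two \code{\link{gene_set}}s, e.g. TE /
#'   EPI / PE marker lists.
#' @inheritParams module_score
#' @return A data frame of class \code{lineage_call}: \code{cell_id}, one
#'   score column per set (named \code{score_<set>}), \code{lineage},
#'   \code{tie}.
#' @export
assign_lineages <- function(norm, sets, nbin = 25, nctrl = 100, seed = 1) {
  if (!is.list(sets) || length(sets) < 2 ||
      !all(vapply(sets, inherits, logical(1), "gene_set")))
    stop("`sets` must be a list of at least two gene_set objects")
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate set names")
  scores <- sapply(sets, function(s)
    module_score(norm, s, nbin = nbin, nctrl = nctrl, seed = seed)$score)
  scores <- matrix(scores, nrow = nrow(norm), dimnames = list(NULL, nm))
  best <- apply(scores, 1, which.max)          # first max on ties
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  tie <- rowSums(scores == top) > 1
  out <- data.frame(cell_id = rownames(norm), scores,
                    lineage = nm[best], tie = tie,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_along(nm)] <- paste0("score_", nm)
  class(out) <- c("lineage_call", "data.frame")
  out
}
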