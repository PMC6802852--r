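# Independent oracles used against the package's own routes.

# Two-sided Wilcoxon rank-sum p by full enumeration of all C(n1+n2, n1)
# group labelings of the pooled sample (mid-ranks; symmetric null).
wilcox_enum_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n1)])
  e_w <- n1 * (length(pool) + 1) / 2
  sel <- utils::combn(length(pool), n1)
  w_all <- apply(sel, 2, function(ix) sum(r[ix]))
  lo <- min(w_obs, 2 * e_w - w_obs)
  hi <- max(w_obs, 2 * e_w - w_obs)
  mean(w_all <= lo + 1e-9 | w_all >= hi - 1e-9)
}

# Hypergeometric upper tail by direct summation of the probability mass
# (choose-product route, independent of phyper).
hyper_sum_p <- function(M, K, n, k) {
  js <- k:min(n, K)
  sum(exp(lchoose(K, js) + lchoose(M - K, n - js) - lchoose(M, n)))
}

# Hypergeometric upper tail by literal subset enumeration: draw every
# n-subset of 1..M, count those overlapping the first K elements in >= k.
hyper_subset_p <- function(M, K, n, k) {
  sel <- utils::combn(M, n)
  mean(apply(sel, 2, function(s) sum(s <= K) >= k))
}

# A small lognorm expression matrix with named cells/genes.
random_lognorm <- function(n_cells, n_genes, seed = 1, sd = 1,
                           mean_range = c(0, 3)) {
  set.seed(seed)
  mu <- runif(n_genes, mean_range[1], mean_range[2])
  v <- abs(sweep(matrix(rnorm(n_cells * n_genes, sd = sd), n_cells), 2,
                 mu, `+`))
  dimnames(v) <- list(sprintf("c%03d", seq_len(n_cells)),
                      sprintf("g%03d", seq_len(n_genes)))
  expr_matrix(v, "lognorm")
}

# Small default-structure simulation for unit tests (fast).
tiny_sim <- function(seed = 1, ...) {
  simulate_bifurcation(simulation_params(
    cells_per_timepoint = 40, n_genes = 300, n_branch_de = 40,
    n_marker_genes = 15, seed = seed, ...))
}
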