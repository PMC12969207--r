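# Independent brute-force oracles used across the suite. These are written
# from first principles (sums, Floyd-Warshall, exhaustive pair enumeration)
# and never call the package functions they check.

# Pearson correlation from raw sums
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# all-pairs shortest paths on a binary undirected graph, Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Watts-Strogatz local clustering by direct triangle count; degree < 2 -> 0
bf_clustering_nodes <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
}

bf_global_efficiency <- function(A) {
  d <- bf_distances(A)
  off <- d[upper.tri(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

bf_global_metrics <- function(A) {
  d <- bf_distances(A)
  off <- d[upper.tri(d)]
  fin <- is.finite(off)
  leff <- vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  list(clustering = mean(bf_clustering_nodes(A)),
       char_path_length = if (any(fin)) mean(off[fin]) else NA_real_,
       global_efficiency = mean(ifelse(fin, 1 / off, 0)),
       local_efficiency = mean(leff))
}

bf_nodal_metrics <- function(A) {
  d <- bf_distances(A)
  list(degree = rowSums(A > 0),
       efficiency = vapply(seq_len(nrow(A)), function(i) {
         di <- d[i, -i]
         mean(ifelse(is.finite(di), 1 / di, 0))
       }, numeric(1)))
}

# random binary graph on n nodes with at least one edge
random_graph <- function(n, p) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    if (sum(A) > 0) return(A)
  }
}

# exhaustive-pair SFC oracle: coupling of (transformed sc, fc z) over the
# sc > 0 pair set restricted by a row/network/global selector
bf_pair_coupling <- function(fc, sc, pairs, log_transform = TRUE) {
  x <- apply(pairs, 1, function(pr) {
    v <- sc[pr[1], pr[2]]
    if (log_transform) log1p(v) else v
  })
  y <- apply(pairs, 1, function(pr) fc[pr[1], pr[2]])
  bf_pearson(x, y)
}

# small cohort used by several files; scaled for test runtime
small_cohort <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_regions = 40L, n_networks = 4L, n_per_group = c(10L, 10L),
         n_timepoints = 200L, sc_density = 0.7, coupling_base = 0.5,
         effect_regions = 35L, effect_delta = -0.3, n_genes = 60L,
         n_coupled_genes = 6L, n_receptor_maps = 5L,
         coupled_map_indices = 2L, receptor_strength = 0.6,
         master_seed = seed),
    list(...))
  gen_cohort(do.call(sim_config, args))
}

cohort_couplings <- function(cohort, ...) {
  lapply(cohort$subjects, function(s) {
    suppressMessages(subject_coupling(s$fc, s$sc, cohort$atlas, ...))
  })
}
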