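## Graph-theoretic validation metrics on thresholded functional networks.
##
## Conventions (the dominant ones in the brain-network literature, GRETNA
## style): binary proportional thresholding of positive Fisher-z edges over a
## sparsity sweep; characteristic path length averages over connected pairs
## only; efficiency sums 1/d with disconnected pairs contributing 0; local
## clustering of nodes with degree < 2 is 0; small-world normalization
## against degree-preserving rewired graphs.

#' Proportional threshold of a functional connectivity matrix
#'
#' Keeps the k largest positive z-entries of the upper triangle, where
#' \code{k = round(sparsity * n(n-1)/2)}, and symmetrizes to a binary
#' adjacency matrix. Ties at the cutoff are broken by the smaller (row,
#' column) index, so the edge set is reproducible. Negative z-values are
#' never retained; when there are fewer positive entries than k, all
#' positives are kept and the achieved sparsity is reported with a warning.
#'
#' @param fc regions x regions Fisher-z matrix.
#' @param sparsity retained edge fraction in (0, 1].
#' @return list of class \code{sfc_graph}: \code{adjacency} (binary,
#'   symmetric, zero diagonal), \code{sparsity} (requested),
#'   \code{achieved_sparsity}.
#' @export
threshold_proportional <- function(fc, sparsity) {
  .check_square_symmetric(unclass(fc), "fc")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  n <- nrow(fc)
  iu <- which(upper.tri(fc), arr.ind = TRUE)
  v <- fc[upper.tri(fc)]
  k <- round(sparsity * length(v))
  pos <- which(v > 0)
  ord <- pos[order(-v[pos], iu[pos, 1L], iu[pos, 2L])]
  if (length(pos) < k) {
    warning(sprintf(
      "threshold_proportional: only %d positive edges for requested %d; achieved sparsity %.4f",
      length(pos), k, length(pos) / length(v)))
  }
  sel <- ord[seq_len(min(k, length(pos)))]
  A <- matrix(0L, n, n)
  A[iu[sel, , drop = FALSE]] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(fc)
  structure(list(adjacency = A, sparsity = sparsity,
                 achieved_sparsity = length(sel) / length(v)),
            class = "sfc_graph")
}

.as_adj <- function(g) {
  if (inherits(g, "sfc_graph")) g$adjacency else as.matrix(g)
}

## nodal efficiency from the same distance routine
.nodal_efficiency <- function(A) {
  d <- .bin_distances(A)
  vapply(seq_len(nrow(A)), function(i) {
    di <- d[i, -i]
    mean(ifelse(is.finite(di), 1 / di, 0))
  }, numeric(1))
}

## all-pairs shortest path lengths of a binary undirected graph by breadth-
## first expansion with boolean matrix products; O(diameter) dense matmuls,
## much faster than per-subgraph graph objects at these sizes
.bin_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  reach <- A > 0
  diag(reach) <- TRUE
  step <- 1L
  repeat {
    newreach <- ((reach %*% (A > 0)) > 0) | reach
    newly <- newreach & !reach
    if (!any(newly)) break
    step <- step + 1L
    d[newly] <- step
    reach <- newreach
  }
  d
}

## deterministic metrics of one binary graph
.graph_metrics <- function(A) {
  n <- nrow(A)
  A <- (A > 0) + 0
  # Watts-Strogatz local clustering from triangle counts; degree < 2 -> 0
  A2 <- A %*% A
  tri <- diag(A2 %*% A)
  deg <- rowSums(A)
  cl <- ifelse(deg < 2, 0, tri / (deg * (deg - 1)))
  d <- .bin_distances(A)
  off <- d[upper.tri(d)]
  fin <- is.finite(off)
  cpl <- if (any(fin)) mean(off[fin]) else NA_real_
  geff <- mean(ifelse(fin, 1 / off, 0))
  leff_node <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    .global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  list(clustering = mean(cl), char_path_length = cpl,
       global_efficiency = geff, local_efficiency = mean(leff_node),
       n_disconnected_pairs = sum(!fin))
}

.global_efficiency <- function(A) {
  d <- .bin_distances(A)
  off <- d[upper.tri(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Global network metrics with small-world normalization
#'
#' Clustering coefficient (mean Watts-Strogatz local clustering, 0 for nodes
#' of degree < 2), characteristic path length (mean over connected pairs),
#' global efficiency (mean inverse distance, disconnected pairs contribute
#' 0), local efficiency (mean over nodes of the global efficiency of the
#' neighbor subgraph), and the small-world quantities gamma (clustering
#' normalized by \code{n_rand} degree-preserving rewired graphs), lambda
#' (path-length ratio) and sigma = gamma / lambda.
#'
#' @param g an \code{sfc_graph} or adjacency matrix.
#' @param n_rand number of rewired null graphs (>= 1).
#' @param seed integer seed for the rewiring stream.
#' @return named list of metrics, including the null-ensemble means
#'   \code{rand_clustering} and \code{rand_char_path_length} used for the
#'   normalization, and \code{n_disconnected_pairs}.
#' @export
global_metrics <- function(g, n_rand = 100L, seed = 1L) {
  A <- .as_adj(g)
  if (sum(A) == 0) stop("global_metrics: empty graph")
  if (n_rand < 1L) stop("n_rand must be >= 1")
  obs <- .graph_metrics(A)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            diag = FALSE)
  set.seed(seed)
  rand_cl <- rand_cpl <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    rw <- igraph::rewire(ig, igraph::keeping_degseq(
      niter = max(100L, 10L * igraph::ecount(ig))))
    Ar <- as.matrix(igraph::as_adjacency_matrix(rw, sparse = FALSE))
    mr <- .graph_metrics(Ar)
    rand_cl[r] <- mr$clustering
    rand_cpl[r] <- mr$char_path_length
  }
  mean_rand_cl <- mean(rand_cl)
  mean_rand_cpl <- mean(rand_cpl, na.rm = TRUE)
  gamma <- if (mean_rand_cl > 0) obs$clustering / mean_rand_cl else NA_real_
  lambda <- if (is.finite(obs$char_path_length) && mean_rand_cpl > 0) {
    obs$char_path_length / mean_rand_cpl
  } else {
    NA_real_
  }
  sigma <- if (is.finite(gamma) && is.finite(lambda) && lambda > 0) {
    gamma / lambda
  } else {
    NA_real_
  }
  c(obs[c("clustering", "char_path_length", "global_efficiency",
          "local_efficiency")],
    list(gamma = gamma, lambda_ratio = lambda, sigma = sigma,
         rand_clustering = mean_rand_cl,
         rand_char_path_length = mean_rand_cpl,
         n_disconnected_pairs = obs$n_disconnected_pairs))
}

#' Nodal degree centrality and nodal efficiency
#'
#' Degree centrality is the node's edge count; nodal efficiency is the mean
#' inverse shortest-path distance to all other nodes (unreachable nodes
#' contribute 0).
#'
#' @param g an \code{sfc_graph} or adjacency matrix.
#' @return data.frame with columns \code{node}, \code{degree_centrality},
#'   \code{nodal_efficiency}.
#' @export
nodal_metrics <- function(g) {
  A <- .as_adj(g)
  n <- nrow(A)
  neff <- .nodal_efficiency(A)
  data.frame(node = if (!is.null(rownames(A))) rownames(A) else
               sprintf("r%03d", seq_len(n) - 1L),
             degree_centrality = as.integer(rowSums(A)),
             nodal_efficiency = neff,
             stringsAsFactors = FALSE)
}

#' Group contrast of network topology over a sparsity sweep
#'
#' For every subject, thresholds the FC matrix at each sparsity in
#' \code{sparsities}, computes global and nodal metrics, and integrates each
#' metric curve over the sweep (trapezoidal AUC). The per-subject AUCs then
#' enter the covariate-adjusted group model of [group_glm_t()]; the seven
#' global metrics form one Bonferroni family, and each nodal metric is
#' corrected over regions.
#'
#' @param fcs list of Fisher-z FC matrices, one per subject, aligned with
#'   \code{meta} rows.
#' @param meta subjects table.
#' @param sparsities increasing sparsity grid (default 0.10 to 0.34 in steps
#'   of 0.01).
#' @param n_rand rewired nulls per graph for the small-world metrics.
#' @param seed integer seed; per-subject streams are derived from it.
#' @return list of class \code{sfc_topology_stats}: \code{global} stat table,
#'   \code{nodal_degree}, \code{nodal_efficiency} stat tables, and
#'   \code{auc} (the per-subject AUC matrices).
#' @export
topology_group_contrast <- function(fcs, meta,
                                    sparsities = seq(0.10, 0.34, by = 0.01),
                                    n_rand = 100L, seed = 1L) {
  stopifnot(length(fcs) == nrow(meta))
  if (length(sparsities) < 2L || is.unsorted(sparsities)) {
    stop("sparsities must be an increasing grid of length >= 2")
  }
  n_sub <- length(fcs)
  n_reg <- nrow(fcs[[1L]])
  gm_names <- c("sigma", "gamma", "lambda_ratio", "clustering",
                "char_path_length", "global_efficiency", "local_efficiency")

  g_auc <- matrix(NA_real_, n_sub, length(gm_names),
                  dimnames = list(meta$subject_id, gm_names))
  deg_auc <- matrix(NA_real_, n_sub, n_reg)
  neff_auc <- matrix(NA_real_, n_sub, n_reg)

  for (s in seq_len(n_sub)) {
    gcurve <- matrix(NA_real_, length(sparsities), length(gm_names),
                     dimnames = list(NULL, gm_names))
    dcurve <- matrix(NA_real_, length(sparsities), n_reg)
    ncurve <- matrix(NA_real_, length(sparsities), n_reg)
    for (k in seq_along(sparsities)) {
      g <- threshold_proportional(fcs[[s]], sparsities[k])
      gm <- global_metrics(g, n_rand = n_rand,
                           seed = derive_seed(seed, sprintf("topo_%d_%d", s, k)))
      gcurve[k, ] <- unlist(gm[gm_names])
      nm <- nodal_metrics(g)
      dcurve[k, ] <- nm$degree_centrality
      ncurve[k, ] <- nm$nodal_efficiency
    }
    g_auc[s, ] <- apply(gcurve, 2L, function(y) {
      if (anyNA(y)) NA_real_ else trapz(sparsities, y)
    })
    deg_auc[s, ] <- apply(dcurve, 2L, trapz, x = sparsities)
    neff_auc[s, ] <- apply(ncurve, 2L, trapz, x = sparsities)
  }

  rn <- if (!is.null(rownames(fcs[[1L]]))) rownames(fcs[[1L]]) else
    sprintf("r%03d", seq_len(n_reg) - 1L)
  colnames(deg_auc) <- colnames(neff_auc) <- rn

  fit_level <- function(Y, level) {
    res <- vector("list", ncol(Y))
    ok <- logical(ncol(Y))
    for (k in seq_len(ncol(Y))) {
      y <- Y[, k]
      keep <- !is.na(y)
      if (sum(keep & meta$group == "patient") < 2L ||
          sum(keep & meta$group == "control") < 2L ||
          stats::sd(y[keep]) == 0) next
      r <- .glm_group_t_mat(matrix(y[keep], ncol = 1L),
                            .design_matrix(meta[keep, , drop = FALSE]))
      res[[k]] <- list(t = r$t, df = r$df, p_unc = r$p_unc)
      ok[k] <- TRUE
    }
    .statmap(colnames(Y)[ok], level, res[ok], n_tests = sum(ok))
  }

  structure(list(global = fit_level(g_auc, "global_metric"),
                 nodal_degree = fit_level(deg_auc, "nodal_degree"),
                 nodal_efficiency = fit_level(neff_auc, "nodal_efficiency"),
                 auc = list(global = g_auc, degree = deg_auc,
                            nodal_efficiency = neff_auc),
                 sparsities = sparsities),
            class = "sfc_topology_stats")
}
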