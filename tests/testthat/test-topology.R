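test_that("proportional thresholding keeps exactly the top positive edges", {
  fc <- matrix(0, 4, 4)
  fc[upper.tri(fc)] <- c(0.5, 0.3, 0.9, 0.1, 0.7, 0.2)
  fc <- fc + t(fc)
  g <- threshold_proportional(fc, 0.5)
  expect_equal(sum(g$adjacency) / 2, 3)
  kept <- fc[upper.tri(fc)][g$adjacency[upper.tri(fc)] == 1]
  expect_setequal(kept, c(0.9, 0.7, 0.5))

  # sparsity 1 on an all-positive matrix -> complete graph
  pos <- matrix(0.1, 4, 4); pos[upper.tri(pos)] <- runif(6) + 0.01
  pos <- pos + t(pos); diag(pos) <- 0
  gc <- threshold_proportional(pos, 1)
  expect_true(all(gc$adjacency[upper.tri(gc$adjacency)] == 1))

  # negative entries are never retained, achieved sparsity is reported
  neg <- matrix(0, 4, 4); neg[upper.tri(neg)] <- c(-1, -2, 0.4, -3, 0.2, -0.5)
  neg <- neg + t(neg)
  expect_warning(gn <- threshold_proportional(neg, 0.9), "achieved sparsity")
  expect_equal(sum(gn$adjacency) / 2, 2)

  expect_error(threshold_proportional(fc, 0), "sparsity")
})

test_that("ties at the threshold break deterministically by index", {
  fc <- matrix(0, 5, 5)
  fc[upper.tri(fc)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.9, 0.9, 0.1, 0.1)
  fc <- fc + t(fc)
  g1 <- threshold_proportional(fc, 0.3)
  g2 <- threshold_proportional(fc, 0.3)
  expect_identical(g1$adjacency, g2$adjacency)
  # the two 0.9 edges plus the lexicographically first 0.5 edge
  expect_equal(sum(g1$adjacency) / 2, 3)
  iu <- which(upper.tri(fc), arr.ind = TRUE)
  tied <- iu[fc[upper.tri(fc)] == 0.5, , drop = FALSE]
  first_tied <- tied[order(tied[, 1], tied[, 2]), , drop = FALSE][1, ]
  expect_equal(g1$adjacency[first_tied[1], first_tied[2]], 1)
})

test_that("closed-form graphs give their textbook metric values", {
  K8 <- matrix(1, 8, 8); diag(K8) <- 0
  gm <- global_metrics(K8, n_rand = 3, seed = 1)
  expect_equal(gm$clustering, 1)
  expect_equal(gm$char_path_length, 1)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$local_efficiency, 1)

  # star with 3 leaves: six pair distances = three 1s and three 2s
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  gs <- global_metrics(star, n_rand = 3, seed = 1)
  expect_equal(gs$global_efficiency, 0.75)
  expect_equal(gs$char_path_length, 1.5)
  nm <- nodal_metrics(star)
  expect_equal(nm$degree_centrality, c(3L, 1L, 1L, 1L))
  expect_equal(nm$nodal_efficiency, c(1, 2/3, 2/3, 2/3))

  # isolated node: degree 0, efficiency 0
  iso <- rbind(cbind(star, 0), 0)
  nmi <- nodal_metrics(iso)
  expect_equal(nmi$degree_centrality[5], 0L)
  expect_equal(nmi$nodal_efficiency[5], 0)
})

test_that("deterministic metrics equal brute force on random small graphs", {
  set.seed(1234)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    A <- random_graph(n, runif(1, 0.2, 0.9))
    gm <- global_metrics(A, n_rand = 1, seed = rep)
    bf <- bf_global_metrics(A)
    expect_equal(gm$clustering, bf$clustering, tolerance = 1e-12)
    expect_equal(gm$char_path_length, bf$char_path_length, tolerance = 1e-12)
    expect_equal(gm$global_efficiency, bf$global_efficiency, tolerance = 1e-12)
    expect_equal(gm$local_efficiency, bf$local_efficiency, tolerance = 1e-12)
    nm <- nodal_metrics(A)
    bfn <- bf_nodal_metrics(A)
    expect_equal(nm$degree_centrality, as.integer(bfn$degree))
    expect_equal(nm$nodal_efficiency, bfn$efficiency, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to node relabeling", {
  set.seed(99)
  for (rep in 1:10) {
    A <- random_graph(8, 0.4)
    perm <- sample(8)
    Ap <- A[perm, perm]
    g1 <- global_metrics(A, n_rand = 1, seed = 1)
    g2 <- global_metrics(Ap, n_rand = 1, seed = 1)
    for (m in c("clustering", "char_path_length", "global_efficiency",
                "local_efficiency")) {
      expect_equal(g1[[m]], g2[[m]], tolerance = 1e-12)
    }
    expect_equal(sort(nodal_metrics(A)$nodal_efficiency),
                 sort(nodal_metrics(Ap)$nodal_efficiency), tolerance = 1e-12)
  }
})

test_that("small-worldness of rewired-null graphs is one in expectation", {
  set.seed(31)
  A <- random_graph(30, 0.25)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  # draw null graphs from the degree-preserving ensemble and measure each
  # one's sigma against its own rewired ensemble; the mean should sit at 1
  sigmas <- vapply(1:50, function(i) {
    rw <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * sum(A) / 2))
    An <- as.matrix(igraph::as_adjacency_matrix(rw, sparse = FALSE))
    global_metrics(An, n_rand = 10, seed = 500 + i)$sigma
  }, numeric(1))
  expect_gte(mean(sigmas), 0.9)
  expect_lte(mean(sigmas), 1.1)
})

test_that("the AUC of a constant metric curve is width times the constant", {
  x <- seq(0.10, 0.34, by = 0.01)
  expect_equal(sfcnet:::trapz(x, rep(2.5, length(x))), 2.5 * 0.24,
               tolerance = 1e-12)
  expect_equal(sfcnet:::trapz(c(0, 1), c(0, 1)), 0.5)
})

test_that("topology_group_contrast flags a planted nodal degradation", {
  set.seed(61)
  n <- 30; n_sub <- 36
  meta <- data.frame(subject_id = sprintf("S%02d", 1:n_sub),
                     group = rep(c("patient", "control"), each = n_sub / 2),
                     age = round(rnorm(n_sub, 26, 5)),
                     education = round(rnorm(n_sub, 14, 2)),
                     fd = round(runif(n_sub, 0.05, 0.3), 3),
                     handedness = sample(c("right", "left"), n_sub, TRUE,
                                         c(0.8, 0.2)),
                     stringsAsFactors = FALSE)
  base <- matrix(0, n, n)
  base[upper.tri(base)] <- runif(n * (n - 1) / 2, 0.1, 0.8)
  base <- base + t(base)
  fcs <- lapply(seq_len(n_sub), function(s) {
    fc <- base + matrix(rnorm(n * n, 0, 0.05), n, n)
    fc <- (fc + t(fc)) / 2; diag(fc) <- 0
    if (meta$group[s] == "patient") {
      fc[5, ] <- fc[5, ] * 0.25   # degrade region 5's connectivity
      fc[, 5] <- fc[5, ]
    }
    fc
  })
  topo <- suppressMessages(topology_group_contrast(
    fcs, meta, sparsities = c(0.15, 0.25, 0.35), n_rand = 3, seed = 7))
  ne <- topo$nodal_efficiency
  expect_equal(nrow(ne), n)
  ord <- order(abs(ne$t), decreasing = TRUE)
  expect_lte(which(ord == 5), 2)   # region 5 among the top |t|
  expect_lt(ne$t[5], 0)
  expect_equal(nrow(topo$global), 7)
  expect_equal(unique(topo$global$n_tests), 7)

  # determinism of the whole stage under a fixed seed
  topo2 <- suppressMessages(topology_group_contrast(
    fcs, meta, sparsities = c(0.15, 0.25, 0.35), n_rand = 3, seed = 7))
  expect_identical(topo$global, topo2$global)
})
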