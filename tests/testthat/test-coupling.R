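test_that("fisher_z matches the closed form and enforces its domain", {
  expect_identical(fisher_z(0), 0)
  # closed form 0.5 * log((1 + r) / (1 - r)) evaluated independently
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  grid <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(grid), 0.5 * log((1 + grid) / (1 - grid)),
               tolerance = 1e-12)
  expect_equal(fisher_z(-grid), -fisher_z(grid))   # odd function

  expect_error(fisher_z(1.0), ">= 1")
  expect_error(fisher_z(-1.0), ">= 1")
  expect_equal(fisher_z(1.0, clip = TRUE), atanh(1 - 1e-7))
})

test_that("compute_fc reproduces a hand-computed Pearson + arctanh table", {
  ts <- cbind(c(1, 3, 2, 5, 4),
              c(2, 2, 4, 6, 7),
              c(9, 7, 5, 4, 1))
  colnames(ts) <- c("rA", "rB", "rC")
  z <- compute_fc(ts)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(z[i, j], atanh(bf_pearson(ts[, i], ts[, j])),
                   tolerance = 1e-12)
    }
  }
  expect_identical(diag(unclass(z)), c(rA = 0, rB = 0, rC = 0))
  expect_equal(unclass(z), t(unclass(z)))
})

test_that("compute_fc rejects degenerate inputs by name", {
  ts <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(compute_fc(ts), "zero-variance.*b")
  expect_error(compute_fc(matrix(rnorm(3), 1, 3)), "2 timepoints")

  dup <- cbind(x = 1:6, y = 1:6, w = rnorm(6))
  expect_error(compute_fc(dup), ">= 1")
  zc <- compute_fc(dup, clip = TRUE)
  expect_equal(zc["x", "y"], atanh(1 - 1e-7))
  neg <- cbind(x = 1:6, y = -(1:6), w = rnorm(6))
  expect_equal(compute_fc(neg, clip = TRUE)["x", "y"], -atanh(1 - 1e-7))
})

test_that("regional_coupling matches direct Pearson on the SC > 0 edge set", {
  # 4-region toy: region 1 connected to 2,3,4
  sc <- matrix(0, 4, 4)
  sc[1, 2:4] <- c(1, 2, 3); sc <- sc + t(sc)
  fc <- matrix(0, 4, 4)
  fc[1, 2:4] <- c(0.1, 0.2, 0.3); fc <- fc + t(fc)
  expect_equal(regional_coupling(fc, sc, 1, log_transform = FALSE), 1.0)
  fc2 <- fc; fc2[1, 2:4] <- c(0.3, 0.2, 0.1); fc2[2:4, 1] <- c(0.3, 0.2, 0.1)
  expect_equal(regional_coupling(fc2, sc, 1, log_transform = FALSE), -1.0)

  # log-transform case against the brute-force oracle
  sc5 <- matrix(0, 5, 5)
  sc5[1, 2:5] <- c(2, 5, 9, 14); sc5 <- sc5 + t(sc5)
  fc5 <- matrix(0, 5, 5)
  fc5[1, 2:5] <- c(0.05, 0.30, 0.20, 0.45); fc5 <- fc5 + t(fc5)
  expect_equal(regional_coupling(fc5, sc5, 1, log_transform = TRUE),
               bf_pearson(log(c(3, 6, 10, 15)), c(0.05, 0.30, 0.20, 0.45)),
               tolerance = 1e-12)

  # fewer structural partners than min_edges -> missing
  sc_sparse <- matrix(0, 5, 5)
  sc_sparse[1, 2:3] <- c(4, 7); sc_sparse <- sc_sparse + t(sc_sparse)
  sc_sparse[4, 5] <- sc_sparse[5, 4] <- 3
  expect_true(is.na(regional_coupling(fc5, sc_sparse, 1)))
})

test_that("subject_coupling agrees with exhaustive pair enumeration", {
  set.seed(77)
  atlas <- gen_atlas(10, 2)
  for (rep in 1:5) {
    sc <- gen_structural(atlas, 0.7, seed = 100 + rep)
    fc <- matrix(0, 10, 10)
    fc[upper.tri(fc)] <- rnorm(45) * 0.4
    fc <- fc + t(fc)
    cp <- suppressMessages(subject_coupling(fc, sc, atlas))

    # whole brain: all sc > 0 upper-triangle pairs
    pairs <- which(upper.tri(sc) & sc > 0, arr.ind = TRUE)
    expect_equal(cp$whole_brain, bf_pair_coupling(fc, sc, pairs),
                 tolerance = 1e-12)

    # every network block
    net <- atlas$network_id + 1
    for (a in 1:2) {
      for (b in a:2) {
        keep <- (pmin(net[pairs[, 1]], net[pairs[, 2]]) == a) &
          (pmax(net[pairs[, 1]], net[pairs[, 2]]) == b)
        if (sum(keep) >= 3) {
          expect_equal(cp$network_block[a, b],
                       bf_pair_coupling(fc, sc, pairs[keep, , drop = FALSE]),
                       tolerance = 1e-12)
        }
      }
    }
    expect_equal(cp$network_block, t(cp$network_block))

    # regional values against the row-restricted oracle
    for (i in c(1, 5, 10)) {
      e <- setdiff(which(sc[i, ] > 0), i)
      expect_equal(unname(cp$regional[i]),
                   bf_pearson(log1p(sc[i, e]), fc[i, e]), tolerance = 1e-12)
    }
  }
})

test_that("a perfectly linear FC-SC relation gives coupling 1 everywhere", {
  atlas <- gen_atlas(10, 2)
  sc <- gen_structural(atlas, 0.8, seed = 3)
  fc <- 0.2 * log1p(unclass(sc))   # exact monotone-linear relation on edges
  diag(fc) <- 0
  cp <- suppressMessages(subject_coupling(fc, sc, atlas))
  expect_equal(unname(cp$whole_brain), 1, tolerance = 1e-10)
  blocks <- cp$network_block[!is.na(cp$network_block)]
  expect_equal(unname(blocks), rep(1, length(blocks)), tolerance = 1e-10)
})

test_that("coupling is invariant to increasing affine rescaling of profiles", {
  atlas <- gen_atlas(12, 2)
  sc <- gen_structural(atlas, 0.8, seed = 9)
  fc <- matrix(0, 12, 12)
  fc[upper.tri(fc)] <- rnorm(66) * 0.3
  fc <- fc + t(fc)
  base <- suppressMessages(subject_coupling(fc, sc, atlas))
  resc <- suppressMessages(subject_coupling(2.5 * fc + 0.1, sc, atlas))
  expect_equal(base$regional, resc$regional, tolerance = 1e-10)
  raw <- suppressMessages(subject_coupling(fc, sc, atlas,
                                           log_transform = FALSE))
  raw2 <- suppressMessages(subject_coupling(fc, 3 * unclass(sc), atlas,
                                            log_transform = FALSE))
  expect_equal(raw$regional, raw2$regional, tolerance = 1e-10)
})
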