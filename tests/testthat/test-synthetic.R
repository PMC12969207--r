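test_that("gen_atlas builds a bihemispheric parcellation deterministically", {
  a <- gen_atlas(8, 2, seed = 1)
  expect_equal(nrow(a), 8)
  expect_equal(sum(a$hemisphere == "L"), 4)
  expect_equal(sum(a$hemisphere == "R"), 4)
  # both networks present in both hemispheres
  for (h in c("L", "R")) {
    expect_setequal(unique(a$network_id[a$hemisphere == h]), c(0, 1))
  }
  expect_identical(a, gen_atlas(8, 2, seed = 1))

  big <- gen_atlas(400, 7, seed = 1)
  expect_equal(nrow(big), 400)
  expect_equal(as.vector(table(big$hemisphere)), c(200, 200))
  expect_equal(length(unique(big$network_id)), 7)

  expect_error(gen_atlas(9, 2), "even")
})

test_that("gen_structural respects density, symmetry and degree floor", {
  a <- gen_atlas(8, 2)
  full <- gen_structural(a, density = 1, seed = 2)
  expect_true(all(full[upper.tri(full)] > 0))
  expect_identical(unclass(full), t(unclass(full)))
  expect_true(all(diag(full) == 0))
  expect_true(all(full >= 0) && all(full == round(full)))

  sc <- gen_structural(a, density = 0.5, seed = 3)
  frac <- mean(sc[upper.tri(sc)] > 0)
  expect_gte(frac, 0.40)
  expect_lte(frac, 0.60)
  expect_true(all(rowSums(sc > 0) >= 3))

  expect_error(gen_structural(a, density = 0), "density")
})

test_that("gen_subject_fc is deterministic and hits extreme coupling targets", {
  a <- gen_atlas(60, 4)
  sc <- gen_structural(a, 0.8, seed = 5)

  s1 <- gen_subject_fc(sc, 0.5, 300, seed = 9)
  s2 <- gen_subject_fc(sc, 0.5, 300, seed = 9)
  expect_identical(s1$ts, s2$ts)

  # near-perfect target coupling is recovered at a long run
  hi <- gen_subject_fc(sc, 0.99, 10000, seed = 4)
  sfc <- vapply(seq_len(60), function(i) {
    regional_coupling(hi$fc, sc, i)
  }, numeric(1))
  expect_true(all(sfc > 0.9))

  expect_error(gen_subject_fc(sc, 1.0, 100), "in \\(-1, 1\\)")
})

test_that("zero target coupling yields near-zero measured SFC", {
  a <- gen_atlas(100, 4)
  sc <- gen_structural(a, 1.0, seed = 6)
  lo <- gen_subject_fc(sc, 0.0, 10000, seed = 8)
  sfc <- vapply(seq_len(100), function(i) {
    regional_coupling(lo$fc, sc, i)
  }, numeric(1))
  expect_lt(mean(abs(sfc)), 0.1)
})

test_that("gen_cohort plants group truth exactly on the effect regions", {
  coh <- small_cohort(seed = 21, effect_regions = 35L, effect_delta = -0.3)
  diffs <- which(coh$truth["patient", ] != coh$truth["control", ])
  expect_identical(diffs, structure(35L, names = colnames(coh$truth)[35]))
  expect_equal(unname(coh$truth["patient", 35] - coh$truth["control", 35]),
               -0.3)

  null <- small_cohort(seed = 22, effect_delta = 0)
  expect_identical(null$truth["patient", ], null$truth["control", ])

  # reproducibility of the full cohort under one master seed
  coh2 <- small_cohort(seed = 21, effect_regions = 35L, effect_delta = -0.3)
  expect_identical(coh$subjects[[3]]$fc, coh2$subjects[[3]]$fc)
  expect_identical(coh$meta, coh2$meta)
})

test_that("covariate effects shift measured coupling in the planted direction", {
  coh <- small_cohort(seed = 31, n_per_group = c(15L, 15L),
                      n_timepoints = 1000L, effect_delta = 0,
                      subject_sigma = 0,
                      covariate_effects = c(age = 0.25, education = 0,
                                            fd = 0, handedness = 0))
  cps <- cohort_couplings(coh)
  mean_sfc <- vapply(cps, function(cp) mean(cp$regional, na.rm = TRUE),
                     numeric(1))
  ct <- cor.test(coh$meta$age, mean_sfc)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("gen_expression plants map-coupled and donor-consistent genes", {
  a <- gen_atlas(100, 4)
  map <- stats::rnorm(100)

  # zero-noise limit: coupled genes equal the standardized map in every donor
  ex <- gen_expression(a, rep(TRUE, 100), n_genes = 20, n_donors = 3,
                       planted_map = map, n_coupled = 5, loading = 1,
                       seed = 3)
  zmap <- (map - mean(map)) / sd(map)
  for (d in 1:3) {
    expect_equal(ex$donor_values[, 1, d], zmap, tolerance = 1e-12)
  }
  ds <- differential_stability(ex$donor_values)
  expect_equal(unname(ds[1:5]), rep(1, 5), tolerance = 1e-12)

  # with no coupled genes, expression is uncorrelated with the map
  ex0 <- gen_expression(a, rep(TRUE, 100), n_genes = 200, n_donors = 2,
                        planted_map = map, n_coupled = 0, loading = 0.8,
                        seed = 4, consistent_fraction = 0)
  rs <- abs(cor(ex0$values, map))
  expect_lt(mean(rs), 0.1)

  expect_error(gen_expression(a, rep(FALSE, 100), 10, 2, map, 2, 0.5),
               "empty region mask")
})

test_that("gen_receptor_maps couples the requested maps monotonically", {
  a <- gen_atlas(60, 4)
  map <- stats::rnorm(60)
  # noise-free: Spearman with the planted map is exactly +/- 1
  mm <- gen_receptor_maps(a, map, n_maps = 5, coupled_indices = c(1, 3),
                          strength = 1, seed = 2)
  expect_equal(cor(mm[, 1], map, method = "spearman"), 1)
  neg <- gen_receptor_maps(a, map, n_maps = 5, coupled_indices = 2,
                           strength = -1, seed = 2)
  expect_equal(cor(neg[, 2], map, method = "spearman"), -1)

  full <- gen_receptor_maps(a, map, n_maps = 19, coupled_indices = c(2, 9),
                            strength = 0.6, seed = 5)
  expect_equal(ncol(full), 19)
  expect_true(all(c("5-HT1b", "SERT") %in% colnames(full)))
})
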