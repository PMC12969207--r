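make_meta <- function(n_pat, n_con, seed = 1) {
  set.seed(seed)
  n <- n_pat + n_con
  data.frame(subject_id = sprintf("S%03d", 1:n),
             group = rep(c("patient", "control"), c(n_pat, n_con)),
             age = round(rnorm(n, 26, 6)),
             education = round(rnorm(n, 14, 3)),
             fd = round(runif(n, 0.05, 0.3), 3),
             handedness = sample(c("right", "left"), n, TRUE, c(0.85, 0.15)),
             stringsAsFactors = FALSE)
}

test_that("group_glm_t equals the stats::lm oracle", {
  for (rep in 1:10) {
    meta <- make_meta(15, 12, seed = rep)
    set.seed(100 + rep)
    y <- rnorm(27) + 0.4 * (meta$group == "patient")
    ours <- group_glm_t(y, meta)
    fit <- summary(stats::lm(
      y ~ I(group == "patient") + age + education + fd +
        I(handedness == "left"), data = meta))
    expect_equal(ours$t, fit$coefficients[2, "t value"], tolerance = 1e-10)
    expect_equal(ours$p_unc, fit$coefficients[2, "Pr(>|t|)"],
                 tolerance = 1e-10)
    expect_equal(ours$df, fit$df[2])
  }
})

test_that("the group coefficient is the plain mean difference under an orthogonal design", {
  # covariates mirrored between groups so group is orthogonal to all of them
  meta <- make_meta(10, 10, seed = 3)
  meta$age <- rep(c(20, 25, 30, 35, 40), 4)
  meta$education <- rep(c(12, 10, 16, 18, 14), 4)
  meta$fd <- rep(c(0.2, 0.1, 0.3, 0.15, 0.25), 4)
  meta$handedness <- rep(c("right", "right", "left", "right", "left"), 4)
  set.seed(5)
  y <- rnorm(20)
  ours <- group_glm_t(y, meta)
  fit <- stats::lm(y ~ I(group == "patient") + age + education + fd +
                     I(handedness == "left"), data = meta)
  expect_equal(unname(coef(fit)[2]),
               mean(y[meta$group == "patient"]) -
                 mean(y[meta$group == "control"]),
               tolerance = 1e-10)
  expect_equal(ours$t, summary(fit)$coefficients[2, "t value"],
               tolerance = 1e-10)
})

test_that("group_glm_t rejects degenerate designs informatively", {
  meta <- make_meta(10, 10, seed = 7)
  expect_error(group_glm_t(rep(1, 20), meta), "zero variance")
  meta2 <- meta
  meta2$education <- 12
  expect_error(group_glm_t(rnorm(20), meta2), "education")
  expect_error(group_glm_t(c(rnorm(19), NA)[c(20, 1:19)], meta[1:2, ]),
               "2 subjects per group|sizes differ")
  expect_message(group_glm_t(c(NA, rnorm(19)), meta), "dropping 1")
})

test_that("null rejection rate is calibrated at the nominal level", {
  meta <- make_meta(100, 100, seed = 42)
  X <- sfcnet:::.design_matrix(meta)
  set.seed(4242)
  Y <- matrix(rnorm(200 * 1000), 200, 1000)
  res <- sfcnet:::.glm_group_t_mat(Y, X)
  rate <- mean(res$p_unc < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("a planted one-SD group deficit is detected with a negative t", {
  meta <- make_meta(40, 40, seed = 8)
  X <- sfcnet:::.design_matrix(meta)
  set.seed(88)
  n_rep <- 200
  Y <- matrix(rnorm(80 * n_rep), 80, n_rep) -
    matrix(meta$group == "patient", 80, n_rep) * 1.0
  res <- sfcnet:::.glm_group_t_mat(Y, X)
  expect_gte(mean(res$t < 0), 0.99)
  # power at two-sided p < 0.001 for d = 1, n = 40/40 is ~0.84 analytically;
  # check the simulation sits near it rather than asserting an unreachable bound
  expect_gte(mean(res$p_unc < 0.001 & res$t < 0), 0.70)
})

test_that("bonferroni is the capped product and monotone", {
  expect_equal(bonferroni(0.0001, 400), 0.04)
  expect_equal(bonferroni(0.01, 400), 1.0)
  expect_equal(bonferroni(0.05, 1), 0.05)
  p <- sort(runif(50))
  expect_true(all(diff(bonferroni(p, 50)) >= 0))
  expect_error(bonferroni(1.2), "outside")
})

test_that("group_contrast_all_levels corrects each level as its own family", {
  coh <- small_cohort(seed = 55, n_regions = 42L, n_networks = 7L,
                      n_per_group = c(8L, 8L), sc_density = 0.9,
                      effect_regions = 20L)
  cps <- cohort_couplings(coh)
  gs <- suppressMessages(group_contrast_all_levels(cps, coh$meta))
  expect_equal(nrow(gs$whole_brain), 1)
  expect_equal(gs$whole_brain$n_tests, 1)
  expect_equal(nrow(gs$network), 28)          # 7 * 8 / 2 unique blocks
  expect_equal(unique(gs$network$n_tests), 28)
  expect_equal(nrow(gs$regional), 42)
  expect_equal(gs$regional$p_corr,
               pmin(1, gs$regional$p_unc * gs$regional$n_tests))
})

test_that("all-missing units are excluded and the family size shrinks", {
  coh <- small_cohort(seed = 56)
  cps <- cohort_couplings(coh)
  for (i in seq_along(cps)) cps[[i]]$regional[3] <- NA_real_
  expect_message(gs <- group_contrast_all_levels(cps, coh$meta), "excluded 1")
  expect_equal(nrow(gs$regional), 39)
  expect_equal(unique(gs$regional$n_tests), 39)
  expect_false(names(cps[[1]]$regional)[3] %in% gs$regional$unit)
})

test_that("clinical correlations recover exact and planted associations", {
  coh <- small_cohort(seed = 57)
  cps <- cohort_couplings(coh)
  vals <- cbind(region35 = vapply(cps, function(cp) cp$regional[35],
                                  numeric(1)))
  meta <- coh$meta

  # affine transform of the coupling -> r = +/- 1
  meta$bai <- 10 + 5 * vals[, 1]
  meta$sds <- 10 - 5 * vals[, 1]
  cc <- clinical_correlations(vals, meta, scores = c("bai", "sds"),
                              patients_only = FALSE)
  expect_equal(cc$r[cc$score == "bai"], 1, tolerance = 1e-10)
  expect_equal(cc$r[cc$score == "sds"], -1, tolerance = 1e-10)

  # fewer than 3 complete pairs -> missing cell
  meta$bai[-(1:2)] <- NA
  cc2 <- clinical_correlations(vals, meta, scores = "bai",
                               patients_only = FALSE)
  expect_true(is.na(cc2$r))
  expect_equal(cc2$n, 2L)
})

test_that("a planted score-coupling association is recovered in patients", {
  coh <- small_cohort(seed = 58, n_per_group = c(96L, 10L),
                      n_timepoints = 300L, assoc_strength = 0.5,
                      assoc_region = 35L, assoc_score = "ybocs_compulsion")
  cps <- cohort_couplings(coh)
  vals <- cbind(r35 = vapply(cps, function(cp) cp$regional[35], numeric(1)))
  cc <- clinical_correlations(vals, coh$meta, scores = "ybocs_compulsion",
                              patients_only = TRUE)
  expect_gte(cc$r, 0.3)
  expect_lte(cc$r, 0.7)
  # an independent score shows no association of that size
  cc0 <- clinical_correlations(vals, coh$meta, scores = "bai",
                               patients_only = TRUE)
  expect_lt(abs(cc0$r), 0.3)
})
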