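## Synthetic cohort generator.
##
## Every generator here is a pure function of (arguments, seed); gen_cohort
## splits its master seed into named substreams via derive_seed() so that the
## structural backbone, FC noise, covariates, scores, expression and receptor
## maps are independent and individually reproducible.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator with defaults that
#' emulate a two-group OCD-style SFC study: a 400-region / 7-network
#' parcellation, 96 patients vs 84 controls, a single right-hemisphere region
#' with a coupling deficit, six expression donors, and 19 receptor maps of
#' which two (5-HT1b- and SERT-like) track the group-difference map.
#'
#' @param n_regions even number of regions.
#' @param n_networks number of canonical networks.
#' @param n_per_group integer pair c(patients, controls).
#' @param n_timepoints functional run length (volumes).
#' @param sc_density fraction of nonzero structural edges in (0, 1].
#' @param coupling_base target regional SFC shared by both groups, in (0, 1).
#' @param effect_regions 1-based region indices carrying the patient deficit;
#'   NULL picks one right-hemisphere region deterministically.
#' @param effect_delta signed change of target SFC in patients on
#'   \code{effect_regions}.
#' @param covariate_effects named numeric: additive effect (on the target-SFC
#'   scale, per standardized covariate unit) of age, education, fd and
#'   handedness (left = 1). Zero by default.
#' @param subject_sigma SD of the per-subject global shift of the target SFC
#'   (between-subject coupling variability shared across regions).
#' @param subject_sc_jitter resample each subject's fiber counts
#'   (Poisson around the backbone counts, support preserved).
#' @param n_genes,n_donors,n_coupled_genes,gene_loading expression generator:
#'   total genes, donors, genes whose spatial profile tracks the planted
#'   group-difference map, and the loading (correlation strength) of that
#'   coupling.
#' @param consistent_fraction fraction of non-coupled genes given a
#'   donor-consistent (but map-independent) spatial profile, so the
#'   differential-stability filter has structure to separate.
#' @param n_receptor_maps,coupled_map_indices,receptor_strength receptor-map
#'   generator: number of maps, which map columns track the planted map, and
#'   the (signed) Spearman-scale strength of that tracking.
#' @param assoc_score,assoc_region,assoc_strength clinical association:
#'   name of the score tied to measured SFC at \code{assoc_region} (default:
#'   the first effect region) in patients, and the target correlation.
#' @param expression_regions "all" or "L": regions covered by the expression
#'   matrix (donor tissue is often left-hemisphere only).
#' @param keep_ts store the simulated time series on each subject (needed to
#'   write a cohort to disk).
#' @param master_seed integer master seed.
#' @return a validated list of class \code{sfc_sim_config}.
#' @export
sim_config <- function(n_regions = 400L,
                       n_networks = 7L,
                       n_per_group = c(patient = 96L, control = 84L),
                       n_timepoints = 240L,
                       sc_density = 0.25,
                       coupling_base = 0.45,
                       effect_regions = NULL,
                       effect_delta = -0.3,
                       covariate_effects = c(age = 0, education = 0,
                                             fd = 0, handedness = 0),
                       subject_sigma = 0.12,
                       subject_sc_jitter = TRUE,
                       n_genes = 1000L,
                       n_donors = 6L,
                       n_coupled_genes = 50L,
                       gene_loading = 0.8,
                       consistent_fraction = 0.3,
                       n_receptor_maps = 19L,
                       coupled_map_indices = c(2L, 9L),
                       receptor_strength = -0.22,
                       assoc_score = "ybocs_compulsion",
                       assoc_region = NULL,
                       assoc_strength = 0.218,
                       expression_regions = c("all", "L"),
                       keep_ts = TRUE,
                       master_seed = 1L) {
  expression_regions <- match.arg(expression_regions)
  if (is.null(effect_regions)) {
    # one region well inside the right hemisphere (rTPJ stand-in)
    effect_regions <- as.integer(n_regions - floor(n_regions / 8) )
  }
  if (is.null(assoc_region)) assoc_region <- effect_regions[1L]
  cfg <- list(n_regions = as.integer(n_regions),
              n_networks = as.integer(n_networks),
              n_per_group = as.integer(n_per_group),
              n_timepoints = as.integer(n_timepoints),
              sc_density = sc_density,
              coupling_base = coupling_base,
              effect_regions = as.integer(effect_regions),
              effect_delta = effect_delta,
              covariate_effects = covariate_effects,
              subject_sigma = subject_sigma,
              subject_sc_jitter = isTRUE(subject_sc_jitter),
              n_genes = as.integer(n_genes),
              n_donors = as.integer(n_donors),
              n_coupled_genes = as.integer(n_coupled_genes),
              gene_loading = gene_loading,
              consistent_fraction = consistent_fraction,
              n_receptor_maps = as.integer(n_receptor_maps),
              coupled_map_indices = as.integer(coupled_map_indices),
              receptor_strength = receptor_strength,
              assoc_score = assoc_score,
              assoc_region = as.integer(assoc_region),
              assoc_strength = assoc_strength,
              expression_regions = expression_regions,
              keep_ts = isTRUE(keep_ts),
              master_seed = as.integer(master_seed))
  .check_sim_config(cfg)
  class(cfg) <- "sfc_sim_config"
  cfg
}

.check_sim_config <- function(cfg) {
  with(cfg, {
    if (n_regions %% 2L != 0L) stop("n_regions must be even")
    if (any(n_per_group < 1L) || length(n_per_group) != 2L) {
      stop("n_per_group must be two counts >= 1")
    }
    if (sc_density <= 0 || sc_density > 1) stop("sc_density must be in (0, 1]")
    if (coupling_base <= 0 || coupling_base >= 1) {
      stop("coupling_base must be in (0, 1)")
    }
    if (length(effect_regions) &&
        (min(effect_regions) < 1L || max(effect_regions) > n_regions)) {
      stop("effect_regions out of range")
    }
    tgt <- coupling_base + effect_delta
    if (tgt <= -1 || tgt >= 1) {
      stop("coupling_base + effect_delta must stay in (-1, 1)")
    }
    if (sc_density * (n_regions - 1L) < 3) {
      stop("sc_density too low: expected nonzero degree per region < 3")
    }
    if (n_coupled_genes > n_genes) stop("n_coupled_genes exceeds n_genes")
    if (gene_loading < 0 || gene_loading > 1) {
      stop("gene_loading must be in [0, 1]")
    }
    if (length(coupled_map_indices) &&
        (min(coupled_map_indices) < 1L ||
         max(coupled_map_indices) > n_receptor_maps)) {
      stop("coupled_map_indices out of range")
    }
    if (abs(receptor_strength) > 1) stop("|receptor_strength| must be <= 1")
    if (abs(assoc_strength) > 1) stop("|assoc_strength| must be <= 1")
  })
  invisible(TRUE)
}

#' Generate a synthetic structural (fiber-count) matrix
#'
#' Symmetric nonnegative integer counts on a random support of the requested
#' density, drawn as a rounded lognormal so the count distribution is
#' heavy-tailed like tract counts. Regenerates (bounded retries) until every
#' region has at least 3 nonzero edges and the realized density is within 10%
#' (relative) of the request.
#'
#' @param atlas an \code{sfc_atlas} (or an integer region count).
#' @param density fraction of nonzero upper-triangle entries, in (0, 1].
#' @param seed integer seed.
#' @param max_retry regeneration bound.
#' @return regions x regions matrix of class \code{sfc_sc}.
#' @export
gen_structural <- function(atlas, density, seed = 1L, max_retry = 50L) {
  n <- if (is.data.frame(atlas)) nrow(atlas) else as.integer(atlas)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n_pairs <- n * (n - 1L) / 2L
  set.seed(seed)
  for (attempt in seq_len(max_retry)) {
    on <- stats::runif(n_pairs) <= density
    counts <- pmax(1, round(stats::rlnorm(n_pairs, meanlog = log(40),
                                          sdlog = 1)))
    v <- ifelse(on, counts, 0)
    sc <- matrix(0, n, n)
    sc[upper.tri(sc)] <- v
    sc <- sc + t(sc)
    deg <- rowSums(sc > 0)
    frac <- mean(v > 0)
    ok_deg <- all(deg >= min(3L, n - 1L))
    ok_frac <- density == 1 || abs(frac - density) <= 0.1 * density
    if (ok_deg && ok_frac) {
      class(sc) <- c("sfc_sc", class(sc))
      return(sc)
    }
  }
  stop("gen_structural: could not satisfy density/degree constraints after ",
       max_retry, " attempts (density = ", density, ", n = ", n, ")")
}

## standardized log-SC profile matrix: z-scored log1p counts on the support,
## zero elsewhere and on the diagonal
.structure_profile <- function(sc) {
  B <- matrix(0, nrow(sc), ncol(sc))
  mask <- sc > 0
  diag(mask) <- FALSE
  v <- log1p(sc[mask])
  if (length(v) > 1L && stats::sd(v) > 0) {
    B[mask] <- (v - mean(v)) / stats::sd(v)
  }
  B
}

## symmetric standard-normal noise matrix, zero diagonal
.sym_noise <- function(n, seed) {
  set.seed(seed)
  N <- matrix(0, n, n)
  N[upper.tri(N)] <- stats::rnorm(n * (n - 1L) / 2L)
  N + t(N)
}

#' Generate one subject's time series and FC with planted regional coupling
#'
#' Builds a target correlation matrix whose region-i connectivity profile is a
#' blend of the (log-transformed, standardized) structural profile and
#' independent symmetric noise; the blend weight on edge (i, j) is the signed
#' geometric mean of the two regions' coupling targets, so a uniform target c
#' yields an expected profile correlation of exactly c. Off-diagonal
#' amplitude is scaled to \code{0.42/sqrt(n)} (the random-matrix bound that
#' keeps the construction near the positive-definite cone), the matrix is
#' projected to the nearest positive-definite correlation matrix by
#' eigenvalue clipping, and \code{n_timepoints} multivariate-normal draws are
#' sampled from it.
#'
#' At finite run lengths the measured SFC is attenuated toward zero by
#' sampling noise in the empirical FC; the attenuation vanishes as
#' \code{n_timepoints} grows (see the methods vignette).
#'
#' @param sc structural matrix (defines the profile being coupled to).
#' @param target_coupling numeric vector of per-region target SFC in (-1, 1)
#'   (recycled if scalar).
#' @param n_timepoints number of samples to draw.
#' @param seed integer seed for the sampling stream.
#' @param noise optional pre-drawn symmetric noise matrix (used by
#'   [gen_cohort()] to share one FC backbone across subjects); defaults to a
#'   fresh draw from \code{seed}.
#' @return list with \code{ts} (timepoints x regions), \code{fc} (empirical
#'   Fisher-z FC), and \code{target} (the projected target correlation
#'   matrix).
#' @export
gen_subject_fc <- function(sc, target_coupling, n_timepoints, seed = 1L,
                           noise = NULL) {
  .check_square_symmetric(sc, "sc")
  n <- nrow(sc)
  cvec <- rep_len(target_coupling, n)
  if (any(abs(cvec) >= 1)) stop("target coupling values must be in (-1, 1)")
  if (n_timepoints < 2L) stop("need at least 2 timepoints")

  B <- .structure_profile(sc)
  N <- if (is.null(noise)) .sym_noise(n, derive_seed(seed, "fc_noise")) else noise
  .check_square_symmetric(N, "noise")

  ## signed geometric-mean blend weights; opposite-signed pairs get zero
  ## structural weight
  s <- sign(cvec)
  a <- sqrt(abs(cvec))
  W <- outer(s * a, s * a)
  W[outer(s, s) < 0] <- 0
  V <- outer((1 - cvec^2)^(1 / 4), (1 - cvec^2)^(1 / 4))

  F0 <- W * B + V * N
  diag(F0) <- 0
  off <- F0[upper.tri(F0)]
  sd0 <- stats::sd(off)
  amp <- if (sd0 > 0) 0.42 / (sqrt(n) * sd0) else 0
  R <- amp * F0
  R[R > 0.95] <- 0.95
  R[R < -0.95] <- -0.95
  diag(R) <- 1

  ## one Higham step: clip negative eigenvalues, rescale to unit diagonal
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < 1e-8) {
    vals <- pmax(eg$values, 1e-8)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    R <- stats::cov2cor(R)
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    stop("gen_subject_fc: positive-definite projection failed ",
         "(min eigenvalue ", format(min(eg$values), digits = 3), ")")
  }

  set.seed(derive_seed(seed, "fc_draws"))
  ts <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n) %*% ch
  colnames(ts) <- sprintf("r%03d", seq_len(n) - 1L)
  list(ts = ts, fc = compute_fc(ts, clip = TRUE), target = R)
}

## plausible covariates; reference centering constants are fixed so that the
## planted covariate effects do not depend on the realized sample
.covariate_refs <- list(age = c(26, 6), education = c(14, 3), fd = c(0.12, 0.08))

.gen_meta <- function(n_patient, n_control, seed) {
  set.seed(seed)
  n <- n_patient + n_control
  group <- c(rep("patient", n_patient), rep("control", n_control))
  age <- pmin(pmax(round(stats::rnorm(n, 26, 6)), 18), 55)
  education <- pmin(pmax(round(stats::rnorm(n, 14, 3)), 6), 22)
  fd <- round(pmin(pmax(stats::rlnorm(n, log(0.12), 0.35), 0.02), 0.6), 4)
  handedness <- sample(c("right", "left"), n, replace = TRUE,
                       prob = c(0.9, 0.1))
  # keep the handedness indicator estimable within each group
  for (g in c("patient", "control")) {
    idx <- which(group == g)
    if (all(handedness[idx] == "right")) handedness[idx[length(idx)]] <- "left"
    if (all(handedness[idx] == "left")) handedness[idx[1L]] <- "right"
  }
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             group = group, age = age, education = education, fd = fd,
             handedness = handedness, stringsAsFactors = FALSE)
}

.score_defs <- list(
  ybocs_obsession  = list(patient = c(12, 3), control = c(1, 1), max = 20),
  ybocs_compulsion = list(patient = c(12, 3), control = c(1, 1), max = 20),
  ocir_washing     = list(patient = c(6, 3),  control = c(1, 1), max = 12),
  ocir_checking    = list(patient = c(6, 3),  control = c(1, 1), max = 12),
  ocir_ordering    = list(patient = c(6, 3),  control = c(1, 1), max = 12),
  ocir_hoarding    = list(patient = c(5, 3),  control = c(1, 1), max = 12),
  ocir_obsessing   = list(patient = c(6, 3),  control = c(1, 1), max = 12),
  ocir_neutralizing = list(patient = c(5, 3), control = c(1, 1), max = 12),
  bai              = list(patient = c(18, 8), control = c(3, 2), max = 63),
  bdi_ii           = list(patient = c(16, 8), control = c(3, 2), max = 63),
  sds              = list(patient = c(14, 6), control = c(2, 2), max = 30)
)

.gen_scores <- function(meta, assoc_score, assoc_strength, assoc_sfc, seed) {
  set.seed(seed)
  n <- nrow(meta)
  pat <- meta$group == "patient"
  scores <- list()
  for (nm in names(.score_defs)) {
    d <- .score_defs[[nm]]
    raw <- numeric(n)
    raw[pat] <- stats::rnorm(sum(pat), d$patient[1], d$patient[2])
    raw[!pat] <- stats::rnorm(sum(!pat), d$control[1], d$control[2])
    if (nm == assoc_score && abs(assoc_strength) > 0 &&
        !is.null(assoc_sfc) && sum(pat) >= 3 &&
        stats::sd(assoc_sfc[pat], na.rm = TRUE) > 0) {
      z <- assoc_sfc[pat]
      z[is.na(z)] <- mean(z, na.rm = TRUE)
      z <- .zscore(z)
      mix <- assoc_strength * z +
        sqrt(1 - assoc_strength^2) * stats::rnorm(sum(pat))
      raw[pat] <- d$patient[1] + d$patient[2] * mix
    }
    scores[[nm]] <- pmin(pmax(round(raw), 0), d$max)
  }
  scores <- as.data.frame(scores)
  scores$ybocs_total <- scores$ybocs_obsession + scores$ybocs_compulsion
  scores
}

#' Generate a full synthetic cohort with planted structure
#'
#' Produces paired structural/functional connectomes for two groups, subject
#' covariates and clinical scores, a donor-stacked expression matrix, and a
#' receptor-map set — all carrying known planted structure so every
#' downstream stage of the pipeline has a recovery test. See the methods
#' vignette for the generative model.
#'
#' The cohort shares one structural backbone and one FC noise matrix across
#' subjects; between-subject variability comes from Poisson-resampled fiber
#' counts, a per-subject global coupling shift (\code{subject_sigma}), and
#' finite-run sampling noise in the empirical FC.
#'
#' @param config an [sim_config()] object.
#' @return an object of class \code{sfc_cohort}: list with \code{atlas},
#'   \code{subjects} (each: \code{fc}, \code{sc}, optionally \code{ts}),
#'   \code{meta}, \code{truth} (2 x regions matrix of covariate-free target
#'   SFC per group), \code{expression}, \code{receptors}, \code{config}.
#' @export
gen_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sfc_sim_config")) config <- do.call(sim_config, config)
  .check_sim_config(config)
  ms <- config$master_seed
  n <- config$n_regions

  atlas <- gen_atlas(n, config$n_networks, derive_seed(ms, "atlas"))
  sc0 <- gen_structural(atlas, config$sc_density, derive_seed(ms, "sc_backbone"))
  N <- .sym_noise(n, derive_seed(ms, "fc_backbone"))

  meta <- .gen_meta(config$n_per_group[1L], config$n_per_group[2L],
                    derive_seed(ms, "meta"))

  truth <- matrix(config$coupling_base, 2L, n,
                  dimnames = list(c("patient", "control"), atlas$region_name))
  truth["patient", config$effect_regions] <-
    config$coupling_base + config$effect_delta

  ce <- config$covariate_effects
  refs <- .covariate_refs
  set.seed(derive_seed(ms, "subject_shift"))
  shift <- stats::rnorm(nrow(meta), 0, config$subject_sigma)

  subjects <- vector("list", nrow(meta))
  assoc_sfc <- rep(NA_real_, nrow(meta))
  for (s in seq_len(nrow(meta))) {
    tgt <- truth[meta$group[s], ] + shift[s] +
      ce[["age"]] * (meta$age[s] - refs$age[1]) / refs$age[2] +
      ce[["education"]] * (meta$education[s] - refs$education[1]) / refs$education[2] +
      ce[["fd"]] * (meta$fd[s] - refs$fd[1]) / refs$fd[2] +
      ce[["handedness"]] * as.integer(meta$handedness[s] == "left")
    tgt <- pmin(pmax(tgt, -0.9), 0.9)

    sc_s <- sc0
    if (config$subject_sc_jitter) {
      set.seed(derive_seed(ms, paste0("sc_jitter_", s)))
      mask <- upper.tri(sc0) & sc0 > 0
      sc_s[mask] <- pmax(1, stats::rpois(sum(mask), sc0[mask]))
      sc_s[lower.tri(sc_s)] <- t(sc_s)[lower.tri(sc_s)]
    }

    gen <- gen_subject_fc(sc_s, tgt, config$n_timepoints,
                          seed = derive_seed(ms, paste0("subject_", s)),
                          noise = N)
    assoc_sfc[s] <- regional_coupling(gen$fc, sc_s, config$assoc_region)
    subjects[[s]] <- list(subject_id = meta$subject_id[s],
                          fc = gen$fc, sc = sc_s,
                          ts = if (config$keep_ts) gen$ts else NULL)
  }

  meta <- cbind(meta, .gen_scores(meta, config$assoc_score,
                                  config$assoc_strength, assoc_sfc,
                                  derive_seed(ms, "scores")))

  planted <- truth["patient", ] - truth["control", ]
  region_mask <- if (config$expression_regions == "L") {
    atlas$hemisphere == "L"
  } else {
    rep(TRUE, n)
  }
  expression <- gen_expression(atlas, region_mask, config$n_genes,
                               config$n_donors, planted,
                               config$n_coupled_genes, config$gene_loading,
                               seed = derive_seed(ms, "expression"),
                               consistent_fraction = config$consistent_fraction)
  receptors <- gen_receptor_maps(atlas, planted, config$n_receptor_maps,
                                 config$coupled_map_indices,
                                 config$receptor_strength,
                                 seed = derive_seed(ms, "receptors"))

  structure(list(atlas = atlas, subjects = subjects, meta = meta,
                 truth = truth, expression = expression,
                 receptors = receptors, config = config),
            class = "sfc_cohort")
}

#' @export
print.sfc_cohort <- function(x, ...) {
  cat("Synthetic SFC cohort:", nrow(x$meta), "subjects (",
      sum(x$meta$group == "patient"), "patients /",
      sum(x$meta$group == "control"), "controls ),",
      x$config$n_regions, "regions,", x$config$n_networks, "networks\n")
  eff <- which(x$truth["patient", ] != x$truth["control", ])
  cat("  planted effect regions:",
      if (length(eff)) paste(eff, collapse = ", ") else "none",
      "( delta =", x$config$effect_delta, ")\n")
  invisible(x)
}

## JuSpace-style receptor/transporter map names
.juspace_names <- c("5-HT1a", "5-HT1b", "5-HT2a", "D1", "D2", "DAT",
                    "F-DOPA", "NAT", "SERT", "5-HT4", "CB1", "CBF_ASL_MRI",
                    "GABAa", "KappaOp", "MU", "NMDA", "VAChT", "mGluR5",
                    "5-HTT")

#' Generate a donor-stacked regional gene-expression matrix
#'
#' The first \code{n_coupled} genes track the standardized planted map at the
#' requested loading (per-donor independent residual noise); a configurable
#' fraction of the remaining genes get a gene-specific spatial profile shared
#' across donors (donor-consistent but map-independent), and the rest are
#' pure per-donor noise. Differential stability therefore separates the
#' consistent genes (coupled + structured) from the inconsistent ones.
#'
#' @param atlas an \code{sfc_atlas}.
#' @param region_mask logical vector over regions (the expression coverage).
#' @param n_genes,n_donors counts.
#' @param planted_map numeric vector over all atlas regions (e.g. the
#'   group-difference truth map); only the masked part is used. A constant
#'   map disables gene coupling with a message.
#' @param n_coupled number of map-coupled genes.
#' @param loading correlation strength of coupled genes with the map, in
#'   [0, 1]; 1 means noise-free.
#' @param seed integer seed.
#' @param consistent_fraction fraction of the non-coupled genes with
#'   donor-consistent structure.
#' @return object of class \code{sfc_expression}: list with \code{values}
#'   (regions x genes, donor mean), \code{donor_values} (regions x genes x
#'   donors array), \code{gene_ids}, \code{region_ids} (0-based),
#'   \code{coupled_genes}.
#' @export
gen_expression <- function(atlas, region_mask, n_genes, n_donors, planted_map,
                           n_coupled, loading, seed = 1L,
                           consistent_fraction = 0.3) {
  .check_atlas(atlas)
  if (!any(region_mask)) stop("gen_expression: empty region mask")
  if (n_coupled > n_genes) stop("n_coupled exceeds n_genes")
  if (n_donors < 1L) stop("need at least one donor")
  regions <- which(region_mask)
  m <- length(regions)
  pm <- planted_map[regions]
  if (stats::sd(pm) == 0) {
    if (n_coupled > 0) {
      message("gen_expression: planted map is constant; coupled genes ",
              "degenerate to noise")
    }
    pstd <- rep(0, m)
  } else {
    pstd <- .zscore(pm)
  }

  set.seed(seed)
  n_structured <- round(consistent_fraction * (n_genes - n_coupled))
  type <- c(rep("coupled", n_coupled), rep("structured", n_structured),
            rep("noise", n_genes - n_coupled - n_structured))
  struct_profiles <- matrix(stats::rnorm(m * n_structured), m, n_structured)

  donor_values <- array(0, dim = c(m, n_genes, n_donors))
  resid <- sqrt(1 - loading^2)
  for (d in seq_len(n_donors)) {
    noise <- matrix(stats::rnorm(m * n_genes), m, n_genes)
    vals <- noise
    if (n_coupled > 0) {
      vals[, seq_len(n_coupled)] <- loading * pstd +
        resid * noise[, seq_len(n_coupled)]
    }
    if (n_structured > 0) {
      cols <- n_coupled + seq_len(n_structured)
      vals[, cols] <- 0.8 * struct_profiles + 0.6 * noise[, cols]
    }
    donor_values[, , d] <- vals
  }

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  values <- apply(donor_values, c(1L, 2L), mean)
  dimnames(values) <- list(sprintf("r%03d", regions - 1L), gene_ids)
  structure(list(values = values, donor_values = donor_values,
                 gene_ids = gene_ids, region_ids = regions - 1L,
                 coupled_genes = gene_ids[seq_len(n_coupled)],
                 gene_type = type),
            class = "sfc_expression")
}

#' Generate a receptor/transporter density map set
#'
#' Coupled maps are a strength-weighted linear (hence monotone) transform of
#' the standardized planted map plus independent noise, so they are
#' Spearman-correlated with it by construction; the remaining maps are
#' independent noise.
#'
#' @param atlas an \code{sfc_atlas}.
#' @param planted_map numeric vector over regions.
#' @param n_maps number of maps; 19 gets the JuSpace-style names.
#' @param coupled_indices which map columns track the planted map.
#' @param strength signed correlation strength in [-1, 1]; |strength| = 1
#'   means noise-free.
#' @param seed integer seed.
#' @return regions x maps numeric matrix (class \code{sfc_receptor_maps})
#'   with map names as column names.
#' @export
gen_receptor_maps <- function(atlas, planted_map, n_maps, coupled_indices,
                              strength, seed = 1L) {
  .check_atlas(atlas)
  n <- nrow(atlas)
  if (length(coupled_indices) &&
      (min(coupled_indices) < 1L || max(coupled_indices) > n_maps)) {
    stop("coupled_indices out of range")
  }
  pstd <- if (stats::sd(planted_map) > 0) .zscore(planted_map) else rep(0, n)
  set.seed(seed)
  maps <- matrix(stats::rnorm(n * n_maps), n, n_maps)
  for (k in coupled_indices) {
    maps[, k] <- strength * pstd + sqrt(1 - strength^2) * maps[, k]
  }
  colnames(maps) <- if (n_maps == 19L) {
    .juspace_names[seq_len(19L)]
  } else {
    sprintf("map%02d", seq_len(n_maps))
  }
  rownames(maps) <- sprintf("r%03d", atlas$region_id)
  class(maps) <- c("sfc_receptor_maps", class(maps))
  maps
}
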