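## Imaging-transcriptomics stage: differential-stability gene filtering and
## first-component PLS regression of the regional group t-map on expression,
## with a region-permutation test of variance explained and bootstrap
## z-score gene selection.
##
## PLS1 here is the classical NIPALS first component for a univariate
## response: the gene weight vector is the normalized covariance X'y of the
## standardized expression matrix with the standardized response, the
## regional score is Xw, and variance explained is the squared Pearson
## correlation between score and response (the response-side definition).

## colwise Spearman between two region x gene matrices
.col_spearman <- function(A, B) {
  ra <- apply(A, 2L, rank)
  rb <- apply(B, 2L, rank)
  sa <- apply(A, 2L, stats::sd)
  sb <- apply(B, 2L, stats::sd)
  ra <- scale(ra)
  rb <- scale(rb)
  out <- colSums(ra * rb) / (nrow(A) - 1L)
  out[sa == 0 | sb == 0] <- NA_real_
  out
}

#' Differential stability of regional expression profiles
#'
#' For every gene, the mean over donor pairs of the Spearman correlation
#' between the two donors' regional expression profiles. Pairs in which a
#' donor's profile is constant contribute a missing value; the mean is taken
#' over the remaining pairs (with a message).
#'
#' @param donor_values regions x genes x donors array (>= 2 donors,
#'   >= 3 regions), or a list of regions x genes matrices.
#' @return per-gene DS score vector (named if gene names are available).
#' @export
differential_stability <- function(donor_values) {
  if (is.list(donor_values)) {
    donor_values <- simplify2array(donor_values)
  }
  stopifnot(length(dim(donor_values)) == 3L)
  m <- dim(donor_values)[1L]
  n_genes <- dim(donor_values)[2L]
  n_donors <- dim(donor_values)[3L]
  if (n_donors < 2L) stop("need at least 2 donors")
  if (m < 3L) stop("need at least 3 regions")
  pairs <- utils::combn(n_donors, 2L)
  acc <- matrix(NA_real_, n_genes, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    acc[, p] <- .col_spearman(donor_values[, , pairs[1L, p]],
                              donor_values[, , pairs[2L, p]])
  }
  n_bad <- sum(is.na(acc))
  if (n_bad > 0) {
    message("differential_stability: ", n_bad,
            " donor-pair correlation(s) undefined (constant profile); ",
            "averaged over the remaining pairs")
  }
  ds <- rowMeans(acc, na.rm = TRUE)
  ds[!is.finite(ds)] <- NA_real_
  names(ds) <- colnames(donor_values)
  ds
}

#' Retain the most stable fraction of genes
#'
#' Genes with DS at or above the (1 - fraction) quantile. Ties at the
#' boundary are all retained (with a message when that inflates the count);
#' genes with missing DS are never retained.
#'
#' @param ds per-gene DS scores.
#' @param fraction fraction to retain, in (0, 1].
#' @return integer indices of retained genes.
#' @export
filter_top_fraction <- function(ds, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ok <- which(!is.na(ds))
  if (!length(ok)) stop("all DS scores missing")
  thr <- stats::quantile(ds[ok], 1 - fraction, names = FALSE)
  keep <- ok[ds[ok] >= thr]
  expected <- ceiling(fraction * length(ok))
  if (length(keep) > expected) {
    message("filter_top_fraction: ", length(keep) - expected,
            " extra gene(s) retained due to ties at the boundary")
  }
  if (length(unique(ds[ok])) == 1L) {
    warning("filter_top_fraction: all DS scores tied; retaining every gene")
  }
  keep
}

#' First-component PLS of a regional response on gene expression
#'
#' Standardizes the columns of X and the response y across regions, takes the
#' first PLS component (weight vector proportional to X'y, the direction of
#' maximal covariance between the X-score and y), and reports the variance
#' explained as the squared Pearson correlation between the PLS1 regional
#' score and y. The sign convention flips the component so that the score-y
#' correlation is positive.
#'
#' @param X regions x genes numeric matrix (already restricted to retained
#'   genes), at least 3 regions.
#' @param y regional response vector (e.g. the unthresholded group t-map) on
#'   the same regions.
#' @return list of class \code{sfc_pls}: \code{weights} (named per-gene),
#'   \code{scores} (per-region), \code{varexp}.
#' @export
fit_pls1 <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < 3L) stop("need at least 3 regions")
  if (stats::sd(y) == 0) stop("constant response")
  Xs <- .col_standardize(X, constant = "error")
  ys <- .zscore(y)
  w <- crossprod(Xs, ys)[, 1L]
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate PLS weight vector (X'y = 0)")
  w <- w / nw
  scores <- as.numeric(Xs %*% w)
  r <- stats::cor(scores, ys)
  if (r < 0) {
    w <- -w
    scores <- -scores
    r <- -r
  }
  names(w) <- colnames(X)
  structure(list(weights = w, scores = scores, varexp = r^2),
            class = "sfc_pls")
}

## fast varexp for pre-standardized Xs and a standardized response block
## (regions x n_perm); returns one varexp per column
.pls1_varexp_block <- function(Xs, Yb) {
  W <- crossprod(Xs, Yb)                       # genes x n_perm
  S <- Xs %*% W                                # regions x n_perm
  Sc <- sweep(S, 2L, colMeans(S), "-")
  Yc <- sweep(Yb, 2L, colMeans(Yb), "-")
  num <- colSums(Sc * Yc)
  den <- sqrt(colSums(Sc^2) * colSums(Yc^2))
  (num / den)^2
}

#' Permutation test of PLS1 variance explained
#'
#' Permutes the region assignment of the response \code{n_perm} times,
#' refits PLS1, and returns the add-one permutation p-value
#' \code{(1 + #\{varexp_perm >= varexp_obs\}) / (n_perm + 1)}. The
#' permutation is uniform over regions; a matrix of user-supplied region
#' orderings (e.g. spin-test nulls) can be given instead.
#'
#' @inheritParams fit_pls1
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param perm_orders optional n_perm x regions matrix of permutation indices
#'   to use instead of uniform draws.
#' @return list with \code{perm_p}, \code{varexp_obs}, \code{n_perm}.
#' @export
pls_perm_test <- function(X, y, n_perm = 5000L, seed = 1L,
                          perm_orders = NULL) {
  X <- as.matrix(X)
  obs <- fit_pls1(X, y)$varexp
  Xs <- .col_standardize(X, constant = "error")
  ys <- .zscore(y)
  if (!is.null(perm_orders)) {
    perm_orders <- as.matrix(perm_orders)
    if (ncol(perm_orders) != length(y)) stop("perm_orders width must equal regions")
    n_perm <- nrow(perm_orders)
  }
  set.seed(derive_seed(seed, "pls_perm"))
  block <- 500L
  exceed <- 0L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    Yb <- vapply(seq_len(nb), function(b) {
      if (is.null(perm_orders)) ys[sample.int(length(ys))]
      else ys[perm_orders[done + b, ]]
    }, numeric(length(ys)))
    ve <- .pls1_varexp_block(Xs, Yb)
    exceed <- exceed + sum(ve >= obs - 1e-12)
    done <- done + nb
  }
  list(perm_p = (1 + exceed) / (n_perm + 1), varexp_obs = obs,
       n_perm = n_perm)
}

#' Bootstrap standard errors and z-scores of PLS1 gene weights
#'
#' Resamples regions with replacement, refits PLS1 on each replicate (with
#' standardization inside the replicate), aligns each replicate's weight
#' vector sign by the sign of its correlation with the original weights
#' (PLS weights are sign-indeterminate per replicate), and returns the
#' per-gene bootstrap SE and z = weight / SE.
#'
#' @inheritParams fit_pls1
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param max_redraw bound on redraws of degenerate replicates (constant
#'   response after resampling).
#' @return list with \code{boot_se}, \code{z} (both named per gene),
#'   \code{weights} (the original fit), \code{n_boot}.
#' @export
pls_bootstrap <- function(X, y, n_boot = 5000L, seed = 1L, max_redraw = 100L) {
  X <- as.matrix(X)
  fit <- fit_pls1(X, y)
  w0 <- fit$weights
  n <- nrow(X)
  set.seed(derive_seed(seed, "pls_boot"))
  W <- matrix(NA_real_, length(w0), n_boot)
  redraws <- 0L
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (stats::sd(yb) == 0) {
      redraws <- redraws + 1L
      if (redraws > max_redraw) {
        stop("pls_bootstrap: exceeded redraw bound for degenerate replicates")
      }
      next
    }
    Xb <- .col_standardize(X[idx, , drop = FALSE], constant = "zero")
    yb <- .zscore(yb)
    wb <- crossprod(Xb, yb)[, 1L]
    nw <- sqrt(sum(wb^2))
    if (nw == 0) {
      redraws <- redraws + 1L
      if (redraws > max_redraw) stop("pls_bootstrap: degenerate replicates")
      next
    }
    wb <- wb / nw
    al <- sum(wb * w0)
    if (al < 0) wb <- -wb
    W[, b] <- wb
    b <- b + 1L
  }
  if (redraws > 0L) {
    message("pls_bootstrap: redrew ", redraws, " degenerate replicate(s)")
  }
  boot_se <- apply(W, 1L, stats::sd)
  z <- w0 / boot_se
  names(boot_se) <- names(z) <- names(w0)
  list(boot_se = boot_se, z = z, weights = w0, n_boot = n_boot)
}

#' Select significant genes from bootstrap z-scores
#'
#' Two-sided normal p-values from the z-scores, BH-FDR correction, and a
#' split of the significant genes by weight sign into the PLS+ (positive
#' weight, higher expression tracking higher response) and PLS- lists.
#'
#' @param z per-gene z-scores (named).
#' @param weights per-gene PLS1 weights (same order).
#' @param alpha FDR threshold (default 0.05).
#' @return list with \code{pls_plus}, \code{pls_minus} (gene name vectors)
#'   and \code{table} (gene, weight, z, p, q, selected).
#' @export
select_genes <- function(z, weights, alpha = 0.05) {
  if (any(!is.finite(z))) stop("non-finite z-scores")
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  sel <- q < alpha
  genes <- if (!is.null(names(z))) names(z) else as.character(seq_along(z))
  tab <- data.frame(gene = genes, weight = as.numeric(weights),
                    z = as.numeric(z), p = p, q = q, selected = sel,
                    stringsAsFactors = FALSE)
  list(pls_plus = genes[sel & weights > 0],
       pls_minus = genes[sel & weights < 0],
       table = tab)
}

#' Full transcriptomic association of a regional t-map
#'
#' Convenience wrapper running the whole stage: differential-stability
#' filtering (when donor-level data are present), PLS1 fit, region
#' permutation test of variance explained, bootstrap z-scores, and BH-FDR
#' gene selection.
#'
#' @param expression an \code{sfc_expression} object (or a plain regions x
#'   genes matrix, in which case no DS filter is applied).
#' @param tmap regional t-vector over all atlas regions (0-based position =
#'   region id), or exactly over the expression regions.
#' @param ds_fraction DS fraction to retain (default 0.5).
#' @param n_perm,n_boot resampling sizes (defaults 5000).
#' @param alpha FDR threshold for gene selection.
#' @param seed integer seed.
#' @param perm_orders optional user-supplied permutation matrix (see
#'   [pls_perm_test()]).
#' @return list of class \code{sfc_pls_result} with \code{varexp},
#'   \code{perm_p}, \code{gene_table}, \code{pls_plus}, \code{pls_minus},
#'   \code{retained}, \code{n_perm}, \code{n_boot}, \code{scores}.
#' @export
transcriptomic_association <- function(expression, tmap, ds_fraction = 0.5,
                                       n_perm = 5000L, n_boot = 5000L,
                                       alpha = 0.05, seed = 1L,
                                       perm_orders = NULL) {
  if (inherits(expression, "sfc_expression")) {
    vals <- expression$values
    region_ids <- expression$region_ids
    donor <- expression$donor_values
  } else {
    vals <- as.matrix(expression)
    region_ids <- NULL
    donor <- NULL
  }
  y <- if (!is.null(region_ids) && length(tmap) != nrow(vals)) {
    if (max(region_ids) + 1L > length(tmap)) {
      stop("tmap shorter than the largest expression region id")
    }
    tmap[region_ids + 1L]
  } else {
    if (length(tmap) != nrow(vals)) stop("tmap length does not match expression")
    tmap
  }
  if (anyNA(y)) stop("t-map has missing values on expression regions")

  retained <- seq_len(ncol(vals))
  if (!is.null(donor) && ds_fraction < 1) {
    ds <- differential_stability(donor)
    retained <- filter_top_fraction(ds, ds_fraction)
  }
  X <- vals[, retained, drop = FALSE]

  fit <- fit_pls1(X, y)
  perm <- pls_perm_test(X, y, n_perm = n_perm, seed = seed,
                        perm_orders = perm_orders)
  boot <- pls_bootstrap(X, y, n_boot = n_boot, seed = seed)
  sel <- select_genes(boot$z, fit$weights, alpha = alpha)

  structure(list(varexp = fit$varexp, perm_p = perm$perm_p,
                 gene_table = sel$table, pls_plus = sel$pls_plus,
                 pls_minus = sel$pls_minus, retained = retained,
                 scores = fit$scores, n_perm = n_perm, n_boot = n_boot,
                 alpha = alpha, seed = seed),
            class = "sfc_pls_result")
}

#' @export
print.sfc_pls_result <- function(x, ...) {
  cat(sprintf("PLS1: %.2f%% of response variance explained (perm p = %.4g, %d perms)\n",
              100 * x$varexp, x$perm_p, x$n_perm))
  cat(sprintf("  %d genes retained after DS filter; %d significant at q < %.2g (%d PLS+, %d PLS-)\n",
              length(x$retained), sum(x$gene_table$selected), x$alpha,
              length(x$pls_plus), length(x$pls_minus)))
  invisible(x)
}
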