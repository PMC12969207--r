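#' Fisher z-transform of correlation coefficients
#'
#' Variance-stabilizing \code{atanh} transform applied to Pearson
#' correlations before they enter the coupling statistic.
#'
#' @param r numeric vector of correlations with \code{|r| < 1}.
#' @param clip when TRUE, values are truncated to \code{+/- clip_bound}
#'   instead of raising an error at \code{|r| >= 1}. Off by default so that
#'   degenerate inputs fail loudly.
#' @param clip_bound truncation bound used when \code{clip} is on.
#' @return numeric vector of z-values.
#' @export
fisher_z <- function(r, clip = FALSE, clip_bound = 1 - 1e-7) {
  if (any(!is.finite(r))) stop("fisher_z: non-finite correlation values")
  if (clip) r <- pmin(pmax(r, -clip_bound), clip_bound)
  if (any(abs(r) >= 1)) {
    stop("fisher_z: |r| >= 1; set clip = TRUE to truncate at the bound")
  }
  atanh(r)
}

#' Functional connectivity matrix from regional time series
#'
#' Pearson correlation between every pair of regional time series, Fisher
#' z-transformed. The diagonal is defined as 0 by convention.
#'
#' @param ts timepoints x regions numeric matrix; at least two timepoints, no
#'   missing values, no zero-variance column.
#' @param clip passed to [fisher_z()]; allows perfectly (anti)correlated
#'   columns to be truncated rather than rejected.
#' @return regions x regions symmetric z-matrix of class \code{sfc_fc}.
#' @export
compute_fc <- function(ts, clip = FALSE) {
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("compute_fc: need at least 2 timepoints")
  if (any(!is.finite(ts))) stop("compute_fc: time series contain missing/non-finite values")
  v <- apply(ts, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    lab <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("compute_fc: zero-variance time series for region(s) ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  r <- stats::cor(ts)
  z <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  off <- row(r) != col(r)
  z[off] <- fisher_z(r[off], clip = clip)
  z <- (z + t(z)) / 2   # guard against asymmetric rounding
  class(z) <- c("sfc_fc", class(z))
  z
}

#' Regional structure-function coupling
#'
#' Pearson correlation between one region's structural connectivity profile
#' (fiber counts to all structurally connected partners, optionally
#' \code{log(1 + count)} transformed) and its functional connectivity profile
#' (Fisher-z values to the same partners). Only partners with a nonzero fiber
#' count enter the correlation; regions with fewer than \code{min_edges} such
#' partners get a missing value.
#'
#' @param fc regions x regions Fisher-z FC matrix.
#' @param sc regions x regions nonnegative fiber-count matrix.
#' @param region 1-based matrix index of the region.
#' @param min_edges minimum number of structurally connected partners
#'   (default 3; below that a correlation is meaningless).
#' @param log_transform apply \code{log1p} to the fiber counts (default TRUE).
#' @return the regional SFC value in [-1, 1], or NA.
#' @export
regional_coupling <- function(fc, sc, region, min_edges = 3L,
                              log_transform = TRUE) {
  .check_square_symmetric(sc, "sc")
  if (!all(dim(fc) == dim(sc))) stop("fc and sc dimensions differ")
  if (min_edges < 3L) stop("min_edges must be >= 3")
  n <- nrow(sc)
  if (region < 1L || region > n) stop("region index out of range")
  e <- setdiff(which(sc[region, ] > 0), region)
  if (length(e) < min_edges) return(NA_real_)
  x <- sc[region, e]
  if (log_transform) x <- log1p(x)
  y <- fc[region, e]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("regional_coupling: zero-variance profile at region ", region,
            "; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Structure-function coupling at regional, network and whole-brain level
#'
#' The regional level applies [regional_coupling()] to every region. The
#' network-block level pools, for every unordered pair of networks (a, b),
#' all region pairs (i in a, j in b, i != j) with a nonzero fiber count and
#' correlates their (transformed) fiber counts with their FC z-values; the
#' whole-brain level does the same over all structurally connected pairs.
#'
#' @inheritParams regional_coupling
#' @param atlas an \code{sfc_atlas} matching the matrices.
#' @return an object of class \code{sfc_coupling}: list with \code{regional}
#'   (named numeric), \code{n_edges}, \code{network_block} (symmetric
#'   networks x networks matrix), \code{whole_brain} (scalar).
#' @export
subject_coupling <- function(fc, sc, atlas, min_edges = 3L,
                             log_transform = TRUE) {
  .check_atlas(atlas)
  .check_square_symmetric(sc, "sc")
  n <- nrow(sc)
  if (nrow(atlas) != n) stop("atlas size does not match matrices")

  regional <- vapply(seq_len(n), function(i) {
    regional_coupling(fc, sc, i, min_edges = min_edges,
                      log_transform = log_transform)
  }, numeric(1))
  n_edges <- vapply(seq_len(n), function(i) {
    sum(sc[i, -i] > 0)
  }, integer(1))
  names(regional) <- names(n_edges) <- atlas$region_name

  x_all <- if (log_transform) log1p(sc) else sc
  ut <- upper.tri(sc)
  mask <- ut & sc > 0
  idx <- which(mask, arr.ind = TRUE)
  xv <- x_all[mask]
  yv <- fc[mask]

  net <- atlas$network_id + 1L
  nets <- sort(unique(net))
  K <- length(nets)
  net_names <- atlas$network_name[match(nets, net)]
  block <- matrix(NA_real_, K, K, dimnames = list(net_names, net_names))
  a <- pmin(net[idx[, 1L]], net[idx[, 2L]])
  b <- pmax(net[idx[, 1L]], net[idx[, 2L]])
  for (i in seq_len(K)) {
    for (j in i:K) {
      sel <- a == nets[i] & b == nets[j]
      if (sum(sel) >= min_edges &&
          stats::sd(xv[sel]) > 0 && stats::sd(yv[sel]) > 0) {
        block[i, j] <- block[j, i] <- stats::cor(xv[sel], yv[sel])
      } else {
        message("subject_coupling: network block ", net_names[i], "-",
                net_names[j], " has too few qualifying pairs; set missing")
      }
    }
  }

  whole <- if (length(xv) >= min_edges && stats::sd(xv) > 0 && stats::sd(yv) > 0) {
    stats::cor(xv, yv)
  } else {
    NA_real_
  }

  structure(list(regional = regional, n_edges = n_edges,
                 network_block = block, whole_brain = whole),
            class = "sfc_coupling")
}

#' @export
print.sfc_coupling <- function(x, ...) {
  cat("Structure-function coupling:", length(x$regional), "regions,",
      nrow(x$network_block), "networks\n")
  cat("  whole-brain SFC:", format(x$whole_brain, digits = 3), "\n")
  cat("  regional SFC: median", format(stats::median(x$regional, na.rm = TRUE),
                                       digits = 3),
      "(", sum(is.na(x$regional)), "missing )\n")
  invisible(x)
}
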