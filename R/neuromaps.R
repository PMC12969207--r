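## Spatial correlation of the unthresholded regional t-map with
## receptor/transporter density maps (JuSpace-style), with uniform
## region-label permutation p-values and BH-FDR across the map family.

#' Spatial Spearman correlation between two regional vectors
#'
#' Spearman rank correlation (average ranks for ties). A constant input
#' yields NA with a warning.
#'
#' @param tmap regional statistic vector.
#' @param map regional density vector on the same regions (>= 3).
#' @return Spearman's rho, or NA.
#' @export
spatial_spearman <- function(tmap, map) {
  if (length(tmap) != length(map)) stop("vectors differ in length")
  if (length(tmap) < 3L) stop("need at least 3 regions")
  if (anyNA(tmap) || anyNA(map)) stop("missing values in input vectors")
  if (stats::sd(tmap) == 0 || stats::sd(map) == 0) {
    warning("spatial_spearman: constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(tmap, map, method = "spearman")
}

#' Permutation p-value for a spatial Spearman correlation
#'
#' Permutes the region labels of the t-map \code{n_perm} times and returns
#' the two-sided add-one p-value
#' \code{(1 + #\{|rho_perm| >= |rho_obs|\}) / (n_perm + 1)}.
#'
#' @inheritParams spatial_spearman
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param perm_orders optional n_perm x regions matrix of permutation
#'   indices (e.g. spin-test orderings) used instead of uniform draws.
#' @return list with \code{rho}, \code{perm_p}, \code{n_perm}.
#' @export
permutation_p <- function(tmap, map, n_perm = 5000L, seed = 1L,
                          perm_orders = NULL) {
  rho <- spatial_spearman(tmap, map)
  if (is.na(rho)) return(list(rho = NA_real_, perm_p = NA_real_, n_perm = n_perm))
  n <- length(tmap)
  rt <- .zscore(rank(tmap))
  rm_ <- .zscore(rank(map))
  if (!is.null(perm_orders)) {
    perm_orders <- as.matrix(perm_orders)
    if (ncol(perm_orders) != n) stop("perm_orders width must equal regions")
    n_perm <- nrow(perm_orders)
    P <- t(apply(perm_orders, 1L, function(o) rt[o]))
  } else {
    set.seed(derive_seed(seed, "neuromap_perm"))
    P <- t(vapply(seq_len(n_perm), function(b) rt[sample.int(n)], numeric(n)))
  }
  rho_perm <- as.numeric(P %*% rm_) / (n - 1L)
  exceed <- sum(abs(rho_perm) >= abs(rho) - 1e-12)
  list(rho = rho, perm_p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Correlate a t-map with every receptor map, with permutation FDR
#'
#' Per-map Spearman rho and permutation p (one shared permutation stream
#' across maps, so the family is tested against a common null), BH-FDR
#' across the map family, and a significance flag at q < alpha.
#'
#' @param tmap unthresholded regional t-vector.
#' @param maps regions x maps matrix (e.g. from [gen_receptor_maps()] or
#'   [read_receptor_maps()]).
#' @param n_perm permutations per map.
#' @param seed integer seed.
#' @param alpha FDR threshold for the significance flag.
#' @param perm_orders optional permutation matrix (see [permutation_p()]).
#' @return data.frame of class \code{sfc_neuromap_result}: map, rho, perm_p,
#'   q, significant — one row per input map.
#' @export
correlate_all_maps <- function(tmap, maps, n_perm = 5000L, seed = 1L,
                               alpha = 0.05, perm_orders = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) != length(tmap)) stop("maps and tmap region counts differ")
  n <- length(tmap)
  map_names <- if (!is.null(colnames(maps))) colnames(maps) else
    sprintf("map%02d", seq_len(ncol(maps)))

  rho <- vapply(seq_len(ncol(maps)), function(k) {
    suppressWarnings(spatial_spearman(tmap, maps[, k]))
  }, numeric(1))

  rt <- .zscore(rank(tmap))
  M <- apply(maps, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(NA_real_, n) else .zscore(rank(v))
  })
  if (!is.null(perm_orders)) {
    perm_orders <- as.matrix(perm_orders)
    if (ncol(perm_orders) != n) stop("perm_orders width must equal regions")
    n_perm <- nrow(perm_orders)
    P <- t(apply(perm_orders, 1L, function(o) rt[o]))
  } else {
    set.seed(derive_seed(seed, "neuromap_perm"))
    P <- t(vapply(seq_len(n_perm), function(b) rt[sample.int(n)], numeric(n)))
  }
  rho_perm <- (P %*% M) / (n - 1L)          # n_perm x maps
  perm_p <- vapply(seq_len(ncol(maps)), function(k) {
    if (is.na(rho[k])) return(NA_real_)
    (1 + sum(abs(rho_perm[, k]) >= abs(rho[k]) - 1e-12)) / (n_perm + 1)
  }, numeric(1))

  out <- data.frame(map = map_names, rho = rho, perm_p = perm_p,
                    q = stats::p.adjust(perm_p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$q) & out$q < alpha
  class(out) <- c("sfc_neuromap_result", "data.frame")
  out
}
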