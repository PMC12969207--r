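#' Derive a reproducible substream seed from a master seed and a label
#'
#' Every stochastic component of the package draws its seed through this
#' splitter so that independent stages (structural backbone, subject noise,
#' permutations, bootstraps, ...) consume independent, reproducible streams.
#' The hash is a 31-bit multiplicative string hash; collisions between the
#' short internal labels are not a practical concern.
#'
#' @param master integer master seed.
#' @param label character scalar naming the substream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(abs(master) %% 2147483647)
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## trapezoidal rule; used for AUC over the sparsity sweep
trapz <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

## column-standardize a matrix; constant columns either error or are zeroed
.col_standardize <- function(X, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    if (constant == "error") {
      stop("constant column(s): ", paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    s[bad] <- 1
  }
  Xs <- sweep(Xc, 2L, s, "/")
  if (any(bad)) Xs[, bad] <- 0
  Xs
}

## symmetric check with tolerance
.check_square_symmetric <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(name, " must be a square matrix")
  }
  if (max(abs(m - t(m))) > 1e-8) stop(name, " must be symmetric")
  invisible(TRUE)
}
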