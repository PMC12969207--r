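## Covariate-adjusted two-group inference on coupling outcomes.
##
## The group contrast is a single ordinary-least-squares model
##   outcome ~ intercept + group(patient = 1) + age + education + fd +
##             handedness(left = 1)
## (ANCOVA-style), not residualize-then-test; the two agree when group is
## orthogonal to the covariates, and the joint model avoids bias when it is
## not.

.design_matrix <- function(meta) {
  need <- c("group", "age", "education", "fd", "handedness")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta is missing columns: ", paste(miss, collapse = ", "))
  if (!all(meta$group %in% c("patient", "control"))) {
    stop("unknown group labels: ",
         paste(unique(setdiff(meta$group, c("patient", "control"))), collapse = ", "))
  }
  if (anyNA(meta[need])) stop("missing covariate values in meta")
  cbind(intercept = 1,
        group = as.integer(meta$group == "patient"),
        age = as.numeric(meta$age),
        education = as.numeric(meta$education),
        fd = as.numeric(meta$fd),
        left_handed = as.integer(meta$handedness == "left"))
}

.check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qrX
}

## vectorized OLS group t for a complete outcome matrix Y (subjects x units)
.glm_group_t_mat <- function(Y, X) {
  qrX <- .check_design(X)
  df <- nrow(X) - ncol(X)
  if (df < 1L) stop("not enough subjects for the covariate model")
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  s2 <- colSums(res^2) / df
  ## chol2inv of R gives (X'X)^-1 in pivoted column order; locate group
  XtXinv <- chol2inv(qr.R(qrX))
  gpos <- which(qrX$pivot == 2L)
  se <- sqrt(s2 * XtXinv[gpos, gpos])
  tval <- coefs[2L, ] / se
  list(t = as.numeric(tval), df = df,
       p_unc = 2 * stats::pt(-abs(as.numeric(tval)), df))
}

#' Covariate-adjusted group contrast for one outcome
#'
#' OLS of the outcome on intercept, group indicator (patient = 1), age,
#' education, mean framewise displacement and a handedness indicator
#' (left = 1). Returns the t-statistic of the group coefficient with
#' \code{df = n - 6} residual degrees of freedom and a two-sided p-value.
#' Subjects with a missing outcome are dropped pairwise (with a message).
#'
#' @param values numeric per-subject outcome (may contain NA).
#' @param meta subjects table with columns \code{group}, \code{age},
#'   \code{education}, \code{fd}, \code{handedness}.
#' @return list with \code{t}, \code{df}, \code{p_unc}, \code{n}.
#' @export
group_glm_t <- function(values, meta) {
  if (length(values) != nrow(meta)) stop("values and meta sizes differ")
  keep <- !is.na(values)
  if (!all(keep)) {
    message("group_glm_t: dropping ", sum(!keep),
            " subject(s) with missing outcome")
  }
  v <- values[keep]
  m <- meta[keep, , drop = FALSE]
  if (min(table(factor(m$group, levels = c("patient", "control")))) < 2L) {
    stop("need at least 2 subjects per group")
  }
  if (stats::sd(v) == 0) stop("outcome has zero variance")
  X <- .design_matrix(m)
  out <- .glm_group_t_mat(matrix(v, ncol = 1L), X)
  list(t = out$t, df = out$df, p_unc = out$p_unc, n = length(v))
}

#' Bonferroni correction
#'
#' Elementwise \code{min(1, p * n_tests)}. The family size defaults to the
#' vector length but can be set explicitly (the pipeline corrects each
#' analysis level as its own family).
#'
#' @param p_unc vector of uncorrected p-values in [0, 1].
#' @param n_tests family size.
#' @return corrected p-values.
#' @export
bonferroni <- function(p_unc, n_tests = length(p_unc)) {
  if (any(p_unc < 0 | p_unc > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  pmin(1, p_unc * n_tests)
}

.statmap <- function(unit, level, res_list, n_tests = length(res_list)) {
  df <- data.frame(level = level, unit = unit,
                   t = vapply(res_list, `[[`, numeric(1), "t"),
                   df = vapply(res_list, `[[`, numeric(1), "df"),
                   p_unc = vapply(res_list, `[[`, numeric(1), "p_unc"),
                   stringsAsFactors = FALSE)
  df$p_corr <- bonferroni(df$p_unc, n_tests)
  df$n_tests <- n_tests
  class(df) <- c("sfc_statmap", "data.frame")
  df
}

#' Group contrast of coupling at whole-brain, network and regional level
#'
#' Applies [group_glm_t()] to the whole-brain scalar (correction family 1),
#' to every unique network block (family = number of testable blocks, 28 for
#' seven networks), and to every region (family = number of testable
#' regions). Units with all-missing coupling, zero variance, or fewer than 2
#' subjects per group after missing-value removal are excluded and the family
#' size reduced, with a message.
#'
#' @param couplings list of \code{sfc_coupling} objects, one per subject, in
#'   the row order of \code{meta}.
#' @param meta subjects table (see [group_glm_t()]).
#' @return list of class \code{sfc_group_stats} with \code{whole_brain},
#'   \code{network}, \code{regional} stat tables (columns: level, unit, t,
#'   df, p_unc, p_corr, n_tests).
#' @export
group_contrast_all_levels <- function(couplings, meta) {
  stopifnot(length(couplings) == nrow(meta))
  X_full <- .design_matrix(meta)

  fit_units <- function(Y, level) {
    ## Y: subjects x units (may contain NA); returns statmap over testable units
    units <- colnames(Y)
    res <- vector("list", ncol(Y))
    ok <- logical(ncol(Y))
    complete <- logical(ncol(Y))
    for (k in seq_len(ncol(Y))) {
      y <- Y[, k]
      keep <- !is.na(y)
      enough <- sum(keep & meta$group == "patient") >= 2L &&
        sum(keep & meta$group == "control") >= 2L
      if (!enough || stats::sd(y[keep]) == 0) {
        next
      }
      if (all(keep)) {
        complete[k] <- TRUE   # fit vectorized below
      } else {
        r <- .glm_group_t_mat(matrix(y[keep], ncol = 1L),
                              X_full[keep, , drop = FALSE])
        res[[k]] <- list(t = r$t, df = r$df, p_unc = r$p_unc)
      }
      ok[k] <- TRUE
    }
    if (any(complete)) {
      r <- .glm_group_t_mat(Y[, complete, drop = FALSE], X_full)
      ci <- which(complete)
      for (j in seq_along(ci)) {
        res[[ci[j]]] <- list(t = r$t[j], df = r$df, p_unc = r$p_unc[j])
      }
    }
    if (any(!ok)) {
      message("group_contrast_all_levels: excluded ", sum(!ok), " ", level,
              " unit(s) with insufficient data; family reduced to ", sum(ok))
    }
    .statmap(units[ok], level, res[ok], n_tests = sum(ok))
  }

  wb <- matrix(vapply(couplings, `[[`, numeric(1), "whole_brain"), ncol = 1L,
               dimnames = list(NULL, "whole_brain"))

  K <- nrow(couplings[[1L]]$network_block)
  bn <- rownames(couplings[[1L]]$network_block)
  pairs <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  net <- vapply(couplings, function(cp) {
    cp$network_block[cbind(pairs[, 1L], pairs[, 2L])]
  }, numeric(nrow(pairs)))
  net <- t(matrix(net, nrow = nrow(pairs)))
  colnames(net) <- paste(bn[pairs[, 1L]], bn[pairs[, 2L]], sep = "-")

  reg <- t(vapply(couplings, `[[`, numeric(length(couplings[[1L]]$regional)),
                  "regional"))
  colnames(reg) <- names(couplings[[1L]]$regional)

  structure(list(whole_brain = fit_units(wb, "whole_brain"),
                 network = fit_units(net, "network"),
                 regional = fit_units(reg, "regional")),
            class = "sfc_group_stats")
}

#' @export
print.sfc_group_stats <- function(x, ...) {
  cat("Group contrast (patient - control), covariate-adjusted\n")
  cat(sprintf("  whole-brain: t = %.3f, p = %.3f\n",
              x$whole_brain$t[1], x$whole_brain$p_unc[1]))
  for (lev in c("network", "regional")) {
    tab <- x[[lev]]
    cat(sprintf("  %s: %d tests, %d with p_unc < 0.05, %d Bonferroni-significant\n",
                lev, nrow(tab), sum(tab$p_unc < 0.05),
                sum(tab$p_corr < 0.05)))
  }
  invisible(x)
}

#' Pearson correlations between coupling and clinical scores
#'
#' Pairwise-complete Pearson correlation and two-sided p-value for every
#' (coupling unit, clinical score) cell, computed within the patient group by
#' default. Cells with fewer than 3 complete pairs are reported missing.
#' Mirrors the usual reporting at uncorrected p < 0.05; \code{fdr = TRUE}
#' appends BH-FDR q-values across all cells for stricter use.
#'
#' @param values subjects x units matrix (or data.frame) of coupling values,
#'   rows aligned with \code{meta}.
#' @param meta subjects table carrying the score columns.
#' @param scores character vector of score column names; defaults to every
#'   known clinical scale present in \code{meta}.
#' @param patients_only restrict to the patient group (default TRUE).
#' @param fdr append BH-FDR q-values.
#' @return data.frame with columns unit, score, n, r, p (and q).
#' @export
clinical_correlations <- function(values, meta, scores = NULL,
                                  patients_only = TRUE, fdr = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(meta))
  if (is.null(scores)) {
    scores <- intersect(c(names(.score_defs), "ybocs_total"), names(meta))
  }
  if (!length(scores)) stop("no score columns found in meta")
  keep <- if (patients_only) meta$group == "patient" else rep(TRUE, nrow(meta))
  v <- values[keep, , drop = FALSE]
  m <- meta[keep, , drop = FALSE]
  out <- expand.grid(unit = colnames(values), score = scores,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$r <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- v[, out$unit[i]]
    y <- m[[out$score[i]]]
    cc <- stats::complete.cases(x, y)
    out$n[i] <- sum(cc)
    if (sum(cc) < 3L || stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) next
    ct <- stats::cor.test(x[cc], y[cc], method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  if (fdr) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
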