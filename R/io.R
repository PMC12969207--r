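## Delimited-text I/O. All on-disk tables are tab-separated with a header
## row; region ids are 0-based in every file (the matrix headers are
## "r000", "r001", ... and atlas tables carry the numeric id). R-level
## matrix indices remain 1-based; the readers/writers own the mapping.

.region_header <- function(n) sprintf("r%03d", seq_len(n) - 1L)

#' Write / read a square regional matrix as TSV
#'
#' First row is the 0-based region-id header; values are written with full
#' precision so reruns are byte-identical.
#'
#' @param m square numeric matrix.
#' @param path file path.
#' @return (reader) the matrix with region-id dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(unclass(m))
  colnames(m) <- .region_header(ncol(m))
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}

#' Write / read a time-series matrix (timepoints x regions) as TSV
#' @param ts timepoints x regions matrix.
#' @param path file path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  ts <- as.matrix(ts)
  colnames(ts) <- .region_header(ncol(ts))
  utils::write.table(format(ts, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write / read an atlas table
#' @param atlas an \code{sfc_atlas}.
#' @param path file path.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  .check_atlas(atlas)
  class(atlas) <- c("sfc_atlas", "data.frame")
  atlas
}

#' Write / read the subjects table (group, covariates, clinical scores)
#' @param meta subjects data.frame.
#' @param path file path.
#' @export
write_subjects <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a regions x genes expression matrix (one file, or one per donor)
#'
#' Expression files are TSV with a \code{region_id} first column (0-based)
#' and one column per gene. With several donor files the per-donor stack is
#' kept so the differential-stability filter can run.
#'
#' @param paths character vector of one or more donor file paths.
#' @return an \code{sfc_expression} object.
#' @export
read_expression <- function(paths) {
  mats <- lapply(paths, function(p) {
    df <- utils::read.table(p, header = TRUE, sep = "\t", check.names = FALSE)
    if (names(df)[1L] != "region_id") {
      stop("expression file must start with a region_id column: ", p)
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- sprintf("r%03d", df$region_id)
    attr(m, "region_ids") <- as.integer(df$region_id)
    m
  })
  region_ids <- attr(mats[[1L]], "region_ids")
  for (m in mats) {
    if (!identical(attr(m, "region_ids"), region_ids) ||
        !identical(colnames(m), colnames(mats[[1L]]))) {
      stop("expression donor files disagree on regions or genes")
    }
  }
  donor <- if (length(mats) > 1L) {
    simplify2array(lapply(mats, function(m) unclass(m)))
  } else {
    NULL
  }
  values <- if (length(mats) > 1L) {
    apply(donor, c(1L, 2L), mean)
  } else {
    unclass(mats[[1L]])
  }
  structure(list(values = values, donor_values = donor,
                 gene_ids = colnames(mats[[1L]]), region_ids = region_ids),
            class = "sfc_expression")
}

#' Write an \code{sfc_expression} object (donor files + mean file)
#' @param expression an \code{sfc_expression}.
#' @param dir output directory.
#' @return character vector of donor file paths (the pipeline input).
#' @export
write_expression <- function(expression, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, path) {
    df <- data.frame(region_id = expression$region_ids, m,
                     check.names = FALSE)
    utils::write.table(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (!is.null(expression$donor_values)) {
    n_d <- dim(expression$donor_values)[3L]
    paths <- vapply(seq_len(n_d), function(d) {
      m <- expression$donor_values[, , d]
      colnames(m) <- expression$gene_ids
      wr(m, file.path(dir, sprintf("expression_donor%02d.tsv", d)))
    }, character(1))
  } else {
    m <- expression$values
    colnames(m) <- expression$gene_ids
    paths <- wr(m, file.path(dir, "expression.tsv"))
  }
  invisible(paths)
}

#' Read / write a receptor-map table (regions x maps, header = map names)
#' @param maps regions x maps matrix.
#' @param path file path.
#' @export
write_receptor_maps <- function(maps, path) {
  df <- data.frame(region_id = seq_len(nrow(maps)) - 1L,
                   unclass(maps), check.names = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_receptor_maps
#' @export
read_receptor_maps <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1L] != "region_id") {
    stop("receptor file must start with a region_id column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- sprintf("r%03d", df$region_id)
  attr(m, "region_ids") <- as.integer(df$region_id)
  m
}

#' Write a synthetic cohort to disk in the pipeline's input layout
#'
#' Produces \code{atlas.tsv}, \code{subjects.tsv}, \code{truth.tsv}, a
#' \code{timeseries/} and \code{sc/} directory with one TSV per subject,
#' expression donor files and \code{receptors.tsv} — the same delimited
#' formats [run_pipeline()] reads, so a generated cohort is
#' indistinguishable from a real one at the interface.
#'
#' @param cohort an \code{sfc_cohort} generated with \code{keep_ts = TRUE}.
#' @param dir output directory.
#' @return a [run_pipeline()]-ready paths list (invisibly).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sfc_cohort"))
  if (is.null(cohort$subjects[[1L]]$ts)) {
    stop("cohort was generated with keep_ts = FALSE; no time series to write")
  }
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "sc"), recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  write_subjects(cohort$meta, file.path(dir, "subjects.tsv"))
  utils::write.table(data.frame(group = rownames(cohort$truth),
                                cohort$truth, check.names = FALSE),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (s in cohort$subjects) {
    write_timeseries_tsv(s$ts, file.path(dir, "timeseries",
                                         paste0(s$subject_id, ".tsv")))
    write_matrix_tsv(s$sc, file.path(dir, "sc",
                                     paste0(s$subject_id, ".tsv")))
  }
  expr_paths <- write_expression(cohort$expression, dir)
  write_receptor_maps(cohort$receptors, file.path(dir, "receptors.tsv"))
  invisible(list(atlas = file.path(dir, "atlas.tsv"),
                 subjects = file.path(dir, "subjects.tsv"),
                 timeseries_dir = file.path(dir, "timeseries"),
                 sc_dir = file.path(dir, "sc"),
                 expression = expr_paths,
                 receptors = file.path(dir, "receptors.tsv")))
}
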