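## End-to-end orchestration: one config, staged execution
## (coupling -> group stats -> topology -> PLS -> neuromaps -> clinical),
## delimited-text outputs, JSON summaries and a run manifest.

#' Default analysis options for [run_pipeline()]
#'
#' @return named list of the tunable analysis options with their defaults:
#'   \code{min_edges} (3), \code{log_transform} (TRUE), \code{clip_fc}
#'   (FALSE; reject |r| = 1 loudly), \code{sparsities} (0.10-0.34 step
#'   0.01), \code{n_rand} (100), \code{topology} (TRUE), \code{n_perm} /
#'   \code{n_boot} (5000), \code{alpha} (0.05), \code{ds_fraction} (0.5),
#'   \code{clinical_patients_only} (TRUE), \code{clinical_fdr} (FALSE).
#' @export
default_options <- function() {
  list(min_edges = 3L, log_transform = TRUE, clip_fc = FALSE,
       sparsities = seq(0.10, 0.34, by = 0.01), n_rand = 100L,
       topology = TRUE, n_perm = 5000L, n_boot = 5000L, alpha = 0.05,
       ds_fraction = 0.5, clinical_patients_only = TRUE, clinical_fdr = FALSE)
}

#' Assemble a run configuration
#'
#' @param paths named list: \code{atlas}, \code{subjects},
#'   \code{timeseries_dir}, \code{sc_dir}, \code{expression} (one or more
#'   donor files), \code{receptors}, and \code{out_dir}.
#' @param options analysis options; unspecified entries take
#'   [default_options()].
#' @param seed master seed for every stochastic stage.
#' @return list of class \code{sfc_run_config}.
#' @export
run_config <- function(paths, options = list(), seed = 1L) {
  opts <- utils::modifyList(default_options(), options)
  structure(list(paths = paths, options = opts, seed = as.integer(seed)),
            class = "sfc_run_config")
}

#' Read a YAML run configuration
#'
#' The file holds the same three blocks as [run_config()]: \code{paths},
#' \code{options}, \code{seed}. Relative paths are resolved against the
#' file's directory.
#'
#' @param path YAML file.
#' @return an \code{sfc_run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    vapply(p, function(x) {
      if (grepl("^(/|[A-Za-z]:)", x)) x else file.path(base, x)
    }, character(1), USE.NAMES = FALSE)
  }
  y$paths <- lapply(y$paths, resolve)
  if (!is.null(y$options$sparsities) && length(y$options$sparsities) == 3L &&
      !is.null(names(y$options$sparsities))) {
    s <- y$options$sparsities
    y$options$sparsities <- seq(s[["from"]], s[["to"]], by = s[["by"]])
  }
  run_config(y$paths, y$options %||% list(), y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline inputs
#'
#' Checks path existence, atlas integrity, subject-file correspondence
#' (every subject needs both a time-series and an SC file), duplicate ids,
#' unknown group labels, missing covariates, matrix dimension agreement on a
#' sample of subjects, and expression/receptor region-id coverage. Hard
#' errors and warnings are distinguished.
#'
#' @param config an \code{sfc_run_config}.
#' @return data.frame of class \code{sfc_validation} with columns
#'   \code{severity} ("error"/"warning") and \code{message}; zero rows mean
#'   a clean configuration.
#' @export
validate_inputs <- function(config) {
  issues <- data.frame(severity = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(sev, msg) {
    issues <<- rbind(issues, data.frame(severity = sev, message = msg,
                                        stringsAsFactors = FALSE))
  }
  p <- config$paths
  for (nm in c("atlas", "subjects", "timeseries_dir", "sc_dir")) {
    if (is.null(p[[nm]]) || !file.exists(p[[nm]])) {
      add("error", paste0("missing path '", nm, "': ",
                          p[[nm]] %||% "<unset>"))
    }
  }
  if (nrow(issues[issues$severity == "error", , drop = FALSE]) > 0) {
    class(issues) <- c("sfc_validation", "data.frame")
    return(issues)
  }

  atlas <- tryCatch(read_atlas(p$atlas), error = function(e) {
    add("error", paste("atlas:", conditionMessage(e)))
    NULL
  })
  meta <- read_subjects(p$subjects)
  if (any(duplicated(meta$subject_id))) {
    add("error", paste("duplicate subject ids:",
                       paste(unique(meta$subject_id[duplicated(meta$subject_id)]),
                             collapse = ", ")))
  }
  bad_grp <- setdiff(unique(meta$group), c("patient", "control"))
  if (length(bad_grp)) {
    add("error", paste("unknown group labels:", paste(bad_grp, collapse = ", ")))
  }
  covs <- intersect(c("age", "education", "fd", "handedness"), names(meta))
  if (length(covs) < 4L) {
    add("error", paste("subjects table missing covariate columns:",
                       paste(setdiff(c("age", "education", "fd", "handedness"),
                                     covs), collapse = ", ")))
  } else if (anyNA(meta[covs])) {
    add("error", "missing covariate values for included subjects")
  }
  for (sid in meta$subject_id) {
    ts_f <- file.path(p$timeseries_dir, paste0(sid, ".tsv"))
    sc_f <- file.path(p$sc_dir, paste0(sid, ".tsv"))
    if (!file.exists(ts_f)) add("error", paste("subject", sid, "has no time-series file"))
    if (!file.exists(sc_f)) add("error", paste("subject", sid, "has no SC file"))
  }
  if (!is.null(atlas) && nrow(meta) > 0) {
    sid <- meta$subject_id[1L]
    ts_f <- file.path(p$timeseries_dir, paste0(sid, ".tsv"))
    sc_f <- file.path(p$sc_dir, paste0(sid, ".tsv"))
    if (file.exists(ts_f) && ncol(read_timeseries_tsv(ts_f)) != nrow(atlas)) {
      add("error", paste("time-series region count disagrees with atlas for", sid))
    }
    if (file.exists(sc_f) && nrow(read_matrix_tsv(sc_f)) != nrow(atlas)) {
      add("error", paste("SC region count disagrees with atlas for", sid))
    }
  }
  if (!is.null(p$expression) && !is.null(atlas)) {
    if (!all(file.exists(p$expression))) {
      add("error", "missing expression file(s)")
    } else {
      ex <- tryCatch(read_expression(p$expression), error = function(e) {
        add("error", paste("expression:", conditionMessage(e)))
        NULL
      })
      if (!is.null(ex) && length(setdiff(ex$region_ids, atlas$region_id))) {
        add("error", "expression file contains region ids absent from the atlas")
      }
    }
  } else if (is.null(p$expression)) {
    add("warning", "no expression input; transcriptomics stage will be skipped")
  }
  if (!is.null(p$receptors) && !is.null(atlas)) {
    if (!file.exists(p$receptors)) {
      add("error", "missing receptor-map file")
    } else {
      rc <- read_receptor_maps(p$receptors)
      if (length(setdiff(attr(rc, "region_ids"), atlas$region_id))) {
        add("error", "receptor file contains region ids absent from the atlas")
      }
    }
  } else if (is.null(p$receptors)) {
    add("warning", "no receptor input; neuromap stage will be skipped")
  }
  class(issues) <- c("sfc_validation", "data.frame")
  issues
}

#' @export
print.sfc_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation: clean\n")
  } else {
    for (i in seq_len(nrow(x))) cat(x$severity[i], ": ", x$message[i], "\n",
                                    sep = "")
  }
  invisible(x)
}

.write_statmap <- function(tab, path) {
  utils::write.table(format(as.data.frame(tab), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## FNV-1a hash of the serialized config, for the manifest
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config[c("paths", "options", "seed")],
                        auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (ch in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), ch) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes coupling, group statistics, topology, transcriptomics, neuromap
#' and clinical-correlation stages in order on the inputs named by the
#' config, writing delimited-text stat tables, JSON summaries and a run
#' manifest to \code{paths$out_dir}. A stage failure halts downstream stages
#' and is recorded in the manifest. Reruns with an identical config and seed
#' reproduce byte-identical stat tables.
#'
#' @param config an \code{sfc_run_config} (or a YAML path).
#' @param verbose print stage progress.
#' @return the manifest list (invisibly): config hash, seed, stage statuses,
#'   output file registry, warnings.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "sfc_run_config"))
  p <- config$paths
  opts <- config$options
  out <- p$out_dir
  if (is.null(out)) stop("config$paths$out_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_file, append = TRUE)
    if (verbose) message(msg)
  }

  issues <- validate_inputs(config)
  for (i in which(issues$severity == "warning")) say("WARNING: ", issues$message[i])
  if (any(issues$severity == "error")) {
    stop("input validation failed:\n  ",
         paste(issues$message[issues$severity == "error"], collapse = "\n  "))
  }

  manifest <- list(config_hash = .config_hash(config), seed = config$seed,
                   stages = list(), files = character(0),
                   warnings = issues$message[issues$severity == "warning"])
  reg <- function(f) manifest$files <<- c(manifest$files, f)
  stage <- function(name, expr) {
    say("stage ", name, " ...")
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      say("stage ", name, " FAILED: ", conditionMessage(res))
      FALSE
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      TRUE
    }
  }

  atlas <- read_atlas(p$atlas)
  meta <- read_subjects(p$subjects)
  couplings <- NULL
  stats_all <- NULL
  fcs <- NULL

  ok <- stage("coupling", {
    fcs <- vector("list", nrow(meta))
    couplings <- vector("list", nrow(meta))
    reg_tab <- NULL
    for (s in seq_len(nrow(meta))) {
      sid <- meta$subject_id[s]
      ts <- read_timeseries_tsv(file.path(p$timeseries_dir, paste0(sid, ".tsv")))
      sc <- read_matrix_tsv(file.path(p$sc_dir, paste0(sid, ".tsv")))
      fc <- compute_fc(ts, clip = opts$clip_fc)
      cp <- suppressMessages(
        subject_coupling(fc, sc, atlas, min_edges = opts$min_edges,
                         log_transform = opts$log_transform))
      fcs[[s]] <- unclass(fc)
      couplings[[s]] <- cp
      reg_tab <- rbind(reg_tab,
                       data.frame(subject_id = sid,
                                  region_id = atlas$region_id,
                                  sfc = as.numeric(cp$regional),
                                  n_edges = as.integer(cp$n_edges)))
    }
    f <- file.path(out, "coupling_regional.tsv")
    utils::write.table(format(reg_tab, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    reg(f)
    wb <- data.frame(subject_id = meta$subject_id,
                     whole_brain_sfc = vapply(couplings, `[[`, numeric(1),
                                              "whole_brain"))
    f <- file.path(out, "coupling_whole_brain.tsv")
    utils::write.table(format(wb, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    reg(f)
    TRUE
  })
  if (!ok) return(.finish_manifest(manifest, out))

  ok <- stage("group_stats", {
    stats_all <- suppressMessages(group_contrast_all_levels(couplings, meta))
    for (lev in c("whole_brain", "network", "regional")) {
      reg(.write_statmap(stats_all[[lev]],
                         file.path(out, paste0("stats_", lev, ".tsv"))))
    }
    TRUE
  })
  if (!ok) return(.finish_manifest(manifest, out))

  if (isTRUE(opts$topology)) {
    stage("topology", {
      topo <- suppressMessages(topology_group_contrast(
        fcs, meta, sparsities = opts$sparsities, n_rand = opts$n_rand,
        seed = derive_seed(config$seed, "topology")))
      for (lev in c("global", "nodal_degree", "nodal_efficiency")) {
        reg(.write_statmap(topo[[lev]],
                           file.path(out, paste0("topology_", lev, ".tsv"))))
      }
      TRUE
    })
  }

  tvec <- stats_all$regional$t
  names(tvec) <- stats_all$regional$unit
  ## unthresholded regional t-map in atlas order (NA where untestable)
  tmap <- rep(NA_real_, nrow(atlas))
  tmap[match(stats_all$regional$unit, atlas$region_name)] <- tvec

  if (!is.null(p$expression)) {
    stage("transcriptomics", {
      expr <- read_expression(p$expression)
      pls <- suppressMessages(transcriptomic_association(
        expr, tmap, ds_fraction = opts$ds_fraction, n_perm = opts$n_perm,
        n_boot = opts$n_boot, alpha = opts$alpha,
        seed = derive_seed(config$seed, "pls")))
      f <- file.path(out, "pls_genes.tsv")
      utils::write.table(format(pls$gene_table, digits = 15, trim = TRUE,
                                scientific = FALSE),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      reg(f)
      f <- file.path(out, "pls_summary.json")
      jsonlite::write_json(list(varexp = pls$varexp, perm_p = pls$perm_p,
                                n_perm = pls$n_perm, n_boot = pls$n_boot,
                                n_retained = length(pls$retained),
                                n_pls_plus = length(pls$pls_plus),
                                n_pls_minus = length(pls$pls_minus),
                                seed = derive_seed(config$seed, "pls")),
                           f, auto_unbox = TRUE, digits = NA)
      reg(f)
      TRUE
    })
  }

  if (!is.null(p$receptors)) {
    stage("neuromap", {
      maps <- read_receptor_maps(p$receptors)
      rid <- attr(maps, "region_ids")
      tm <- tmap[rid + 1L]
      keep <- !is.na(tm)
      nm <- correlate_all_maps(tm[keep], maps[keep, , drop = FALSE],
                               n_perm = opts$n_perm,
                               seed = derive_seed(config$seed, "neuromap"),
                               alpha = opts$alpha)
      reg(.write_statmap(nm, file.path(out, "neuromap_correlations.tsv")))
      TRUE
    })
  }

  stage("clinical", {
    sig <- stats_all$regional$unit[stats_all$regional$p_unc < opts$alpha]
    units <- if (length(sig)) sig else stats_all$regional$unit[
      order(abs(stats_all$regional$t), decreasing = TRUE)][1L]
    vals <- vapply(couplings, function(cp) cp$regional[units],
                   numeric(length(units)))
    vals <- matrix(vals, nrow = nrow(meta), byrow = TRUE,
                   dimnames = list(NULL, units))
    cc <- clinical_correlations(vals, meta,
                                patients_only = opts$clinical_patients_only,
                                fdr = opts$clinical_fdr)
    reg(.write_statmap(cc, file.path(out, "clinical_correlations.tsv")))
    TRUE
  })

  .finish_manifest(manifest, out)
}

.finish_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
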