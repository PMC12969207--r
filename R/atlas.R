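#' Generate a toy cortical parcellation
#'
#' Builds an atlas table in the style of a bihemispheric parcellation with a
#' small number of canonical networks (e.g. Schaefer-400 with the Yeo seven
#' networks): the first half of the regions is labelled hemisphere \code{L},
#' the second half \code{R}, and networks are assigned in contiguous blocks
#' within each hemisphere so that every network appears in both hemispheres.
#'
#' @param n_regions even number of regions.
#' @param n_networks number of networks, at most \code{n_regions / 2}.
#' @param seed integer seed (accepted for interface symmetry; the construction
#'   is deterministic).
#' @return a data.frame of class \code{sfc_atlas} with columns
#'   \code{region_id} (0-based), \code{region_name}, \code{hemisphere},
#'   \code{network_id} (0-based), \code{network_name}.
#' @examples
#' a <- gen_atlas(8, 2)
#' table(a$hemisphere, a$network_name)
#' @export
gen_atlas <- function(n_regions, n_networks, seed = 1L) {
  if (n_regions %% 2L != 0L) {
    stop("n_regions must be even (regions split into L/R hemispheres), got ",
         n_regions)
  }
  if (n_networks < 1L || n_networks > n_regions / 2L) {
    stop("n_networks must lie in [1, n_regions/2]")
  }
  half <- n_regions %/% 2L
  # contiguous network blocks within a hemisphere
  net_within <- floor(seq_len(half) * n_networks / half - 1e-9)
  net_names <- if (n_networks == 7L) {
    c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  } else {
    sprintf("net%d", seq_len(n_networks))
  }
  hemi <- rep(c("L", "R"), each = half)
  network_id <- c(net_within, net_within)
  atlas <- data.frame(
    region_id = 0:(n_regions - 1L),
    region_name = sprintf("%s_%s_%03d", hemi, net_names[network_id + 1L],
                          c(seq_len(half), seq_len(half))),
    hemisphere = hemi,
    network_id = as.integer(network_id),
    network_name = net_names[network_id + 1L],
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("sfc_atlas", "data.frame")
  atlas
}

.check_atlas <- function(atlas) {
  need <- c("region_id", "region_name", "hemisphere", "network_id", "network_name")
  if (!all(need %in% names(atlas))) {
    stop("atlas is missing columns: ",
         paste(setdiff(need, names(atlas)), collapse = ", "))
  }
  if (any(duplicated(atlas$region_id)) ||
      !identical(sort(atlas$region_id), 0:(nrow(atlas) - 1L))) {
    stop("atlas region_id must be the contiguous 0-based sequence")
  }
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop("atlas hemisphere labels must be 'L' or 'R'")
  }
  invisible(TRUE)
}
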