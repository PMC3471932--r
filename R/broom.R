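# Broom-style tidiers for the package's result objects.

#' Tidy a plate QC report
#'
#' @param x a `plate_qc`.
#' @param ... unused.
#' @return per-arm, per-parameter control KS summary tibble.
#' @method tidy plate_qc
#' @export
tidy.plate_qc <- function(x, ...) x$control_summary

#' @rdname tidy.plate_qc
#' @return [glance.plate_qc()]: one-row tibble with well counts, gate and
#'   Z'.
#' @method glance plate_qc
#' @export
glance.plate_qc <- function(x, ...) {
  ws <- x$well_stats
  tibble(
    n_wells = nrow(ws),
    n_excluded = nrow(x$excluded),
    n_pos = sum(ws$role == "positive_control"),
    n_neg = sum(ws$role == "negative_control"),
    gate = x$gate,
    z_prime = if (!is.null(x$zprime)) x$zprime$z_prime else NA_real_,
    viability_neg = x$viability_neg
  )
}

#' Tidy a classification
#'
#' @param x a `scrit_classification`.
#' @param ... unused.
#' @return per-item tibble: cluster, group and MDS coordinates.
#' @method tidy scrit_classification
#' @export
tidy.scrit_classification <- function(x, ...) {
  left_join(x$groups, x$mds, by = "item")
}

#' @rdname tidy.scrit_classification
#' @method glance scrit_classification
#' @export
glance.scrit_classification <- function(x, ...) {
  tibble(
    n_items = nrow(x$groups),
    n_compounds = length(unique(x$groups$compound)),
    n_clusters = length(unique(x$groups$cluster)),
    metric = x$config$metric,
    linkage = x$config$linkage,
    cut_k = x$config$k
  )
}

#' Tidy a secondary-screen result
#'
#' @param x a `secondary_screen`.
#' @param ... unused.
#' @return compound-level tibble: majority group, replicate count and
#'   consistency diagnostics.
#' @method tidy secondary_screen
#' @export
tidy.secondary_screen <- function(x, ...) {
  left_join(x$consistency$report,
            attr(x$classification$groups, "compound_groups"),
            by = "compound")
}

#' @rdname tidy.secondary_screen
#' @method glance secondary_screen
#' @export
glance.secondary_screen <- function(x, ...) {
  tibble(
    n_compounds = length(unique(x$scrit$compound)),
    n_outliers = sum(x$consistency$report$outlier),
    n_vectors = nrow(x$classification$groups),
    n_components = nrow(scrit_index_map(x$scrit)),
    config_hash = x$config_hash
  )
}
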