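# SCRIT vectors: ordered multifactorial response fingerprints
# (parameters x growth conditions x doses), one per compound replicate.

scrit_attrs <- c("index_map", "parameters", "conditions", "doses",
                 "control_viability")

set_scrit_attrs <- function(tbl, template = NULL, ...) {
  vals <- list(...)
  for (a in scrit_attrs) {
    attr(tbl, a) <- vals[[a]] %||% if (!is.null(template)) attr(template, a)
  }
  if (!inherits(tbl, "scrit_tbl")) class(tbl) <- c("scrit_tbl", class(tbl))
  tbl
}

#' SCRIT component index map
#'
#' @param scrit a `scrit_tbl`.
#' @return tibble with one row per vector component: `index`, `parameter`,
#'   `condition`, `dose`, `component` (the column name `param|cond|dose`).
#' @export
scrit_index_map <- function(scrit) attr(scrit, "index_map")

make_index_map <- function(parameters, conditions, doses) {
  im <- expand.grid(dose = sort(doses), condition = conditions,
                    parameter = parameters, stringsAsFactors = FALSE)
  im <- as_tibble(im[, c("parameter", "condition", "dose")])
  im$component <- paste(im$parameter, im$condition, signif(im$dose, 3),
                        sep = "|")
  im$index <- seq_len(nrow(im))
  im[, c("index", "parameter", "condition", "dose", "component")]
}

#' Assemble SCRIT response vectors from well statistics
#'
#' One vector per compound and biological replicate, in canonical component
#' order: parameter-major, then condition (glucose before galactose), then
#' dose ascending. KS parameters enter as signed KS values, `"viability"`
#' as the rescaled live fraction, so every component lies in \[-1, 1\].
#' Technical replicate wells of the same (compound, replicate, condition,
#' dose) cell are averaged into one statistic first. Vectors with any
#' missing dose-condition cell are excluded and listed in the
#' `"incomplete"` attribute with a reason.
#'
#' @param well_stats output of [well_statistics()], rows from one or more
#'   plates (must cover every condition requested).
#' @param parameters ordered parameter list; `"viability"` plus features
#'   named in the `ks_` columns. The standard designs are the 40-point
#'   (TMRM peripheral integral + viability), 60-point (+ Hoechst mean) and
#'   14-point single-dose 7-parameter vectors.
#' @param conditions conditions to include, in order.
#' @return a `scrit_tbl`: tibble with `compound`, `replicate`, then one
#'   column per component; attributes `index_map`, `parameters`,
#'   `conditions`, `doses`, `control_viability` (per-condition mean
#'   rescaled viability of negative-control wells).
#' @export
build_scrit <- function(well_stats,
                        parameters = c("tmrm_peripheral_integral",
                                       "viability"),
                        conditions = c("glu_plus", "glu_minus")) {
  assert_columns(well_stats, c("compound", "replicate", "condition", "dose",
                               "role", "excluded"), "well statistics")
  conditions <- intersect(conditions, unique(well_stats$condition))
  if (length(conditions) == 0) stop_contract("no requested condition present")
  stat_col <- function(p) {
    if (p == "viability") "viability_rescaled" else paste0("ks_", p)
  }
  assert_columns(well_stats, vapply(parameters, stat_col, character(1)),
                 "well statistics")
  ctrl <- well_stats[well_stats$role == "negative_control" &
                       !well_stats$excluded, ]
  control_viability <- vapply(setNames(nm = conditions), function(cc) {
    mean(ctrl$viability_rescaled[ctrl$condition == cc])
  }, numeric(1))
  ws <- well_stats[well_stats$role == "test" & !well_stats$excluded &
                     well_stats$condition %in% conditions, ]
  long <- bind_rows(lapply(parameters, function(p) {
    tibble(compound = ws$compound, replicate = ws$replicate,
           parameter = p, condition = ws$condition, dose = ws$dose,
           value = ws[[stat_col(p)]])
  }))
  cells <- long %>%
    group_by(.data$compound, .data$replicate, .data$parameter,
             .data$condition, .data$dose) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  doses <- sort(unique(cells$dose))
  im <- make_index_map(parameters, conditions, doses)
  n_comp <- nrow(im)
  vec <- cells %>%
    group_by(.data$compound, .data$replicate) %>%
    summarise(n_cells_present = n(), .groups = "drop")
  incomplete <- vec[vec$n_cells_present < n_comp, c("compound", "replicate")]
  if (nrow(incomplete) > 0) {
    incomplete$reason <- "missing dose x condition cell(s)"
    warn(sprintf("%d SCRIT vector(s) excluded as incomplete", nrow(incomplete)))
  }
  keep <- vec[vec$n_cells_present == n_comp, c("compound", "replicate")]
  cells <- left_join(keep, cells, by = c("compound", "replicate"))
  cells$component <- paste(cells$parameter, cells$condition,
                           signif(cells$dose, 3), sep = "|")
  wide <- tidyr::pivot_wider(
    cells[, c("compound", "replicate", "component", "value")],
    names_from = "component", values_from = "value")
  wide <- wide[order(wide$compound, wide$replicate),
               c("compound", "replicate", im$component)]
  out <- set_scrit_attrs(wide, index_map = im, parameters = parameters,
                         conditions = conditions, doses = doses,
                         control_viability = control_viability)
  attr(out, "incomplete") <- incomplete
  out
}

#' @export
print.scrit_tbl <- function(x, ...) {
  im <- scrit_index_map(x)
  cat(sprintf(
    "<scrit_tbl> %d vector(s), %d components (%d parameter(s) x %d condition(s) x %d dose(s))\n",
    nrow(x), nrow(im), length(attr(x, "parameters")),
    length(attr(x, "conditions")), length(attr(x, "doses"))))
  NextMethod()
}

#' Extract the numeric SCRIT matrix
#'
#' @param scrit a `scrit_tbl`.
#' @return numeric matrix, one row per vector, rownames
#'   `"compound:replicate"`.
#' @export
scrit_matrix <- function(scrit) {
  im <- scrit_index_map(scrit)
  m <- as.matrix(as_tibble(scrit)[, im$component])
  rownames(m) <- paste(scrit$compound, scrit$replicate, sep = ":")
  m
}

#' Truncate SCRIT vectors to a subset of components
#'
#' Filters components by parameter, condition and/or dose while preserving
#' canonical order; the index map is rebuilt to match. Truncating a
#' 60-dimensional vector to glucose-only data yields the 30-dimensional
#' variant used to show the loss of direct-toxicant resolution.
#'
#' @param scrit a `scrit_tbl`.
#' @param parameters,conditions,doses subsets to keep (`NULL` = keep all).
#' @return a `scrit_tbl` with the filtered components.
#' @export
truncate_scrit <- function(scrit, parameters = NULL, conditions = NULL,
                           doses = NULL) {
  im <- scrit_index_map(scrit)
  keep_p <- parameters %||% attr(scrit, "parameters")
  keep_c <- conditions %||% attr(scrit, "conditions")
  keep_d <- doses %||% attr(scrit, "doses")
  im2 <- im[im$parameter %in% keep_p & im$condition %in% keep_c &
              im$dose %in% keep_d, ]
  if (nrow(im2) == 0) stop_contract("truncation selects no components")
  im2$index <- seq_len(nrow(im2))
  out <- as_tibble(scrit)[, c("compound", "replicate", im2$component)]
  set_scrit_attrs(out, scrit,
                  index_map = im2,
                  parameters = intersect(attr(scrit, "parameters"), keep_p),
                  conditions = intersect(attr(scrit, "conditions"), keep_c),
                  doses = intersect(attr(scrit, "doses"), keep_d))
}

#' Primary-screen activity call
#'
#' Applies the 20% activity cut-off to single-dose 7-parameter SCRIT
#' vectors (7 parameters x 2 conditions = 14 components): a compound is
#' active when any KS component reaches `cutoff` in magnitude, or its
#' rescaled viability departs from the negative-control viability by at
#' least `2 * cutoff` (20 percentage points of live fraction). Inactive
#' compounds are designated group IV.
#'
#' @param scrit a single-dose `scrit_tbl` with 7 parameters and 2
#'   conditions.
#' @param cutoff activity threshold on the KS scale.
#' @param control_viability named per-condition rescaled viability of the
#'   negative controls; defaults to the value stored on the `scrit_tbl`,
#'   then to +1.
#' @return tibble: `compound`, `replicate`, `active`, `group` (`"IV"` for
#'   inactive rows), `triggers` (list column of component names at or
#'   beyond the cut-off).
#' @export
primary_screen_select <- function(scrit, cutoff = 0.2,
                                  control_viability = NULL) {
  im <- scrit_index_map(scrit)
  n_par <- length(unique(im$parameter))
  n_cond <- length(unique(im$condition))
  n_dose <- length(unique(im$dose))
  if (n_dose != 1 || n_cond != 2 || n_par != 7) {
    stop_contract(sprintf(
      "primary screen expects 7 parameters x 2 conditions x 1 dose, got %d x %d x %d",
      n_par, n_cond, n_dose))
  }
  ref <- control_viability %||% attr(scrit, "control_viability") %||%
    setNames(rep(1, n_cond), unique(im$condition))
  m <- scrit_matrix(scrit)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    dev <- vapply(seq_len(nrow(im)), function(j) {
      if (im$parameter[j] == "viability") {
        abs(m[i, j] - ref[[im$condition[j]]]) / 2
      } else {
        abs(m[i, j])
      }
    }, numeric(1))
    hit <- im$component[dev >= cutoff]
    tibble(compound = scrit$compound[i], replicate = scrit$replicate[i],
           active = length(hit) > 0,
           group = ifelse(length(hit) > 0, NA_character_, "IV"),
           triggers = list(hit))
  })
  bind_rows(rows)
}

#' Replicate-consistency filter
#'
#' Computes all pairwise Pearson distances between the replicate vectors of
#' each compound; any pair above `threshold` flags the whole compound as an
#' outlier and removes it entirely -- the disagreement taints the
#' compound, not just one vector. Compounds with a single replicate pass
#' with a warning.
#'
#' @param scrit a `scrit_tbl`.
#' @param threshold maximum tolerated pairwise Pearson distance.
#' @return list with `kept` (a `scrit_tbl` of retained vectors), `report`
#'   (per compound: `n_replicates`, `max_distance`, `outlier`) and `pairs`
#'   (every pairwise distance).
#' @export
replicate_consistency <- function(scrit, threshold = 0.2) {
  m <- scrit_matrix(scrit)
  pair_rows <- list()
  rep_rows <- list()
  for (cmp in unique(scrit$compound)) {
    idx <- which(scrit$compound == cmp)
    if (length(idx) < 2) {
      warn(sprintf("compound '%s' has a single replicate; kept unchecked",
                   cmp))
      rep_rows[[cmp]] <- tibble(compound = cmp, n_replicates = length(idx),
                                max_distance = NA_real_, outlier = FALSE)
      next
    }
    prs <- utils::combn(idx, 2)
    d <- vapply(seq_len(ncol(prs)), function(k) {
      pearson_distance(m[prs[1, k], ], m[prs[2, k], ])
    }, numeric(1))
    pair_rows[[cmp]] <- tibble(
      compound = cmp,
      replicate_a = scrit$replicate[prs[1, ]],
      replicate_b = scrit$replicate[prs[2, ]],
      distance = d)
    rep_rows[[cmp]] <- tibble(compound = cmp, n_replicates = length(idx),
                              max_distance = max(d),
                              outlier = max(d) > threshold)
  }
  report <- bind_rows(rep_rows)
  keep_cmp <- report$compound[!report$outlier]
  kept <- set_scrit_attrs(
    as_tibble(scrit)[scrit$compound %in% keep_cmp, ], scrit)
  list(kept = kept, report = report, pairs = bind_rows(pair_rows))
}

#' Read / write SCRIT tables
#'
#' Tab-separated text, one row per vector with `param|cond|dose` component
#' columns, plus a JSON sidecar (`<path>.json`) holding the index map and
#' vector metadata.
#'
#' @param scrit a `scrit_tbl`.
#' @param path TSV path.
#' @return `path` (write) or a `scrit_tbl` (read).
#' @export
write_scrit <- function(scrit, path) {
  readr::write_tsv(as_tibble(scrit), path, progress = FALSE)
  meta <- list(index_map = scrit_index_map(scrit),
               parameters = attr(scrit, "parameters"),
               conditions = attr(scrit, "conditions"),
               doses = attr(scrit, "doses"),
               control_viability = as.list(attr(scrit, "control_viability")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scrit
#' @export
read_scrit <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cv <- unlist(meta$control_viability)
  set_scrit_attrs(tbl,
                  index_map = as_tibble(meta$index_map),
                  parameters = meta$parameters,
                  conditions = meta$conditions,
                  doses = meta$doses,
                  control_viability = cv)
}
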