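# Plate layouts, dose series, well bookkeeping (96-well convention).

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' Well ids for an 8 x 12 plate
#'
#' Letter row (A-H) plus zero-padded column (01-12), e.g. `"A01"`, `"H12"`.
#'
#' @param rows,cols row letters and column numbers.
#' @return character vector of well ids, row-major.
#' @export
well_ids <- function(rows = PLATE_ROWS, cols = PLATE_COLS) {
  as.vector(t(outer(rows, sprintf("%02d", cols), paste0)))
}

new_plate_layout <- function(wells) {
  layout <- as_tibble(wells)
  assert_columns(layout, c("well", "row", "col", "compound", "dose",
                           "condition", "role", "replicate"), "plate layout")
  if (anyDuplicated(layout$well) > 0) {
    stop_config("duplicated well ids in layout")
  }
  bad_cond <- setdiff(unique(layout$condition), c("glu_plus", "glu_minus"))
  if (length(bad_cond) > 0) {
    stop_config(paste("unknown condition:", paste(bad_cond, collapse = ", ")))
  }
  if (any(layout$dose[layout$role == "negative_control"] != 0)) {
    stop_config("negative-control wells must have dose 0")
  }
  class(layout) <- c("plate_layout", class(layout))
  layout
}

#' Geometric dilution dose series
#'
#' Doses of a serial dilution: `top / ratio^(k - 1)` for `k = 1..n_points`,
#' returned in decreasing order. The default screen series is ten 1:3
#' dilutions from 100 uM, bottoming out at about 0.005 uM.
#'
#' @param top top dose in uM (> 0).
#' @param ratio dilution factor between consecutive doses (> 1).
#' @param n_points number of doses (>= 1).
#' @return numeric vector of doses in uM, strictly decreasing.
#' @examples
#' dose_series(100, 3, 10)
#' @export
dose_series <- function(top = 100, ratio = 3, n_points = 10) {
  if (!is.numeric(top) || length(top) != 1 || top <= 0) {
    stop_domain("`top` must be a single positive dose (uM)")
  }
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 1) {
    stop_domain("`ratio` must be a single dilution factor > 1")
  }
  if (n_points < 1) stop_domain("`n_points` must be >= 1")
  top / ratio^(seq_len(n_points) - 1)
}

#' Control plate layout (positive/negative columns)
#'
#' Whole-column control plate used for assay development and plate QC:
#' `n_cols_per_condition` columns of positive controls (FCCP, 75 uM by
#' default) and the same number of vehicle (DMSO) negative-control columns.
#' Negative columns fill from the left of the plate, positive columns from
#' the right; with 6 + 6 columns the full plate is used (48 wells per arm).
#'
#' @param n_cols_per_condition whole columns per control arm.
#' @param condition growth medium for the whole plate, `"glu_plus"` or
#'   `"glu_minus"`.
#' @param positive_dose dose (uM) recorded for positive-control wells.
#' @return A `plate_layout` tibble (one row per assigned well).
#' @examples
#' table(build_control_plate(6)$role)
#' @export
build_control_plate <- function(n_cols_per_condition = 6,
                                condition = "glu_plus",
                                positive_dose = 75) {
  k <- n_cols_per_condition
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop_config("`n_cols_per_condition` must be a positive integer")
  }
  if (2 * k > length(PLATE_COLS)) {
    stop_config(sprintf("2 x %d control columns exceed the %d plate columns",
                        k, length(PLATE_COLS)))
  }
  neg_cols <- seq_len(k)
  pos_cols <- rev(length(PLATE_COLS) - seq_len(k) + 1)
  grid <- expand.grid(row = PLATE_ROWS, col = c(neg_cols, pos_cols),
                      stringsAsFactors = FALSE)
  role <- ifelse(grid$col %in% neg_cols, "negative_control", "positive_control")
  new_plate_layout(tibble(
    well = paste0(grid$row, sprintf("%02d", grid$col)),
    row = grid$row, col = grid$col,
    compound = ifelse(role == "positive_control", "FCCP", "DMSO"),
    dose = ifelse(role == "positive_control", positive_dose, 0),
    condition = condition,
    role = role,
    replicate = 1L
  ))
}

#' Dose-response (secondary screen) plate layout
#'
#' Each compound occupies `n_replicates` full rows; each row carries the dose
#' series, lowest dose in column 1 and ascending rightward. Controls sit in
#' fixed columns after the dose block: one column of positive controls
#' (75 uM FCCP) then one of negative controls (DMSO), filled top-down. The
#' standard design - two repeats of ten 1:3 dilutions for four compounds
#' plus eight positive and eight negative controls - fills all 96 wells.
#'
#' @param compounds character vector of compound ids (one block of rows each).
#' @param series dose series from [dose_series()] (decreasing uM).
#' @param n_replicates replicate rows per compound on this plate.
#' @param n_pos,n_neg number of positive / negative control wells.
#' @param condition growth medium for the plate.
#' @param positive_dose dose (uM) of the positive control.
#' @param replicate_offset first replicate id on this plate (biological
#'   replicates 3-4 of a quadruplicate live on a second plate).
#' @return A `plate_layout` tibble.
#' @export
build_dose_response_plate <- function(compounds,
                                      series = dose_series(),
                                      n_replicates = 2,
                                      n_pos = 8, n_neg = 8,
                                      condition = "glu_plus",
                                      positive_dose = 75,
                                      replicate_offset = 1L) {
  n_used <- length(compounds) * n_replicates * length(series) + n_pos + n_neg
  if (n_used > 96) {
    stop_config(sprintf("layout needs %d wells but the plate has 96", n_used))
  }
  n_rows_needed <- length(compounds) * n_replicates
  if (n_rows_needed > length(PLATE_ROWS)) {
    stop_config(sprintf("%d compound x replicate rows exceed the 8 plate rows",
                        n_rows_needed))
  }
  n_ctrl_cols <- ceiling(n_pos / 8) + ceiling(n_neg / 8)
  if (length(series) + n_ctrl_cols > length(PLATE_COLS)) {
    stop_config("dose series plus control columns exceed the 12 plate columns")
  }
  doses_asc <- sort(series)
  test <- expand.grid(slot = seq_len(n_rows_needed),
                      dose_idx = seq_along(doses_asc))
  comp_of_slot <- rep(compounds, each = n_replicates)
  rep_of_slot <- rep(seq_len(n_replicates) + replicate_offset - 1L,
                     times = length(compounds))
  test_tbl <- tibble(
    row = PLATE_ROWS[test$slot],
    col = test$dose_idx,
    compound = comp_of_slot[test$slot],
    dose = doses_asc[test$dose_idx],
    condition = condition,
    role = "test",
    replicate = as.integer(rep_of_slot[test$slot])
  )
  pos_col0 <- length(doses_asc) + 1L
  ctrl <- function(n, col0, compound, dose, role) {
    if (n == 0) return(NULL)
    idx <- seq_len(n) - 1L
    tibble(
      row = PLATE_ROWS[idx %% 8 + 1], col = col0 + idx %/% 8,
      compound = compound, dose = dose, condition = condition,
      role = role, replicate = 1L
    )
  }
  pos_tbl <- ctrl(n_pos, pos_col0, "FCCP", positive_dose, "positive_control")
  neg_tbl <- ctrl(n_neg, pos_col0 + ceiling(n_pos / 8), "DMSO", 0,
                  "negative_control")
  layout <- bind_rows(test_tbl, pos_tbl, neg_tbl)
  layout$well <- paste0(layout$row, sprintf("%02d", layout$col))
  new_plate_layout(layout[, c("well", "row", "col", "compound", "dose",
                              "condition", "role", "replicate")])
}

#' Single-dose (primary screen) plate layout
#'
#' One well per compound at a single high dose (100 uM by default), filled
#' column-major from the top left. The last plate column carries four
#' positive (75 uM FCCP) and four negative (DMSO) controls.
#'
#' @param compounds compound ids, at most 88.
#' @param dose screening dose in uM.
#' @param condition growth medium for the plate.
#' @param replicate biological replicate id recorded for every test well.
#' @return A `plate_layout` tibble.
#' @export
build_single_dose_plate <- function(compounds, dose = 100,
                                    condition = "glu_plus",
                                    replicate = 1L) {
  if (length(compounds) > 88) {
    stop_config("a single-dose plate holds at most 88 compounds")
  }
  idx <- seq_along(compounds) - 1L
  test_tbl <- tibble(
    row = PLATE_ROWS[idx %% 8 + 1], col = idx %/% 8 + 1L,
    compound = compounds, dose = dose, condition = condition,
    role = "test", replicate = as.integer(replicate)
  )
  ctrl_tbl <- tibble(
    row = PLATE_ROWS,
    col = 12L,
    compound = rep(c("FCCP", "DMSO"), each = 4),
    dose = rep(c(75, 0), each = 4),
    condition = condition,
    role = rep(c("positive_control", "negative_control"), each = 4),
    replicate = 1L
  )
  layout <- bind_rows(test_tbl, ctrl_tbl)
  layout$well <- paste0(layout$row, sprintf("%02d", layout$col))
  new_plate_layout(layout[, c("well", "row", "col", "compound", "dose",
                              "condition", "role", "replicate")])
}

#' Validate screening-plate control content
#'
#' Screening plates must carry at least four negative and four positive
#' control wells; negative controls must be at dose 0.
#'
#' @param layout a `plate_layout`.
#' @return the layout, invisibly; errors otherwise.
#' @export
validate_screen_layout <- function(layout) {
  n_neg <- sum(layout$role == "negative_control")
  n_pos <- sum(layout$role == "positive_control")
  if (n_neg < 4 || n_pos < 4) {
    stop_config(sprintf(
      "screening plates need >= 4 controls per arm (found %d neg, %d pos)",
      n_neg, n_pos))
  }
  invisible(layout)
}

#' Read or write a plate layout
#'
#' Layouts are exchanged as delimited text (CSV) or YAML with one record per
#' well, mirroring the `plate_layout` columns.
#'
#' @param path file path; `.yaml`/`.yml` is parsed as YAML, anything else as
#'   comma-separated text.
#' @return [read_plate_layout()] returns a `plate_layout`;
#'   [write_plate_layout()] returns `path` invisibly.
#' @export
read_plate_layout <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    recs <- yaml::read_yaml(path)
    layout <- list_rbind(map(recs, as_tibble))
  } else {
    layout <- readr::read_csv(path, show_col_types = FALSE)
  }
  layout$replicate <- as.integer(layout$replicate %||% 1L)
  new_plate_layout(layout)
}

#' @rdname read_plate_layout
#' @param layout a `plate_layout`.
#' @export
write_plate_layout <- function(layout, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(purrr::transpose(as.list(as_tibble(layout))), path)
  } else {
    readr::write_csv(as_tibble(layout), path)
  }
  invisible(path)
}
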