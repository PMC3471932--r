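# Per-cell feature tables: schema, readers and writers.

#' Names of the seven measured per-cell features
#'
#' TMRM peripheral integral and max pixel intensity, Hoechst33342 integral
#' and mean intensity, nuclear area and circularity, and TO-PRO-3 mean
#' intensity -- the iCys outputs the screen is built on.
#'
#' @return character vector of column names.
#' @export
feature_names <- function() {
  c("tmrm_peripheral_integral", "tmrm_max_pixel",
    "hoechst_integral", "hoechst_mean",
    "nuclear_area", "nuclear_circularity",
    "topro_mean")
}

# id columns expected alongside the features
feature_id_cols <- function() c("well", "field", "cell")

#' Construct / validate a cell feature table
#'
#' One row per segmented cell; mandatory columns are the well, field and
#' cell ids plus the seven features of [feature_names()]. Extra columns are
#' preserved. Intensities must be non-negative and circularity in (0, 1].
#'
#' @param x a data frame.
#' @return a tibble with class `cell_features`.
#' @export
as_cell_features <- function(x) {
  tbl <- as_tibble(x)
  assert_columns(tbl, c(feature_id_cols(), feature_names()), "feature table")
  intens <- c("tmrm_peripheral_integral", "tmrm_max_pixel",
              "hoechst_integral", "hoechst_mean", "topro_mean")
  for (col in intens) {
    if (any(tbl[[col]] < 0, na.rm = TRUE)) {
      stop_format(sprintf("negative intensities in `%s`", col))
    }
  }
  circ <- tbl$nuclear_circularity
  if (any(circ <= 0 | circ > 1, na.rm = TRUE)) {
    stop_format("`nuclear_circularity` must lie in (0, 1]")
  }
  if (!inherits(tbl, "cell_features")) {
    class(tbl) <- c("cell_features", class(tbl))
  }
  tbl
}

#' Read / write per-cell feature tables
#'
#' Plain delimited text with a header row naming the seven features
#' (tab-separated by default, commas accepted); round trips are lossless
#' and preserve row order and unknown columns.
#'
#' @param path file path; `.csv` selects comma separation.
#' @param delim field delimiter; inferred from the extension when `NULL`.
#' @return [read_feature_table()] returns a `cell_features` tibble.
#' @export
read_feature_table <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_cell_features(tbl)
}

#' @rdname read_feature_table
#' @param table a `cell_features` table (or coercible data frame).
#' @export
write_feature_table <- function(table, path, delim = NULL) {
  table <- as_cell_features(table)
  delim <- delim %||% if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(table, path, delim = delim, progress = FALSE)
  invisible(path)
}
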