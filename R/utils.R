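# Internal helpers: error classes, stable seeding, config hashing.

stop_config <- function(msg) abort(msg, class = "scritscreen_config_error")
stop_domain <- function(msg) abort(msg, class = "scritscreen_domain_error")
stop_format <- function(msg) abort(msg, class = "scritscreen_format_error")
stop_contract <- function(msg) abort(msg, class = "scritscreen_contract_error")

#' Stable integer hash of strings
#'
#' Polynomial rolling hash over UTF-8 code points, reduced modulo the largest
#' 32-bit prime. Used to derive per-well random seeds from a master seed plus
#' the well id (and an optional plate salt), so a plate simulation is
#' reproducible well-by-well and insensitive to well ordering.
#'
#' @param ... character or numeric fragments combined into the hash.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
stable_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = "\037"),
                    character(1)), collapse = "\036")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

#' Derive a well-level simulation seed
#'
#' @param master_seed master (plate or run) seed, an integer.
#' @param well well id such as `"A01"`.
#' @param salt optional extra context (e.g. plate id) kept separate from the
#'   well id so layout edits elsewhere on the plate do not change this well.
#' @return integer seed below `2^31`.
#' @export
well_seed <- function(master_seed, well, salt = "") {
  stable_hash("well", as.integer(master_seed), well, salt)
}

# Deterministic hash of an R object (config provenance). Not cryptographic.
config_hash <- function(x) {
  sprintf("%08x", stable_hash(paste(deparse(x), collapse = "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(tbl, cols, what = "table") {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    stop_format(sprintf("%s is missing mandatory column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(tbl)
}
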