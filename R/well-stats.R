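# Per-well statistics: signed KS against pooled in-plate negative controls,
# TO-PRO-3 gating and viability, and KS-based Z' plate quality control.

#' Signed Kolmogorov-Smirnov distance
#'
#' The maximum signed difference between the empirical CDFs of a sample and
#' a reference, evaluated exactly over all jump points of the pooled
#' support: `D = F_ref(x*) - F_sample(x*)` at the point `x*` maximizing
#' `|F_ref - F_sample|`. The sign is positive when the sample is shifted
#' toward higher values (its CDF lies below the reference), so an
#' FCCP-like TMRM intensity drop scores negative and a nicardipine-like
#' increase scores positive. Exact; no asymptotic approximation and no
#' p-value. Ties in `|F_ref - F_sample|` resolve to the smallest `x`.
#'
#' @param sample numeric sample values (n >= 1).
#' @param reference numeric reference values (n >= 1), typically the pooled
#'   negative-control distribution.
#' @return a single value in \[-1, 1\].
#' @examples
#' signed_ks(c(5, 6, 7), c(1, 2, 3))   # +1, disjoint above
#' signed_ks(1:10, 1:10)               # 0
#' @export
signed_ks <- function(sample, reference) {
  sample <- as.numeric(sample)
  reference <- as.numeric(reference)
  if (length(sample) < 1 || anyNA(sample)) {
    stop_domain("`sample` must contain at least one non-missing value")
  }
  if (length(reference) < 1 || anyNA(reference)) {
    stop_domain("`reference` must contain at least one non-missing value")
  }
  x <- sort(unique(c(sample, reference)))
  f_s <- findInterval(x, sort(sample)) / length(sample)
  f_r <- findInterval(x, sort(reference)) / length(reference)
  d <- f_r - f_s
  d[which.max(abs(d))] # which.max: first maximum = smallest x
}

#' Pooled negative-control distribution
#'
#' Concatenates the values of one feature over all cells of all
#' negative-control wells of a plate: the in-plate reference every treated
#' well is normalized against.
#'
#' @param features a `cell_features` table for the plate.
#' @param layout the plate layout.
#' @param parameter feature column name.
#' @return sorted numeric vector.
#' @export
pooled_control <- function(features, layout, parameter) {
  assert_columns(features, parameter, "feature table")
  neg_wells <- layout$well[layout$role == "negative_control"]
  vals <- features[[parameter]][features$well %in% neg_wells]
  if (length(vals) == 0) {
    abort("plate rejected: no negative-control cells to pool",
          class = "scritscreen_qc_error")
  }
  sort(vals)
}

#' Choose the TO-PRO-3 live/dead gate
#'
#' Finds the valley of a kernel-smoothed log10-intensity density between the
#' two dominant modes of the plate-wide TO-PRO-3 distribution. When no
#' convincing bimodality is present (fewer than two modes, or a shallow
#' valley) the default gate of 10^3.25 a.u. is used. The returned value
#' carries attributes `method` (`"valley"` or `"default"`) and `log10`.
#'
#' @param topro_values plate-wide TO-PRO-3 mean intensities (>= 100 cells
#'   for valley detection; fewer falls back to the default).
#' @param default fallback gate in a.u.
#' @param bw kernel bandwidth on the log10 scale.
#' @param min_mode_height modes lower than this fraction of the tallest
#'   mode are ignored.
#' @param max_valley_ratio the valley must be below this fraction of the
#'   lower of the two mode heights to call bimodality.
#' @return the gate in a.u.
#' @export
choose_topro_gate <- function(topro_values, default = 10^3.25, bw = 0.1,
                              min_mode_height = 0.1,
                              max_valley_ratio = 0.8) {
  vals <- topro_values[is.finite(topro_values) & topro_values > 0]
  fallback <- structure(default, method = "default", log10 = log10(default))
  if (length(vals) < 100) return(fallback)
  lv <- log10(vals)
  den <- density(lv, bw = bw, n = 512)
  y <- den$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= min_mode_height * max(y)]
  if (length(is_max) < 2) return(fallback)
  # the two tallest retained modes, in position order
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  v <- between[which.min(y[between])]
  if (y[v] > max_valley_ratio * min(y[top2])) return(fallback)
  structure(10^den$x[v], method = "valley", log10 = den$x[v])
}

#' Viability fraction of a well
#'
#' Fraction of cells at or below the TO-PRO-3 gate (TO-PRO-3-negative =
#' live, membrane intact).
#'
#' @param topro_values per-cell TO-PRO-3 mean intensities of one well.
#' @param gate gate in a.u.
#' @return fraction in \[0, 1\].
#' @export
viability_fraction <- function(topro_values, gate) {
  if (length(topro_values) < 1) {
    stop_domain("empty well: no TO-PRO-3 values")
  }
  mean(topro_values <= gate)
}

#' Rescale a viability fraction to the KS range
#'
#' Maps the live fraction \[0, 1\] linearly onto \[-1, +1\]
#' (`2 * fraction - 1`): -1 all dead, +1 all live, matching the range of
#' signed KS values so both can share one response vector.
#'
#' @param fraction live fraction in \[0, 1\].
#' @return value in \[-1, 1\].
#' @export
rescale_viability <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    stop_domain("viability fraction must lie in [0, 1]")
  }
  2 * fraction - 1
}

#' Per-well statistics against pooled in-plate controls
#'
#' For every well: signed KS of each requested feature against the plate's
#' pooled negative-control distribution, the gated viability fraction and
#' its rescaled value, the cell count, and the gate used. Wells with fewer
#' than `min_cells` cells are flagged `excluded` with a reason and get NA
#' statistics.
#'
#' @param features `cell_features` for the plate.
#' @param layout the plate layout.
#' @param ks_parameters features summarized as signed KS.
#' @param gate TO-PRO-3 gate in a.u.; `NULL` runs [choose_topro_gate()] on
#'   the plate.
#' @param min_cells minimum cells per well for statistics.
#' @return a tibble, one row per layout well: layout columns plus
#'   `n_cells`, `gate`, `excluded`, `reason`, `ks_<feature>` columns,
#'   `viability` and `viability_rescaled`.
#' @export
well_statistics <- function(features, layout,
                            ks_parameters = setdiff(feature_names(),
                                                    "topro_mean"),
                            gate = NULL, min_cells = 50) {
  features <- as_cell_features(features)
  gate <- gate %||% choose_topro_gate(features$topro_mean)
  pooled <- lapply(setNames(nm = ks_parameters), function(p) {
    pooled_control(features, layout, p)
  })
  by_well <- split(features, factor(features$well, levels = layout$well))
  stats_rows <- map(layout$well, function(w) {
    cells <- by_well[[w]]
    n <- if (is.null(cells)) 0L else nrow(cells)
    out <- list(well = w, n_cells = n, gate = as.numeric(gate))
    if (n < min_cells) {
      out$excluded <- TRUE
      out$reason <- sprintf("only %d cells (min %d)", n, min_cells)
      for (p in ks_parameters) out[[paste0("ks_", p)]] <- NA_real_
      out$viability <- NA_real_
      out$viability_rescaled <- NA_real_
    } else {
      out$excluded <- FALSE
      out$reason <- NA_character_
      for (p in ks_parameters) {
        out[[paste0("ks_", p)]] <- signed_ks(cells[[p]], pooled[[p]])
      }
      out$viability <- viability_fraction(cells$topro_mean, gate)
      out$viability_rescaled <- rescale_viability(out$viability)
    }
    as_tibble(out)
  })
  left_join(as_tibble(layout), bind_rows(stats_rows), by = "well")
}

#' Z' screening-window factor
#'
#' The standard screening-window statistic
#' `Z' = 1 - 3 * (sigma_p + sigma_n) / |mu_p - mu_n|`, computed here on KS
#' distances of control wells rather than raw intensities.
#'
#' @param mu_p,mu_n means of the positive- and negative-control statistic.
#' @param sigma_p,sigma_n their standard deviations.
#' @return an object of class `zprime_result` (also a list with fields
#'   `mu_p`, `mu_n`, `sigma_p`, `sigma_n`, `z_prime`).
#' @examples
#' zprime(0.8, 0, 0.05, 0.05)$z_prime # 0.625
#' @export
zprime <- function(mu_p, mu_n, sigma_p, sigma_n) {
  if (mu_p == mu_n) {
    abort("Z' undefined: positive and negative control means coincide",
          class = "scritscreen_qc_error")
  }
  structure(
    list(mu_p = mu_p, mu_n = mu_n, sigma_p = sigma_p, sigma_n = sigma_n,
         z_prime = 1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)),
    class = "zprime_result"
  )
}

#' @export
print.zprime_result <- function(x, ...) {
  cat(sprintf(
    "Z' = %.3f  (mu_p %.3f, mu_n %.3f, sigma_p %.3f, sigma_n %.3f)\n",
    x$z_prime, x$mu_p, x$mu_n, x$sigma_p, x$sigma_n))
  invisible(x)
}

#' KS-based control Z' of a plate
#'
#' For every control well, the magnitude of the signed KS of the chosen
#' feature (TMRM peripheral integral by default) against the pooled
#' negative-control distribution; Z' is then the standard formula applied
#' to the positive- and negative-well KS samples.
#'
#' @param features `cell_features` for the plate.
#' @param layout the plate layout (>= 2 wells per control arm).
#' @param parameter feature used for the control window.
#' @param min_cells minimum cells per control well.
#' @return a `zprime_result` with extra fields `parameter`, `ks_pos`,
#'   `ks_neg`.
#' @export
zprime_ks <- function(features, layout,
                      parameter = "tmrm_peripheral_integral",
                      min_cells = 50) {
  features <- as_cell_features(features)
  pooled <- pooled_control(features, layout, parameter)
  ctrl_ks <- function(role) {
    wells <- layout$well[layout$role == role]
    ks <- map_dbl(wells, function(w) {
      vals <- features[[parameter]][features$well == w]
      if (length(vals) < min_cells) return(NA_real_)
      abs(signed_ks(vals, pooled))
    })
    ks[!is.na(ks)]
  }
  ks_pos <- ctrl_ks("positive_control")
  ks_neg <- ctrl_ks("negative_control")
  if (length(ks_pos) < 2 || length(ks_neg) < 2) {
    abort("Z' needs >= 2 usable control wells per arm",
          class = "scritscreen_qc_error")
  }
  res <- zprime(mean(ks_pos), mean(ks_neg), sd(ks_pos), sd(ks_neg))
  res$parameter <- parameter
  res$ks_pos <- ks_pos
  res$ks_neg <- ks_neg
  res
}

#' Plate quality-control report
#'
#' Per-parameter control summaries (means, SDs, CVs of the per-well control
#' KS values), the control Z' (omitted with a warning when a control arm is
#' missing or degenerate), the gate, and the excluded wells with reasons.
#'
#' @param features `cell_features` for the plate.
#' @param layout the plate layout.
#' @param ks_parameters features summarized as signed KS.
#' @param gate,min_cells forwarded to [well_statistics()].
#' @return an object of class `plate_qc`: list with `well_stats`,
#'   `control_summary`, `zprime`, `gate`, `excluded`, `config_hash`.
#' @export
plate_qc <- function(features, layout,
                     ks_parameters = setdiff(feature_names(), "topro_mean"),
                     gate = NULL, min_cells = 50) {
  ws <- well_statistics(features, layout, ks_parameters, gate, min_cells)
  ctrl <- ws[ws$role %in% c("negative_control", "positive_control") &
               !ws$excluded, ]
  summarise_arm <- function(df) {
    bind_rows(lapply(ks_parameters, function(p) {
      v <- df[[paste0("ks_", p)]]
      tibble(parameter = p, n_wells = length(v), mean_ks = mean(v),
             sd_ks = sd(v), cv_ks = sd(v) / abs(mean(v)))
    }))
  }
  control_summary <- bind_rows(
    mutate(summarise_arm(ctrl[ctrl$role == "negative_control", ]),
           role = "negative_control", .before = 1),
    mutate(summarise_arm(ctrl[ctrl$role == "positive_control", ]),
           role = "positive_control", .before = 1)
  )
  zp <- tryCatch(
    zprime_ks(features, layout, min_cells = min_cells),
    scritscreen_qc_error = function(e) {
      warn(paste("Z' omitted:", conditionMessage(e)))
      NULL
    })
  out <- list(
    well_stats = ws,
    control_summary = control_summary,
    zprime = zp,
    gate = ws$gate[1],
    excluded = ws[ws$excluded, c("well", "role", "n_cells", "reason")],
    viability_neg = mean(ws$viability[ws$role == "negative_control" &
                                        !ws$excluded]),
    config_hash = config_hash(list(ks_parameters, gate, min_cells))
  )
  class(out) <- "plate_qc"
  out
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("<plate_qc> %d wells (%d excluded), gate %.0f a.u.\n",
              nrow(x$well_stats), nrow(x$excluded), x$gate))
  if (!is.null(x$zprime)) {
    cat(sprintf("  control Z' (%s): %.3f\n",
                x$zprime$parameter, x$zprime$z_prime))
  }
  invisible(x)
}

#' Write a machine-readable QC report
#'
#' @param qc a `plate_qc` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  payload <- list(
    gate = qc$gate,
    zprime = if (!is.null(qc$zprime)) {
      qc$zprime[c("mu_p", "mu_n", "sigma_p", "sigma_n", "z_prime",
                  "parameter")]
    },
    control_summary = qc$control_summary,
    excluded = qc$excluded,
    config_hash = qc$config_hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
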