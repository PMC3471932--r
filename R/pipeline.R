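# End-to-end screen stages on simulated plates: control QC, single-dose
# primary screen, and the dose-response secondary screen.

#' Simulate a multi-plate dose-response screen
#'
#' Lays compounds out on dose-response plates (four compounds x two
#' replicate rows per plate, plus eight controls of each arm), simulates
#' every plate in both growth conditions and for every replicate pair, and
#' reduces each plate to per-well statistics. Each physical plate gets its
#' own seed salt, so plates are independent but individually reproducible.
#'
#' @param compounds tibble with `compound` and `archetype` columns, or a
#'   named character vector `compound -> archetype`.
#' @param models optional named list of `phenotype_model` overrides; by
#'   default each compound gets `make_phenotype_model(archetype)`.
#' @param doses dose series (uM).
#' @param conditions growth media to run.
#' @param n_replicates biological replicates per compound (multiple of the
#'   2 replicate rows a plate carries).
#' @param n_cells expected cells per well.
#' @param seed master seed.
#' @param ks_parameters,min_cells forwarded to [well_statistics()].
#' @return well-statistics tibble over all plates, with a `plate` column.
#' @export
simulate_screen <- function(compounds,
                            models = NULL,
                            doses = dose_series(),
                            conditions = c("glu_plus", "glu_minus"),
                            n_replicates = 2,
                            n_cells = 500,
                            seed = 1L,
                            ks_parameters = setdiff(feature_names(),
                                                    "topro_mean"),
                            min_cells = 50) {
  if (!is.data.frame(compounds)) {
    compounds <- tibble(compound = names(compounds),
                        archetype = unname(compounds))
  }
  assert_columns(compounds, c("compound", "archetype"), "compound table")
  models <- models %||% lapply(setNames(compounds$archetype,
                                        compounds$compound),
                               make_phenotype_model)
  chunks <- split(compounds$compound,
                  ceiling(seq_along(compounds$compound) / 4))
  rep_pairs <- split(seq_len(n_replicates),
                     ceiling(seq_len(n_replicates) / 2))
  plates <- list()
  for (cond in conditions) {
    for (rp in rep_pairs) {
      for (ci in seq_along(chunks)) {
        plate_id <- sprintf("%s_rep%d_p%d", cond, rp[1], ci)
        layout <- build_dose_response_plate(
          chunks[[ci]], series = doses,
          n_replicates = length(rp),
          condition = cond, replicate_offset = rp[1])
        features <- simulate_plate(layout, models, n_cells = n_cells,
                                   seed = seed, salt = plate_id)
        ws <- well_statistics(features, layout,
                              ks_parameters = ks_parameters,
                              min_cells = min_cells)
        ws$plate <- plate_id
        plates[[plate_id]] <- ws
      }
    }
  }
  bind_rows(plates)
}

#' Control-plate QC stage
#'
#' Simulates (or accepts) a whole-column control plate and reports the
#' plate QC bundle: per-parameter control KS summaries, the KS-based
#' control Z' on TMRM peripheral integral, gate, and exclusions.
#'
#' @param seed master seed for the simulated plate.
#' @param n_cols_per_condition control columns per arm (6 = the 48/48
#'   development plate).
#' @param n_cells expected cells per well.
#' @param condition growth medium.
#' @param features,layout supply both to run QC on existing data instead
#'   of simulating.
#' @return a `plate_qc` with `config` and `config_hash` fields recorded.
#' @export
run_control_qc <- function(seed = 1L, n_cols_per_condition = 6,
                           n_cells = 500, condition = "glu_plus",
                           features = NULL, layout = NULL) {
  cfg <- list(stage = "control_qc", seed = seed,
              n_cols_per_condition = n_cols_per_condition,
              n_cells = n_cells, condition = condition)
  if (is.null(layout)) {
    layout <- build_control_plate(n_cols_per_condition, condition = condition)
  }
  if (sum(layout$role == "positive_control") == 0) {
    stop_config("control QC requires positive-control wells")
  }
  if (is.null(features)) {
    features <- simulate_plate(layout, seed = seed, n_cells = n_cells,
                               salt = "control_qc")
  }
  qc <- plate_qc(features, layout)
  qc$config <- cfg
  qc$config_hash <- config_hash(cfg)
  qc
}

#' Primary (single-dose) screening stage
#'
#' Simulates duplicate single-dose plates per growth condition, builds the
#' 7-parameter x 2-condition (14-component) SCRIT vector of each compound
#' replicate, averages replicates, applies the 20% activity cut-off, and
#' returns activity calls with a Euclidean distance matrix for review.
#'
#' @param compounds tibble (`compound`, `archetype`) or named vector.
#' @param dose screening dose (uM).
#' @param n_replicates duplicate plates per condition.
#' @param n_cells,seed simulation controls.
#' @param cutoff activity threshold.
#' @param interference optional character vector of compounds flagged for
#'   marker interference; they are excluded from the automated calls and
#'   listed in the result.
#' @return list with `calls` (per-compound activity table), `scrit`,
#'   `dist` (Euclidean), `interference`, `config`, `config_hash`.
#' @export
run_primary_screen <- function(compounds, dose = 100, n_replicates = 2,
                               n_cells = 500, seed = 1L, cutoff = 0.2,
                               interference = character(0)) {
  cfg <- list(stage = "primary", dose = dose, n_replicates = n_replicates,
              n_cells = n_cells, seed = seed, cutoff = cutoff)
  if (!is.data.frame(compounds)) {
    compounds <- tibble(compound = names(compounds),
                        archetype = unname(compounds))
  }
  models <- lapply(setNames(compounds$archetype, compounds$compound),
                   make_phenotype_model)
  all_ws <- list()
  for (cond in c("glu_plus", "glu_minus")) {
    for (r in seq_len(n_replicates)) {
      plate_id <- sprintf("primary_%s_rep%d", cond, r)
      layout <- build_single_dose_plate(compounds$compound, dose = dose,
                                        condition = cond, replicate = r)
      features <- simulate_plate(layout, models, n_cells = n_cells,
                                 seed = seed, salt = plate_id)
      ws <- well_statistics(features, layout)
      ws$plate <- plate_id
      all_ws[[plate_id]] <- ws
    }
  }
  ws <- bind_rows(all_ws)
  params7 <- c("tmrm_peripheral_integral", "tmrm_max_pixel", "hoechst_mean",
               "hoechst_integral", "nuclear_area", "nuclear_circularity",
               "viability")
  scrit <- build_scrit(ws, parameters = params7)
  calls_rep <- primary_screen_select(scrit, cutoff = cutoff)
  # the activity call is made on the replicate-mean vector of each
  # compound (duplicate plates average out well-level noise)
  im <- scrit_index_map(scrit)
  mean_tbl <- as_tibble(scrit) %>%
    group_by(.data$compound) %>%
    summarise(across(all_of(im$component), mean), .groups = "drop") %>%
    mutate(replicate = 1L, .after = "compound")
  mean_scrit <- set_scrit_attrs(mean_tbl, scrit)
  calls <- primary_screen_select(mean_scrit, cutoff = cutoff) %>%
    select(-"replicate") %>%
    mutate(interference = .data$compound %in% interference)
  d <- scrit_dist(scrit, metric = "euclidean")
  list(calls = calls, replicate_calls = calls_rep, scrit = scrit,
       mean_scrit = mean_scrit, dist = d,
       interference = interference, config = cfg,
       config_hash = config_hash(cfg))
}

#' Secondary (dose-response) screening stage
#'
#' Full classification pipeline: simulate dose-response plates in both
#' media, build SCRIT vectors (TMRM peripheral integral KS, Hoechst mean
#' KS, rescaled viability by default), drop replicate-inconsistent
#' compounds, then cluster, embed and label the retained vectors.
#'
#' @param compounds tibble (`compound`, `archetype`) or named vector.
#' @param parameters SCRIT parameter set.
#' @param doses dose series.
#' @param n_replicates biological replicates per compound (>= 2).
#' @param n_cells,seed simulation controls.
#' @param outlier_threshold replicate-consistency bound.
#' @param k flat clusters for group labels.
#' @return object of class `secondary_screen`: list with `well_stats`,
#'   `scrit`, `consistency`, `classification`, `config`, `config_hash`.
#' @export
run_secondary_screen <- function(compounds,
                                 parameters = c("tmrm_peripheral_integral",
                                                "hoechst_mean", "viability"),
                                 doses = dose_series(),
                                 n_replicates = 2,
                                 n_cells = 500, seed = 1L,
                                 outlier_threshold = 0.2, k = 5) {
  cfg <- list(stage = "secondary", parameters = parameters,
              doses = doses, n_replicates = n_replicates,
              n_cells = n_cells, seed = seed,
              outlier_threshold = outlier_threshold, k = k)
  ws <- simulate_screen(compounds, doses = doses,
                        n_replicates = n_replicates,
                        n_cells = n_cells, seed = seed)
  scrit <- build_scrit(ws, parameters = parameters)
  consistency <- replicate_consistency(scrit, threshold = outlier_threshold)
  classification <- classify_scrit(consistency$kept, k = k)
  structure(list(well_stats = ws, scrit = scrit, consistency = consistency,
                 classification = classification, config = cfg,
                 config_hash = config_hash(cfg)),
            class = "secondary_screen")
}

#' @export
print.secondary_screen <- function(x, ...) {
  cat(sprintf("<secondary_screen> %d compounds, %d retained vectors\n",
              length(unique(x$scrit$compound)),
              nrow(x$classification$groups)))
  print(attr(x$classification$groups, "compound_groups"), n = Inf)
  invisible(x)
}

#' Five-archetype synthetic benchmark
#'
#' The standard recovery benchmark: three compounds per archetype (their
#' potencies spread deterministically around the archetype EC50 by the
#' `ec50_spread` multipliers, as unrelated compounds of one mechanistic
#' class would differ), simulated in quadruplicate over the ten-dose 1:3
#' series in both growth media.
#'
#' @param archetypes archetype set (default: the five mechanistic groups).
#' @param n_per_archetype compounds per archetype.
#' @param ec50_spread potency multipliers recycled over the compounds of
#'   an archetype.
#' @param glu_plus_spread scale factors on the glucose-condition effect
#'   sizes of the direct-mitochondrial (group I) compounds. Members of
#'   that class genuinely differ in how much of their toxicity already
#'   shows under glucose (from respiratory-chain inhibitors with hardly
#'   any glucose-medium response to ionophores that respond equally in
#'   both media); the spread keeps their common glucose-withdrawal
#'   amplification while varying the glucose-only face of the response.
#' @return list with `compounds` (tibble: compound, archetype, group) and
#'   `models` (named list of `phenotype_model`s).
#' @export
archetype_benchmark <- function(archetypes = c("I_direct_mito",
                                               "II_glu_independent",
                                               "III_glu_dependent",
                                               "IV_inactive",
                                               "V_uncoupler"),
                                n_per_archetype = 3,
                                ec50_spread = c(0.7, 1, 1.4),
                                glu_plus_spread = c(0.5, 1, 1.5)) {
  compounds <- tibble(
    archetype = rep(archetypes, each = n_per_archetype),
    idx = rep(seq_len(n_per_archetype), times = length(archetypes))
  ) %>%
    mutate(compound = sprintf("%s_c%d", sub("_.*", "", .data$archetype),
                              .data$idx),
           group = sub("_.*", "", .data$archetype))
  mult <- rep(ec50_spread, length.out = n_per_archetype)
  gp_mult <- rep(glu_plus_spread, length.out = n_per_archetype)
  models <- lapply(seq_len(nrow(compounds)), function(i) {
    base <- make_phenotype_model(compounds$archetype[i])
    m <- make_phenotype_model(compounds$archetype[i],
                              list(ec50 = base$ec50 * mult[compounds$idx[i]],
                                   dead_ec50 = base$dead_ec50 *
                                     mult[compounds$idx[i]]))
    if (compounds$archetype[i] == "I_direct_mito") {
      for (nm in c("tmrm", "hoechst", "area", "circularity", "dead_max")) {
        m$effects$glu_plus[[nm]] <-
          m$effects$glu_plus[[nm]] * gp_mult[compounds$idx[i]]
      }
    }
    m
  })
  names(models) <- compounds$compound
  list(compounds = compounds[, c("compound", "archetype", "group")],
       models = models)
}
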