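# Plate simulator: draws per-cell feature tables from phenotype models.

#' Simulate one well of per-cell features
#'
#' Cell count is Poisson around `n_cells`; each channel is sampled
#' log-normally around its Hill-modulated median (with one log-normal
#' well-effect factor per channel group, shared by all cells of the well);
#' TO-PRO-3 is drawn from the live/dead mixture with a dose-dependent dead
#' fraction. Fully deterministic for a fixed seed; the caller's RNG state
#' is untouched.
#'
#' @param model a [make_phenotype_model()] object.
#' @param dose dose in uM (>= 0).
#' @param condition `"glu_plus"` or `"glu_minus"`.
#' @param n_cells expected cells per well.
#' @param seed integer seed for this well.
#' @param well,field_count well id recorded in the table and number of
#'   fields of view the cells are attributed to.
#' @return a `cell_features` tibble.
#' @export
simulate_well <- function(model, dose, condition, n_cells = 500,
                          seed = 1L, well = "A01", field_count = 6L) {
  if (!inherits(model, "phenotype_model")) {
    stop_contract("`model` must be a phenotype_model")
  }
  if (dose < 0) stop_domain("`dose` must be >= 0")
  cond <- match.arg(condition, c("glu_plus", "glu_minus"))
  withr::with_seed(as.integer(seed), {
    n <- rpois(1, n_cells)
    groups <- c("tmrm", "hoechst", "area", "circularity")
    ws_sig <- model$well_sigma
    if (!is.list(ws_sig)) ws_sig <- as.list(setNames(rep(ws_sig[[1]],
                                                         4), groups))
    w <- setNames(vapply(groups, function(g) rnorm(1, 0, ws_sig[[g]]),
                         numeric(1)), groups)
    draw <- function(parameter) {
      base <- model$baselines[[parameter]]
      med <- channel_median(model, parameter, dose, cond)
      grp <- effect_group(parameter)
      if (parameter == "nuclear_circularity") {
        # sample (1 - circularity) log-normally, clamp into (0, 1]
        x <- rlnorm(n, log(1 - med) + w[[grp]], base$sigma)
        pmax(pmin(1 - x, 1), 0.05)
      } else {
        rlnorm(n, log(med) + w[[grp]], base$sigma)
      }
    }
    direct <- setdiff(feature_names(), c("topro_mean", "hoechst_integral"))
    feats <- lapply(setNames(nm = direct), draw)
    feats$nuclear_area <- pmax(pmin(feats$nuclear_area, 250), 20)
    # Hoechst integral = mean x nuclear pixel area (DNA content conserved
    # under condensation) with a small residual spread
    feats$hoechst_integral <- feats$hoechst_mean *
      (feats$nuclear_area / GEN_PX_AREA) *
      rlnorm(n, 0, model$baselines$hoechst_integral$residual_sigma)
    feats <- feats[setdiff(feature_names(), "topro_mean")]
    p_dead <- dead_fraction(model, dose, cond)
    if (p_dead > 0 && p_dead < 1) {
      # well-to-well biological variability of the dead fraction
      p_dead <- plogis(qlogis(p_dead) + rnorm(1, 0, 0.15))
    }
    dead <- rbinom(n, 1, p_dead) == 1
    topro_med <- ifelse(dead, model$topro$dead_median, model$topro$live_median)
    feats$topro_mean <- rlnorm(n, log(topro_med), model$topro$sdlog)
    as_cell_features(tibble(
      well = well,
      field = if (n > 0) rep_len(seq_len(field_count), n) else integer(0),
      cell = seq_len(n),
      !!!feats
    ))
  })
}

#' Simulate a whole plate
#'
#' Every well of the layout is simulated with its own seed derived from the
#' master seed, the well id and `salt` via a stable hash, so results are
#' bit-reproducible and unaffected by row order or edits to other wells.
#' Negative-control wells use the inactive (vehicle) archetype, positive
#' controls the uncoupler archetype at the layout's control dose.
#'
#' @param layout a `plate_layout`.
#' @param models named list mapping each test compound to a
#'   `phenotype_model`; controls need no entry.
#' @param n_cells expected cells per well.
#' @param seed master seed.
#' @param salt extra seed context, e.g. a plate id, separating replicate
#'   plates of identical layout.
#' @return a `cell_features` tibble for all wells.
#' @export
simulate_plate <- function(layout, models = list(), n_cells = 500,
                           seed = 1L, salt = "") {
  vehicle <- make_phenotype_model("IV_inactive")
  uncoupler <- make_phenotype_model("V_uncoupler")
  test_compounds <- unique(layout$compound[layout$role == "test"])
  missing <- setdiff(test_compounds, names(models))
  if (length(missing) > 0) {
    stop_config(paste("no phenotype model for compound(s):",
                      paste(missing, collapse = ", ")))
  }
  rows <- seq_len(nrow(layout))
  tabs <- lapply(rows, function(i) {
    role <- layout$role[i]
    model <- switch(role,
                    negative_control = vehicle,
                    positive_control = uncoupler,
                    models[[layout$compound[i]]])
    simulate_well(model, dose = layout$dose[i],
                  condition = layout$condition[i],
                  n_cells = n_cells,
                  seed = well_seed(seed, layout$well[i], salt),
                  well = layout$well[i])
  })
  as_cell_features(bind_rows(tabs))
}
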