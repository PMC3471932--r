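# Generative phenotype archetypes: Hill-modulated log-normal channel models
# with a two-component live/dead TO-PRO-3 mixture.

ARCHETYPES <- c("I_direct_mito", "II_glu_independent", "III_glu_dependent",
                "IV_inactive", "V_uncoupler", "inverse_tmrm")

# effect groups: tmrm/hoechst/area are fractional median changes in [-1, 1]
# (positive = intensity/area decrease, negative = increase); circularity is
# the fractional reduction of (1 - circularity), i.e. rounding-up of nuclei;
# dead_max is the saturating dead fraction in [0, 1].
archetype_effects <- function(archetype) {
  z <- list(tmrm = 0, hoechst = 0, area = 0, circularity = 0, dead_max = 0)
  eff <- function(tmrm, hoechst, area, circularity, dead_max) {
    list(tmrm = tmrm, hoechst = hoechst, area = area,
         circularity = circularity, dead_max = dead_max)
  }
  switch(archetype,
    I_direct_mito = list(
      ec50 = 1.5, hill = 1.5,
      glu_plus  = eff(0.35, -0.15, 0.10, 0.20, 0.25),
      glu_minus = eff(0.90, -0.55, 0.30, 0.50, 0.90)),
    II_glu_independent = list(
      ec50 = 2, hill = 1.5,
      glu_plus  = eff(0.75, -0.30, 0.25, 0.40, 0.85),
      glu_minus = eff(0.75, -0.30, 0.25, 0.40, 0.85)),
    III_glu_dependent = list(
      ec50 = 3.3, hill = 3,
      glu_plus  = z,
      glu_minus = eff(0.80, -0.25, 0.25, 0.40, 0.85)),
    IV_inactive = list(
      ec50 = 1, hill = 1.5,
      glu_plus = z, glu_minus = z),
    V_uncoupler = list(
      ec50 = 5, hill = 1.5,
      glu_plus  = eff(0.60, -0.15, 0.20, 0.30, 0.50),
      glu_minus = eff(0.65, -0.20, 0.20, 0.30, 0.95)),
    inverse_tmrm = list(
      ec50 = 4, hill = 1.5,
      glu_plus  = eff(-0.80, -0.10, 0.10, 0.15, 0.60),
      glu_minus = eff(-0.80, -0.10, 0.10, 0.15, 0.60)),
    stop_domain(sprintf("unknown archetype '%s' (expected one of %s)",
                        archetype, paste(ARCHETYPES, collapse = ", ")))
  )
}

default_baselines <- function() {
  # hoechst_integral is derived (mean x nuclear pixel area x a small
  # residual): nuclear DNA content is conserved under condensation, so the
  # integral barely responds while the mean rises. Its entry documents the
  # implied median (6500 a.u. x 440 px at 110 um^2 / 0.25 um^2 per px) and
  # the combined spread used for analytic expectations.
  list(
    tmrm_peripheral_integral = list(median = 1e6,    sigma = 0.35),
    tmrm_max_pixel           = list(median = 3500,   sigma = 0.30),
    hoechst_integral         = list(median = 2.86e6, sigma = 0.33,
                                    residual_sigma = 0.10),
    hoechst_mean             = list(median = 6500,   sigma = 0.25),
    nuclear_area             = list(median = 110,    sigma = 0.18),
    nuclear_circularity      = list(median = 0.85,   sigma = 0.40)
  )
}

# pixel area (um^2) the generator assumes when tying Hoechst integral to
# mean intensity and nuclear area (square 0.5 um pixels)
GEN_PX_AREA <- 0.25

#' Build a mechanistic phenotype archetype
#'
#' Generative model of per-cell feature distributions as functions of dose
#' and growth medium. Channel medians follow Hill dose-response curves on a
#' log-normal cell-to-cell background; cell death follows its own Hill curve
#' feeding a two-component (live/dead) log-normal TO-PRO-3 mixture whose
#' component medians bracket the default 10^3.25 a.u. viability gate.
#'
#' The six archetypes encode the screen's mechanistic classes:
#' * `I_direct_mito` - direct mitochondrial toxins: responses in glucose,
#'   strongly amplified after galactose substitution;
#' * `II_glu_independent` - equal toxicity in both media;
#' * `III_glu_dependent` - response only without glucose;
#' * `IV_inactive` - flat;
#' * `V_uncoupler` - FCCP-like: clear TMRM drop with about half the cells
#'   surviving in glucose, near-total viability loss without glucose and
#'   little further TMRM change;
#' * `inverse_tmrm` - nicardipine-like TMRM increase with viability loss.
#'
#' @param archetype one of the six archetype names (see above).
#' @param overrides named list merged recursively over the defaults
#'   (e.g. `list(ec50 = 0.5)` or `list(effects = list(glu_plus =
#'   list(tmrm = 0.2)))`).
#' @return an object of class `phenotype_model`.
#' @examples
#' make_phenotype_model("V_uncoupler")$effects$glu_plus$dead_max # 0.5
#' @export
make_phenotype_model <- function(archetype, overrides = list()) {
  pars <- archetype_effects(archetype)
  model <- list(
    archetype = archetype,
    ec50 = pars$ec50,
    hill = pars$hill,
    dead_ec50 = pars$ec50,
    dead_hill = pars$hill,
    effects = list(glu_plus = pars$glu_plus, glu_minus = pars$glu_minus),
    baselines = default_baselines(),
    topro = list(live_median = 10^2.5, dead_median = 10^4,
                 sdlog = 0.25 * log(10)),
    # log-scale well-to-well effects per channel group: the
    # potential-sensitive TMRM staining is the volatile one (incubation and
    # temperature sensitivity), DNA-stoichiometric Hoechst varies less, and
    # nuclear morphology is nearly free of well effects
    well_sigma = list(tmrm = 0.07, hoechst = 0.04, area = 0.02,
                      circularity = 0.02)
  )
  model <- modifyList(model, overrides)
  stopifnot(model$topro$live_median < model$topro$dead_median)
  class(model) <- "phenotype_model"
  model
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("<phenotype_model: %s> ec50 %.3g uM, hill %.3g\n",
              x$archetype, x$ec50, x$hill))
  for (cond in names(x$effects)) {
    e <- x$effects[[cond]]
    cat(sprintf("  %-9s tmrm %+0.2f hoechst %+0.2f area %+0.2f dead_max %.2f\n",
                cond, e$tmrm, e$hoechst, e$area, e$dead_max))
  }
  invisible(x)
}

#' Hill occupancy
#'
#' `dose^h / (dose^h + ec50^h)`, 0 at dose 0.
#' @param dose dose in uM (>= 0).
#' @param ec50 half-maximal dose in uM.
#' @param hill Hill slope.
#' @export
hill_response <- function(dose, ec50, hill) {
  ifelse(dose <= 0, 0, dose^hill / (dose^hill + ec50^hill))
}

effect_group <- function(parameter) {
  switch(parameter,
    tmrm_peripheral_integral = , tmrm_max_pixel = "tmrm",
    hoechst_integral = , hoechst_mean = "hoechst",
    nuclear_area = "area",
    nuclear_circularity = "circularity",
    stop_domain(sprintf("no effect group for parameter '%s'", parameter))
  )
}

#' Model-implied dead fraction and channel medians
#'
#' Closed-form (noise-free) summaries of a phenotype model, used both by the
#' simulator and to build analytic reference response vectors.
#'
#' @param model a `phenotype_model`.
#' @param dose dose in uM.
#' @param condition `"glu_plus"` or `"glu_minus"`.
#' @return [dead_fraction()]: expected dead fraction in \[0, 1\].
#' @export
dead_fraction <- function(model, dose, condition) {
  e <- model$effects[[condition]]
  e$dead_max * hill_response(dose, model$dead_ec50, model$dead_hill)
}

#' @rdname dead_fraction
#' @param parameter one of the six non-TO-PRO-3 features of
#'   [feature_names()].
#' @return [channel_median()]: the median of the feature's distribution at
#'   this dose (circularity on its own (0, 1] scale).
#' @export
channel_median <- function(model, parameter, dose, condition) {
  base <- model$baselines[[parameter]]
  if (is.null(base)) stop_domain(sprintf("unknown channel '%s'", parameter))
  h <- hill_response(dose, model$ec50, model$hill)
  eff <- model$effects[[condition]]
  if (parameter == "hoechst_integral") {
    # derived channel: mean intensity x nuclear pixel area
    return(channel_median(model, "hoechst_mean", dose, condition) *
             channel_median(model, "nuclear_area", dose, condition) /
             GEN_PX_AREA)
  }
  e <- eff[[effect_group(parameter)]]
  if (parameter == "nuclear_circularity") {
    1 - (1 - base$median) * (1 - e * h)
  } else {
    base$median * max(1 - e * h, 0.01)
  }
}

# Expected signed KS of a treated log-normal channel against its control,
# both with cell-level log-sd sigma: a location shift of delta log-units
# gives KS = 2*pnorm(|delta| / (2*sigma)) - 1, signed by the direction of
# the shift (positive = shifted to higher values).
expected_ks <- function(model, parameter, dose, condition) {
  base <- model$baselines[[parameter]]
  m0 <- channel_median(model, parameter, 0, condition)
  m1 <- channel_median(model, parameter, dose, condition)
  if (parameter == "nuclear_circularity") {
    # circularity is modeled through log(1 - c); value shift is reversed
    delta <- log((1 - m1) / (1 - m0))
    sgn <- -sign(delta)
  } else {
    delta <- log(m1 / m0)
    sgn <- sign(delta)
  }
  if (delta == 0) return(0)
  sgn * (2 * pnorm(abs(delta) / (2 * base$sigma)) - 1)
}

#' Analytic (noise-free) SCRIT reference vector for an archetype
#'
#' Expected response-vector components implied by a phenotype model:
#' analytic signed KS for intensity/morphology parameters and rescaled
#' expected viability, in canonical component order (parameter-major,
#' glucose condition before galactose, doses ascending). These serve as the
#' reference fingerprints that cluster labels are matched against.
#'
#' @param model a `phenotype_model`.
#' @param parameters SCRIT parameters; `"viability"` plus any of the six
#'   channel features.
#' @param doses dose series in uM.
#' @param conditions conditions to include, in SCRIT order.
#' @return numeric vector of length
#'   `length(parameters) * length(conditions) * length(doses)`.
#' @export
expected_scrit <- function(model,
                           parameters = c("tmrm_peripheral_integral",
                                          "hoechst_mean", "viability"),
                           doses = dose_series(),
                           conditions = c("glu_plus", "glu_minus")) {
  doses <- sort(doses)
  unlist(lapply(parameters, function(p) {
    unlist(lapply(conditions, function(cond) {
      vapply(doses, function(d) {
        if (p == "viability") {
          rescale_viability(1 - dead_fraction(model, d, cond))
        } else {
          expected_ks(model, p, d, cond)
        }
      }, numeric(1))
    }))
  }))
}
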