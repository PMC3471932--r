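test_that("SCRIT dimensionality follows parameters x conditions x doses", {
  doses10 <- dose_series(100, 3, 10)
  ws <- fake_well_stats(doses = doses10,
                        ks_parameters = c("tmrm_peripheral_integral",
                                          "hoechst_mean"))
  s40 <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                        "viability"))
  expect_equal(nrow(scrit_index_map(s40)), 40)
  s60 <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                        "hoechst_mean", "viability"))
  expect_equal(nrow(scrit_index_map(s60)), 60)
  ws14 <- fake_well_stats(doses = 100,
                          ks_parameters = setdiff(feature_names(),
                                                  "topro_mean"))
  s14 <- build_scrit(ws14, parameters = c(setdiff(feature_names(),
                                                  "topro_mean"),
                                          "viability"))
  expect_equal(nrow(scrit_index_map(s14)), 14)
})

test_that("component count identity holds over random shapes", {
  withr::with_seed(55, {
    for (i in 1:6) {
      np <- sample(1:3, 1); nd <- sample(1:6, 1)
      conds <- if (runif(1) < 0.5) c("glu_plus", "glu_minus") else "glu_plus"
      pars <- c(sample(c("tmrm_peripheral_integral", "hoechst_mean",
                         "nuclear_area"), np), "viability")
      ws <- fake_well_stats(doses = dose_series(100, 3, nd),
                            conditions = conds,
                            ks_parameters = setdiff(pars, "viability"))
      sc <- build_scrit(ws, parameters = pars, conditions = conds)
      expect_equal(nrow(scrit_index_map(sc)),
                   length(pars) * length(conds) * nd)
    }
  })
})

test_that("component order is parameter-major, glucose first, dose ascending", {
  ws <- fake_well_stats(doses = dose_series(100, 3, 3))
  sc <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                       "viability"))
  im <- scrit_index_map(sc)
  expect_equal(im$parameter, rep(c("tmrm_peripheral_integral", "viability"),
                                 each = 6))
  expect_equal(im$condition,
               rep(rep(c("glu_plus", "glu_minus"), each = 3), 2))
  expect_equal(im$dose, rep(sort(dose_series(100, 3, 3)), 4))
  expect_equal(im$component[1],
               paste("tmrm_peripheral_integral", "glu_plus",
                     signif(min(im$dose), 3), sep = "|"))
})

test_that("vector assembly is permutation-safe and averages twin wells", {
  ws <- fake_well_stats(doses = dose_series(100, 3, 5))
  sc1 <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                        "viability"))
  sc2 <- build_scrit(ws[rev(seq_len(nrow(ws))), ],
                     parameters = c("tmrm_peripheral_integral", "viability"))
  expect_equal(as.data.frame(sc1), as.data.frame(sc2))
  # duplicate wells at one cell average into a single statistic
  extra <- ws[ws$role == "test", ][1, ]
  extra$well <- "X999"
  extra$ks_tmrm_peripheral_integral <- 0.4
  ws3 <- dplyr::bind_rows(ws, extra)
  sc3 <- build_scrit(ws3, parameters = c("tmrm_peripheral_integral",
                                         "viability"))
  comp <- paste("tmrm_peripheral_integral", extra$condition,
                signif(extra$dose, 3), sep = "|")
  expect_equal(sc3[[comp]], 0.2)
})

test_that("incomplete vectors are excluded with a recorded reason", {
  ws <- fake_well_stats(compounds = c("a", "b"),
                        doses = dose_series(100, 3, 4))
  drop_cell <- ws$role == "test" & ws$compound == "b" &
    ws$dose == max(ws$dose) & ws$condition == "glu_minus"
  expect_warning(
    sc <- build_scrit(ws[!drop_cell, ],
                      parameters = c("tmrm_peripheral_integral",
                                     "viability")),
    "incomplete")
  expect_equal(sc$compound, "a")
  expect_equal(attr(sc, "incomplete")$compound, "b")
})

test_that("truncation filters components and composes", {
  ws <- fake_well_stats(doses = dose_series(100, 3, 10),
                        ks_parameters = c("tmrm_peripheral_integral",
                                          "hoechst_mean"))
  s60 <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                        "hoechst_mean", "viability"))
  glu <- truncate_scrit(s60, conditions = "glu_plus")
  expect_equal(nrow(scrit_index_map(glu)), 30)
  s40 <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                        "viability"))
  tm <- truncate_scrit(s40, parameters = "tmrm_peripheral_integral")
  expect_equal(nrow(scrit_index_map(tm)), 20)
  # truncation then truncation equals the combined truncation
  both1 <- truncate_scrit(truncate_scrit(s60, conditions = "glu_plus"),
                          parameters = "viability")
  both2 <- truncate_scrit(s60, conditions = "glu_plus",
                          parameters = "viability")
  expect_equal(as.data.frame(both1), as.data.frame(both2))
  expect_error(truncate_scrit(s60, parameters = "no_such"),
               class = "scritscreen_contract_error")
})

test_that("SCRIT tables round-trip through TSV + JSON sidecar", {
  ws <- fake_well_stats(compounds = c("a", "b"),
                        doses = dose_series(100, 3, 5), ks_value = -0.3,
                        viability = 0.8)
  sc <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                       "viability"))
  path <- file.path(withr::local_tempdir(), "scrit.tsv")
  write_scrit(sc, path)
  back <- read_scrit(path)
  expect_equal(as.data.frame(back), as.data.frame(sc), ignore_attr = TRUE)
  expect_equal(scrit_index_map(back)$component, scrit_index_map(sc)$component)
  expect_equal(attr(back, "control_viability"), attr(sc, "control_viability"))
})

test_that("the 20% activity cut-off drives primary-screen calls", {
  pars7 <- c(setdiff(feature_names(), "topro_mean"), "viability")
  ws <- fake_well_stats(doses = 100,
                        ks_parameters = setdiff(pars7, "viability"))
  quiet <- build_scrit(ws, parameters = pars7)
  res <- primary_screen_select(quiet)
  expect_false(res$active)
  expect_equal(res$group, "IV")
  # one KS component at 0.25 triggers activity
  active <- quiet
  active[[scrit_index_map(quiet)$component[1]]] <- 0.25
  res2 <- primary_screen_select(active)
  expect_true(res2$active)
  expect_equal(res2$triggers[[1]], scrit_index_map(quiet)$component[1])
  # a 15-point viability drop alone stays below the cut-off
  ws3 <- fake_well_stats(doses = 100,
                         ks_parameters = setdiff(pars7, "viability"),
                         viability = 0.85)
  res3 <- primary_screen_select(build_scrit(ws3, parameters = pars7))
  expect_false(res3$active)
  # a 25-point drop crosses it
  ws4 <- fake_well_stats(doses = 100,
                         ks_parameters = setdiff(pars7, "viability"),
                         viability = 0.75)
  res4 <- primary_screen_select(build_scrit(ws4, parameters = pars7))
  expect_true(res4$active)
  # wrong shape is a contract error
  ws10 <- fake_well_stats(doses = dose_series(100, 3, 10))
  s40 <- build_scrit(ws10, parameters = c("tmrm_peripheral_integral",
                                          "viability"))
  expect_error(primary_screen_select(s40),
               class = "scritscreen_contract_error")
})

test_that("replicate consistency flags discordant compounds", {
  ws <- fake_well_stats(replicates = 1:2, doses = dose_series(100, 3, 10))
  sc <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                       "viability"))
  im <- scrit_index_map(sc)
  m <- scrit_matrix(sc)
  # craft replicate 1 as a clean dose response, replicate 2 uncorrelated
  resp <- -tanh(seq(0, 3, length.out = 20))
  sc[1, im$component] <- as.list(c(resp, rev(resp)) / 2)
  sc[2, im$component] <- as.list(withr::with_seed(5, runif(40, -0.5, 0.5)))
  rc <- replicate_consistency(sc)
  expect_true(rc$report$outlier)
  expect_gt(rc$report$max_distance, 0.2)
  expect_equal(nrow(rc$kept), 0)
  # identical replicates pass at distance zero
  sc[2, im$component] <- sc[1, im$component]
  rc2 <- replicate_consistency(sc)
  expect_false(rc2$report$outlier)
  expect_equal(rc2$report$max_distance, 0)
  expect_equal(nrow(rc2$kept), 2)
  # a single replicate passes with a warning
  expect_warning(rc3 <- replicate_consistency(sc[1, ]), "single replicate")
  expect_false(rc3$report$outlier)
})
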