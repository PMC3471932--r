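test_that("signed KS satisfies identity, antisymmetry and range", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(signed_ks(x, x), 0)
  expect_equal(signed_ks(c(5, 6, 7), c(1, 2, 3)), 1)   # sample above ref
  expect_equal(signed_ks(c(1, 2, 3), c(5, 6, 7)), -1)  # sample below ref
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- rnorm(sample(1:40, 1))
      b <- rnorm(sample(1:40, 1), mean = runif(1, -2, 2))
      expect_equal(signed_ks(a, b), -signed_ks(b, a))
      expect_true(abs(signed_ks(a, b)) <= 1)
    }
  })
  expect_error(signed_ks(numeric(0), x), class = "scritscreen_domain_error")
})

test_that("signed KS equals the brute-force breakpoint scan exactly", {
  withr::with_seed(202, {
    for (i in 1:300) {
      n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
      # include ties by rounding half the draws
      a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
      if (i %% 2 == 0) { a <- round(a, 1); b <- round(b, 1) }
      expect_identical(signed_ks(a, b), brute_force_signed_ks(a, b))
    }
  })
})

test_that("|signed KS| matches the classical two-sample statistic", {
  withr::with_seed(303, {
    for (i in 1:100) {
      a <- rnorm(sample(5:50, 1))
      b <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
      ks <- suppressWarnings(stats::ks.test(a, b)$statistic)
      expect_equal(abs(signed_ks(a, b)), unname(ks))
    }
  })
})

test_that("signed KS is invariant under monotone transforms and
           monotone under stochastic dominance shifts", {
  withr::with_seed(404, {
    for (i in 1:50) {
      a <- rlnorm(30); b <- rlnorm(25, meanlog = runif(1, -1, 1))
      d0 <- signed_ks(a, b)
      expect_equal(signed_ks(log(a), log(b)), d0)
      expect_equal(signed_ks(a^3, b^3), d0)
      expect_gte(signed_ks(a + 0.5, b), d0)
    }
  })
})

test_that("TO-PRO-3 gate detection finds the mixture valley", {
  withr::with_seed(7, {
    mix <- c(rlnorm(2000, log(10^2.5), 0.25 * log(10)),
             rlnorm(2000, log(10^4), 0.25 * log(10)))
    g <- choose_topro_gate(mix)
    expect_equal(attr(g, "method"), "valley")
    expect_gte(as.numeric(g), 1.8e3)
    expect_lte(as.numeric(g), 2.5e3)
    # analytic valley of a symmetric mixture sits at the log midpoint
    mix2 <- c(rlnorm(4000, log(10^2), 0.2 * log(10)),
              rlnorm(4000, log(10^5), 0.2 * log(10)))
    g2 <- choose_topro_gate(mix2)
    expect_lt(abs(attr(g2, "log10") - 3.5), 0.05)
    # unimodal plate falls back to the default gate
    uni <- rlnorm(3000, log(10^2.5), 0.25 * log(10))
    g3 <- choose_topro_gate(uni)
    expect_equal(attr(g3, "method"), "default")
    expect_equal(as.numeric(g3), 10^3.25)
    # too few cells also falls back
    expect_equal(attr(choose_topro_gate(mix[1:50]), "method"), "default")
  })
})

test_that("viability fraction and rescaling hit their endpoints", {
  expect_equal(viability_fraction(c(10, 20, 30), gate = 100), 1)
  expect_equal(viability_fraction(c(1e4, 2e4), gate = 100), 0)
  expect_error(viability_fraction(numeric(0), 100),
               class = "scritscreen_domain_error")
  expect_equal(rescale_viability(1), 1)
  expect_equal(rescale_viability(0), -1)
  expect_equal(rescale_viability(0.5), 0)
  expect_error(rescale_viability(1.2), class = "scritscreen_domain_error")
})

test_that("Z' follows the closed form", {
  expect_equal(zprime(0.8, 0, 0.05, 0.05)$z_prime, 0.625)
  expect_equal(zprime(0.5, 0.1, 0, 0)$z_prime, 1)
  expect_error(zprime(0.3, 0.3, 0.1, 0.1), class = "scritscreen_qc_error")
})

test_that("pooled control concatenates negative-control cells", {
  lay <- build_control_plate(1)
  feats <- simulate_plate(lay, seed = 2, n_cells = 60)
  pooled <- pooled_control(feats, lay, "tmrm_peripheral_integral")
  n_neg <- sum(feats$well %in% lay$well[lay$role == "negative_control"])
  expect_length(pooled, n_neg)
  expect_false(is.unsorted(pooled))
  no_neg <- lay[lay$role == "positive_control", ]
  expect_error(pooled_control(feats, no_neg, "tmrm_peripheral_integral"),
               class = "scritscreen_qc_error")
})

test_that("well statistics flag sparse wells and record the gate", {
  lay <- build_control_plate(1)
  feats <- simulate_plate(lay, seed = 6, n_cells = 100)
  # starve one well below the cell-count floor
  w0 <- lay$well[1]
  feats <- feats[!(feats$well == w0 & feats$cell > 10), ]
  ws <- well_statistics(feats, lay, min_cells = 50)
  expect_equal(nrow(ws), nrow(lay))
  expect_true(ws$excluded[ws$well == w0])
  expect_match(ws$reason[ws$well == w0], "min 50")
  expect_true(all(is.na(ws$ks_tmrm_peripheral_integral[ws$well == w0])))
  done <- ws[!ws$excluded, ]
  expect_true(all(abs(done$ks_tmrm_peripheral_integral) <= 1))
  expect_true(all(done$viability_rescaled == 2 * done$viability - 1))
  expect_equal(unique(ws$gate), ws$gate[1])
})

test_that("control-plate Z' on KS distances lands in the expected window", {
  qc <- run_control_qc(seed = 1)
  expect_equal(sum(qc$well_stats$role == "positive_control"), 48)
  expect_equal(sum(qc$well_stats$role == "negative_control"), 48)
  expect_gte(qc$zprime$z_prime, 0.6)
  expect_lte(qc$zprime$z_prime, 0.7)
  # the intra-plate CV of the positive-control KS is reported
  cv <- qc$control_summary$cv_ks[
    qc$control_summary$role == "positive_control" &
      qc$control_summary$parameter == "tmrm_peripheral_integral"]
  expect_true(is.finite(cv))
})

test_that("plate QC is deterministic and degrades gracefully", {
  lay <- build_control_plate(1)
  feats <- simulate_plate(lay, seed = 3, n_cells = 100)
  q1 <- plate_qc(feats, lay)
  q2 <- plate_qc(feats, lay)
  expect_identical(tidy(q1), tidy(q2))
  expect_identical(glance(q1), glance(q2))
  neg_only <- lay[lay$role == "negative_control", ]
  feats_neg <- feats[feats$well %in% neg_only$well, ]
  expect_warning(qn <- plate_qc(feats_neg, neg_only), "Z' omitted")
  expect_null(qn$zprime)
  expect_true(is.na(glance(qn)$z_prime))
})
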