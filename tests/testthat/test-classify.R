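test_that("Pearson distance endpoints and formula agreement", {
  u <- c(1, 2, 3, 5, 4)
  expect_equal(pearson_distance(u, u), 0)
  expect_equal(pearson_distance(u, 10 - u), 2)
  expect_equal(pearson_distance(c(1, -1, 1, -1), c(1, 1, -1, -1)), 1)
  withr::with_seed(8, {
    for (i in 1:100) {
      a <- rnorm(sample(3:30, 1)); b <- rnorm(length(a))
      direct <- 1 - sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      expect_equal(pearson_distance(a, b), direct, tolerance = 1e-12)
      # affine invariance with positive slope
      expect_equal(pearson_distance(2.5 * a + 3, b), pearson_distance(a, b))
    }
  })
  expect_warning(d <- pearson_distance(rep(1, 5), u), "near-constant")
  expect_equal(d, 1)
  expect_error(pearson_distance(u, u[1:3]),
               class = "scritscreen_contract_error")
  expect_error(pearson_distance(1:2, 2:1),
               class = "scritscreen_contract_error")
})

make_scrit_from_matrix <- function(m, doses = NULL) {
  # 2 parameters x 1 condition x (ncol / 2) doses
  doses <- doses %||% dose_series(100, 3, ncol(m) / 2)
  ws <- fake_well_stats(compounds = rownames(m), doses = doses,
                        conditions = "glu_plus")
  sc <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                       "viability"),
                    conditions = "glu_plus")
  sc <- sc[match(rownames(m), sc$compound), ]
  im <- scrit_index_map(sc)
  for (i in seq_len(nrow(m))) sc[i, im$component] <- as.list(m[i, ])
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("distance matrices are symmetric with the requested metric", {
  m <- rbind(a = c(rep(0, 3), rep(1, 3)), b = c(rep(0, 3), rep(1, 3)),
             c = c(rep(0, 3), rep(1, 3)))
  sc <- make_scrit_from_matrix(m)
  d <- scrit_dist(sc, metric = "pearson")
  expect_true(all(as.vector(d) == 0))
  m2 <- rbind(a = c(0, 0, 1, 1, 1, 0), b = c(3, 4, 1, 1, 1, 0))
  sc2 <- make_scrit_from_matrix(m2)
  d2 <- scrit_dist(sc2, metric = "euclidean")
  expect_equal(as.vector(d2), 5)
  dm <- as.matrix(scrit_dist(sc2, metric = "pearson"))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c(0, 0), ignore_attr = TRUE)
})

test_that("average-linkage clustering matches a hand trace", {
  # 4 items with distances: ab=1, cd=2, (ac,ad,bc,bd)=5,6,7,8
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 1
  dm["c", "d"] <- dm["d", "c"] <- 2
  dm["a", "c"] <- dm["c", "a"] <- 5
  dm["a", "d"] <- dm["d", "a"] <- 6
  dm["b", "c"] <- dm["c", "b"] <- 7
  dm["b", "d"] <- dm["d", "b"] <- 8
  hc <- hierarchical_cluster(stats::as.dist(dm))
  # merges: (a,b)@1, (c,d)@2, ((a,b),(c,d))@ mean(5,6,7,8)=6.5
  expect_equal(hc$height, c(1, 2, 6.5))
  expect_true(all(diff(hc$height) >= 0))
  # two items merge at exactly their distance
  hc2 <- hierarchical_cluster(stats::as.dist(dm[1:2, 1:2]))
  expect_equal(hc2$height, 1)
  # duplicated items merge first at height zero
  dm3 <- dm
  dm3["a", "b"] <- dm3["b", "a"] <- 0
  hc3 <- hierarchical_cluster(stats::as.dist(dm3))
  expect_equal(hc3$height[1], 0)
})

test_that("classical MDS reproduces planar configurations", {
  # collinear points at 0, 1, 2: 1-D embedding is exact
  dm <- stats::as.dist(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  emb1 <- mds_embed(dm, dims = 1)
  expect_equal(as.vector(dist(emb1$mds1)), c(1, 2, 1), tolerance = 1e-9)
  # distances generated from true 2-D points are reproduced
  withr::with_seed(12, {
    pts <- matrix(rnorm(20), 10, 2)
    rownames(pts) <- paste0("p", 1:10)
    d <- dist(pts)
    emb <- mds_embed(d, dims = 2)
    expect_equal(as.vector(dist(as.matrix(emb[, c("mds1", "mds2")]))),
                 as.vector(d), tolerance = 1e-9)
  })
  # duplicated items land on identical coordinates
  dm4 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  # duplicated points give rank-1 geometry: embedding reduces with warning
  expect_warning(emb4 <- mds_embed(stats::as.dist(dm4), dims = 2),
                 "reduced")
  expect_equal(emb4$mds1[1], emb4$mds1[2])
  # requesting more dimensions than the geometry supports warns
  w <- testthat::capture_warnings(mds_embed(dm, dims = 3))
  expect_true(any(grepl("reduced", w)))
})

test_that("group assignment labels archetypal fingerprints correctly", {
  doses <- dose_series(100, 3, 10)
  pars <- c("tmrm_peripheral_integral", "hoechst_mean", "viability")
  archs <- c(I = "I_direct_mito", II = "II_glu_independent",
             III = "III_glu_dependent", IV = "IV_inactive",
             V = "V_uncoupler")
  m <- t(vapply(archs, function(a) {
    expected_scrit(make_phenotype_model(a), parameters = pars,
                   doses = doses)
  }, numeric(60)))
  rownames(m) <- names(archs)
  ws <- fake_well_stats(compounds = rownames(m), doses = doses,
                        ks_parameters = c("tmrm_peripheral_integral",
                                          "hoechst_mean"))
  sc <- build_scrit(ws, parameters = pars)
  sc <- sc[match(rownames(m), sc$compound), ]
  im <- scrit_index_map(sc)
  for (i in seq_len(nrow(m))) sc[i, im$component] <- as.list(m[i, ])
  d <- suppressWarnings(scrit_dist(sc, metric = "pearson"))
  hc <- hierarchical_cluster(d)
  groups <- suppressWarnings(assign_groups(hc, sc, k = 5, d = d))
  expect_equal(groups$group[match(names(archs), groups$compound)],
               names(archs))
  # an all-flat vector is labeled group IV
  expect_equal(groups$group[groups$compound == "IV"], "IV")
})

test_that("classification bundles serialize to a results directory", {
  ws <- fake_well_stats(compounds = letters[1:4],
                        doses = dose_series(100, 3, 5), ks_value = -0.4,
                        viability = 0.7)
  sc <- build_scrit(ws, parameters = c("tmrm_peripheral_integral",
                                       "viability"))
  im <- scrit_index_map(sc)
  withr::with_seed(3, {
    for (i in 1:4) {
      sc[i, im$component] <- as.list(runif(20, -1, 1))
    }
  })
  cl <- classify_scrit(sc, k = 2)
  dir <- withr::local_tempdir()
  write_classification(cl, dir)
  expect_true(all(file.exists(file.path(
    dir, c("distance_matrix.tsv", "dendrogram.nwk", "mds.tsv",
           "groups.tsv", "run.json")))))
  nwk <- readLines(file.path(dir, "dendrogram.nwk"))
  expect_match(nwk, "^\\(.*\\);$")
  expect_equal(nrow(tidy(cl)), 4)
  expect_equal(glance(cl)$n_items, 4)
})
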