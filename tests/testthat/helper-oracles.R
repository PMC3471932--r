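# Shared test helpers: independent oracles and fixture builders.

# Brute-force signed KS: scan every breakpoint of the pooled support and
# report the signed CDF difference at the first (smallest-x) maximum of
# |F_ref - F_sample|. Independent of the package's implementation.
brute_force_signed_ks <- function(sample, reference) {
  xs <- sort(unique(c(sample, reference)))
  best <- 0
  for (x in xs) {
    d <- mean(reference <= x) - mean(sample <= x)
    if (abs(d) > abs(best)) best <- d
  }
  best
}

# A bright, noiseless feature table for renderer round trips: every cell
# sits safely above the segmentation threshold.
bright_cells <- function(areas, hoechst_mean = 6500, tmrm = 1e6,
                         tmrm_max = 4000, topro = 400) {
  n <- length(areas)
  tibble::tibble(
    well = "A01", field = 1L, cell = seq_len(n),
    tmrm_peripheral_integral = rep_len(tmrm, n),
    tmrm_max_pixel = rep_len(tmrm_max, n),
    hoechst_integral = hoechst_mean * areas / 0.25,
    hoechst_mean = rep_len(hoechst_mean, n),
    nuclear_area = areas,
    nuclear_circularity = 0.95,
    topro_mean = rep_len(topro, n)
  )
}

# Draw anti-aliased disks of one intensity into a blank field (no noise).
disk_image <- function(centers, radius_px, value = 6000,
                       nx = 300, ny = 300) {
  h <- matrix(0, nx, ny)
  for (k in seq_len(nrow(centers))) {
    dmat <- sqrt(outer((seq_len(nx) - centers[k, 1])^2,
                       (seq_len(ny) - centers[k, 2])^2, "+"))
    h <- pmax(h, value * pmin(pmax(radius_px + 0.5 - dmat, 0), 1))
  }
  field_image(h, matrix(0, nx, ny), matrix(0, nx, ny))
}

# Minimal hand-built well-statistics table covering a full
# parameters x conditions x doses grid for SCRIT assembly tests.
fake_well_stats <- function(compounds = "cmpA", replicates = 1L,
                            doses = dose_series(100, 3, 10),
                            conditions = c("glu_plus", "glu_minus"),
                            ks_parameters = c("tmrm_peripheral_integral"),
                            ks_value = 0, viability = 1) {
  grid <- expand.grid(compound = compounds, replicate = replicates,
                      condition = conditions, dose = doses,
                      stringsAsFactors = FALSE)
  ws <- tibble::as_tibble(grid)
  ws$well <- sprintf("W%03d", seq_len(nrow(ws)))
  ws$role <- "test"
  ws$excluded <- FALSE
  for (p in ks_parameters) ws[[paste0("ks_", p)]] <- ks_value
  ws$viability <- viability
  ws$viability_rescaled <- 2 * viability - 1
  neg <- ws[!duplicated(ws$condition), ]
  neg$compound <- "DMSO"
  neg$dose <- 0
  neg$role <- "negative_control"
  neg$well <- sprintf("N%03d", seq_len(nrow(neg)))
  for (p in ks_parameters) neg[[paste0("ks_", p)]] <- 0
  neg$viability <- 1
  neg$viability_rescaled <- 1
  dplyr::bind_rows(ws, neg)
}
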