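# Synthetic field rendering: turns per-cell feature rows into the three
# fluorescence channels so segmentation can be tested end-to-end.

#' Field image container
#'
#' @param hoechst,tmrm,topro numeric intensity matrices (a.u.), identical
#'   dimensions, x (along the 500 um axis) in rows.
#' @param pixel_size pixel edge length(s) in um; a scalar means square
#'   pixels (the default geometry is square 0.5 um; the instrument's
#'   nominal 0.5 x 0.48 um rectangle is accepted as a length-2 value).
#' @return object of class `field_image`.
#' @export
field_image <- function(hoechst, tmrm, topro, pixel_size = 0.5) {
  stopifnot(identical(dim(hoechst), dim(tmrm)),
            identical(dim(hoechst), dim(topro)))
  if (any(hoechst < 0) || any(tmrm < 0) || any(topro < 0)) {
    stop_domain("channel intensities must be >= 0")
  }
  structure(list(hoechst = hoechst, tmrm = tmrm, topro = topro,
                 pixel_size = rep(pixel_size, length.out = 2)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px (%.3g x %.3g um), 3 channels\n",
              nrow(x$hoechst), ncol(x$hoechst),
              nrow(x$hoechst) * x$pixel_size[1],
              ncol(x$hoechst) * x$pixel_size[2]))
  invisible(x)
}

default_field_px <- function(pixel_size = 0.5) {
  ps <- rep(pixel_size, length.out = 2)
  c(floor(500 / ps[1]), floor(368.6 / ps[2]))
}

#' Render a field image from per-cell features
#'
#' Draws each table row as an anti-aliased disk in the Hoechst channel
#' whose area and integrated intensity match the row, a TO-PRO-3 disk
#' co-located with the nucleus, and a perinuclear TMRM annulus carrying
#' the row's peripheral integral with one pixel at the row's max-pixel
#' intensity. Nuclear radii are pre-compensated for the erosion that the
#' 5x5 smoothing + fixed threshold of the segmentation stage applies, so
#' the rendered geometry round-trips through [segment_nuclei()]. Centers
#' are placed by rejection sampling without overlap (ring-to-ring contact
#' is allowed); cells that cannot be placed are dropped with a warning.
#' Gaussian background noise stays well below the segmentation threshold.
#'
#' @param table `cell_features` rows to draw (one field's worth).
#' @param pixel_size pixel size in um (scalar = square).
#' @param dim_px image size in pixels; default is the 500 x 368.6 um field.
#' @param seed placement/noise seed.
#' @param threshold segmentation threshold the radii are compensated for.
#' @param bg_mean,bg_sd background noise parameters (a.u.).
#' @param max_tries rejection-sampling attempts per cell.
#' @return a `field_image`; dropped row indices in attribute `"dropped"`.
#' @export
render_well_image <- function(table, pixel_size = 0.5,
                              dim_px = default_field_px(pixel_size),
                              seed = 1L, threshold = 2500,
                              bg_mean = 200, bg_sd = 50,
                              max_tries = 200) {
  table <- as_cell_features(table)
  ps <- rep(pixel_size, length.out = 2)
  px_area <- prod(ps)
  nx <- dim_px[1]; ny <- dim_px[2]
  withr::with_seed(as.integer(seed), {
    hoechst <- matrix(pmax(rnorm(nx * ny, bg_mean, bg_sd), 0), nx, ny)
    tmrm <- matrix(pmax(rnorm(nx * ny, bg_mean / 10, bg_sd / 10), 0), nx, ny)
    topro <- matrix(pmax(rnorm(nx * ny, bg_mean / 10, bg_sd / 10), 0), nx, ny)
    n <- nrow(table)
    if (n == 0) return(field_image(hoechst, tmrm, topro, pixel_size))
    r_nuc <- sqrt(table$nuclear_area / px_area / pi)
    # Self-consistent draw radius R and paint intensity I: the 5x5
    # smoothing + threshold erode a disk of intensity I by about
    # 5 * threshold / I - 2.5 px (straight-edge model), and conserving the
    # row's integrated intensity ties I to R (I = integral / (pi R^2)).
    # Substituting gives a*R^2 - R + (r - 2.5) = 0 with
    # a = 5 * threshold * pi / integral; the physical root recovers the
    # nominal radius r after segmentation.
    a <- 5 * threshold * pi / table$hoechst_integral
    disc <- pmax(1 - 4 * a * (r_nuc - 2.5), 0)
    r_draw <- (1 - sqrt(disc)) / (2 * a)
    # Dim nuclei (implied paint intensity within ~25% of the threshold)
    # have no radius/intensity pair that conserves both area and integral
    # through the smoothing + threshold; they are painted at the minimum
    # reliably-segmentable intensity instead, conserving count and area at
    # the cost of some integral fidelity -- near-threshold nuclei are
    # photometrically unreliable on the instrument too.
    paint_min <- 1.25 * threshold
    implied_I <- table$hoechst_integral / (pi * r_draw^2)
    dim_cell <- !is.finite(implied_I) | implied_I < paint_min | disc <= 0
    r_draw[dim_cell] <- r_nuc[dim_cell] + 1.5 # erosion at paint_min
    paint_floor <- ifelse(dim_cell, paint_min, 0)
    # ring painted fully inside the extraction ring (4 px expansion +
    # 14 px peripheral band)
    ring_in <- r_draw + 5
    ring_out <- r_draw + 13
    margin <- ring_out + 2
    centers <- matrix(NA_real_, n, 2)
    dropped <- integer(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- runif(1, margin[i], nx - margin[i])
        cy <- runif(1, margin[i], ny - margin[i])
        ok <- TRUE
        if (i > 1) {
          prev <- which(!is.na(centers[seq_len(i - 1), 1]))
          if (length(prev) > 0) {
            dd <- sqrt((centers[prev, 1] - cx)^2 + (centers[prev, 2] - cy)^2)
            ok <- all(dd > ring_out[prev] + ring_out[i] + 2)
          }
        }
        if (ok) {
          centers[i, ] <- c(cx, cy)
          placed <- TRUE
          break
        }
      }
      if (!placed) dropped <- c(dropped, i)
    }
    if (length(dropped) > 0) {
      warn(sprintf("field too crowded: %d cell(s) dropped", length(dropped)))
    }
    for (i in setdiff(seq_len(n), dropped)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      R <- ceiling(ring_out[i]) + 1
      xs <- max(1, floor(cx - R)):min(nx, ceiling(cx + R))
      ys <- max(1, floor(cy - R)):min(ny, ceiling(cy + R))
      dmat <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
      cover <- pmin(pmax(r_draw[i] + 0.5 - dmat, 0), 1)
      paint_val <- max(table$hoechst_integral[i] / sum(cover),
                       paint_floor[i])
      hoechst[xs, ys] <- hoechst[xs, ys] + paint_val * cover
      # TO-PRO-3 is read out as a mean over the 4-px-expanded primary
      # region, so its disk is painted over that footprint
      cover_exp <- pmin(pmax(r_draw[i] + 6.5 - dmat, 0), 1)
      topro[xs, ys] <- topro[xs, ys] + table$topro_mean[i] * cover_exp
      ring <- dmat >= ring_in[i] & dmat <= ring_out[i]
      n_ring <- sum(ring)
      if (n_ring > 0) {
        val <- table$tmrm_peripheral_integral[i] / n_ring
        block <- tmrm[xs, ys]
        block[ring] <- block[ring] + val
        # one max-pixel hotspot on the ring
        hot <- which(ring)[1]
        block[hot] <- max(block[hot], table$tmrm_max_pixel[i])
        tmrm[xs, ys] <- block
      }
    }
    img <- field_image(hoechst, tmrm, topro, pixel_size)
    attr(img, "dropped") <- dropped
    attr(img, "centers") <- centers
    img
  })
}

#' Write / read a field image as per-channel 16-bit TIFFs
#'
#' Files are named `<prefix>_<channel>.tif`; intensities are stored as
#' 16-bit grayscale (a.u. clipped to 0..65535).
#'
#' @param image a `field_image`.
#' @param prefix path prefix.
#' @return the three file paths (write) or a `field_image` (read).
#' @export
write_field_image <- function(image, prefix) {
  paths <- character(0)
  for (ch in c("hoechst", "tmrm", "topro")) {
    p <- paste0(prefix, "_", ch, ".tif")
    m <- pmin(pmax(image[[ch]], 0), 65535) / 65535
    EBImage::writeImage(EBImage::Image(m), p, type = "tiff",
                        bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_image
#' @param pixel_size pixel size to record on the read image.
#' @export
read_field_image <- function(prefix, pixel_size = 0.5) {
  ch <- lapply(c("hoechst", "tmrm", "topro"), function(x) {
    m <- EBImage::imageData(EBImage::readImage(paste0(prefix, "_", x, ".tif")))
    m * 65535
  })
  field_image(ch[[1]], ch[[2]], ch[[3]], pixel_size)
}
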