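# Nuclear segmentation and per-cell feature extraction, mirroring the
# imaging cytometer's contour protocol: threshold + 5x5 low-pass + watershed
# on the Hoechst channel, area filter, 4-px expanded primary contours and a
# 14-px peripheral ring.

#' Segment nuclei from the Hoechst channel
#'
#' Pixels of the 5x5 box-smoothed Hoechst channel above the fixed threshold
#' (2500 a.u.) form candidate nuclei; touching nuclei are split by a
#' watershed on the distance transform of the thresholded mask; labels
#' outside the area window (20-250 um^2: debris and clumps) are removed.
#' Deterministic; a blank image yields an empty mask.
#'
#' @param image a `field_image`.
#' @param threshold intensity threshold in a.u.
#' @param min_area,max_area area filter bounds in um^2.
#' @param smooth apply the 5x5 low-pass filter (disable only for tests).
#' @param watershed_tolerance minimum depth between distance-map maxima for
#'   a split (px).
#' @return object of class `labeled_mask`: list with `labels` (integer
#'   matrix, 0 = background, labels contiguous 1..N), `table` (per-label
#'   `label`, `area` um^2, `centroid_x/y` px, `perimeter` px,
#'   `circularity` = 4 pi A / P^2 clamped to (0, 1]) and `pixel_size`.
#' @export
segment_nuclei <- function(image, threshold = 2500,
                           min_area = 20, max_area = 250,
                           smooth = TRUE, watershed_tolerance = 1) {
  if (!inherits(image, "field_image")) {
    stop_contract("`image` must be a field_image")
  }
  ps <- image$pixel_size
  px_area <- prod(ps)
  h <- image$hoechst
  if (smooth) h <- EBImage::filter2(h, matrix(1 / 25, 5, 5))
  mask <- h > threshold
  empty <- structure(
    list(labels = matrix(0L, nrow(h), ncol(h)),
         table = tibble(label = integer(0), area = numeric(0),
                        centroid_x = numeric(0), centroid_y = numeric(0),
                        perimeter = numeric(0), circularity = numeric(0)),
         pixel_size = ps),
    class = "labeled_mask")
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                               ext = 1))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * px_area >= min_area & counts * px_area <= max_area)
  if (length(keep) == 0) return(empty)
  relabel <- integer(length(counts))
  relabel[keep] <- seq_along(keep)
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  new_lab[nz] <- relabel[lab[nz]]
  shp <- EBImage::computeFeatures.shape(new_lab)
  mom <- EBImage::computeFeatures.moment(new_lab)
  area_um <- shp[, "s.area"] * px_area
  circ <- pmin(4 * pi * shp[, "s.area"] / shp[, "s.perimeter"]^2, 1)
  structure(
    list(labels = new_lab,
         table = tibble(label = seq_along(keep),
                        area = unname(area_um),
                        centroid_x = unname(mom[, "m.cx"]),
                        centroid_y = unname(mom[, "m.cy"]),
                        perimeter = unname(shp[, "s.perimeter"]),
                        circularity = unname(circ)),
         pixel_size = ps),
    class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d nuclei in a %d x %d px field\n",
              nrow(x$table), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Extract the seven per-cell features
#'
#' Primary contours are expanded by `expand` pixels; the peripheral
#' (cytoplasmic) contour is a ring of `ring_width` pixels beyond the
#' expanded region. Where expansions or rings of neighbouring cells would
#' overlap, each pixel goes to the nearest label (geodesic propagation), so
#' nothing is double-counted; ring and expanded-primary pixel sets are
#' disjoint by construction. Per label: Hoechst integral and mean over the
#' expanded primary region, nuclear area and circularity from the primary
#' contour, TMRM integral and max pixel over the ring, TO-PRO-3 mean over
#' the expanded region. Rings clipped by the field border are flagged in
#' the `qc_ring_clipped` column.
#'
#' @param mask a `labeled_mask` from [segment_nuclei()].
#' @param image the matching `field_image`.
#' @param expand primary-contour expansion in pixels.
#' @param ring_width peripheral ring width in pixels.
#' @param well,field ids recorded in the output table.
#' @return a `cell_features` tibble (one row per label) with an extra
#'   `qc_ring_clipped` logical column.
#' @export
extract_features <- function(mask, image, expand = 4, ring_width = 14,
                             well = "A01", field = 1L) {
  if (!inherits(mask, "labeled_mask")) {
    stop_contract("`mask` must come from segment_nuclei()")
  }
  lab <- mask$labels
  if (!identical(dim(lab), dim(image$hoechst))) {
    stop_contract("mask and image dimensions differ")
  }
  n <- nrow(mask$table)
  if (n == 0) {
    return(as_cell_features(tibble(
      well = character(0), field = integer(0), cell = integer(0),
      tmrm_peripheral_integral = numeric(0), tmrm_max_pixel = numeric(0),
      hoechst_integral = numeric(0), hoechst_mean = numeric(0),
      nuclear_area = numeric(0), nuclear_circularity = numeric(0),
      topro_mean = numeric(0), qc_ring_clipped = logical(0))))
  }
  fg <- lab > 0
  disc <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  exp_mask <- EBImage::dilate(fg, disc(expand)) > 0
  exp_lab <- EBImage::imageData(
    EBImage::propagate(image$hoechst, seeds = lab, mask = exp_mask))
  zone_mask <- EBImage::dilate(exp_mask, disc(ring_width)) > 0
  zone_lab <- EBImage::imageData(
    EBImage::propagate(image$hoechst, seeds = exp_lab, mask = zone_mask))
  ring_lab <- zone_lab
  ring_lab[exp_mask] <- 0L
  border <- matrix(FALSE, nrow(lab), ncol(lab))
  border[c(1, nrow(lab)), ] <- TRUE
  border[, c(1, ncol(lab))] <- TRUE
  sum_by <- function(vals, labs) {
    s <- rep(0, n)
    t <- tapply(vals[labs > 0], labs[labs > 0], sum)
    s[as.integer(names(t))] <- t
    s
  }
  count_by <- function(labs) {
    s <- rep(0L, n)
    t <- tabulate(labs[labs > 0], nbins = n)
    s[seq_len(n)] <- t
    s
  }
  max_by <- function(vals, labs) {
    s <- rep(0, n)
    t <- tapply(vals[labs > 0], labs[labs > 0], max)
    s[as.integer(names(t))] <- t
    s
  }
  exp_n <- count_by(exp_lab)
  ring_n <- count_by(ring_lab)
  hoechst_int <- sum_by(image$hoechst, exp_lab)
  topro_sum <- sum_by(image$topro, exp_lab)
  tmrm_int <- sum_by(image$tmrm, ring_lab)
  tmrm_max <- max_by(image$tmrm, ring_lab)
  clipped <- as.logical(sum_by(border, zone_lab) > 0)
  as_cell_features(tibble(
    well = well, field = as.integer(field), cell = mask$table$label,
    tmrm_peripheral_integral = tmrm_int,
    tmrm_max_pixel = tmrm_max,
    hoechst_integral = hoechst_int,
    hoechst_mean = hoechst_int / pmax(exp_n, 1),
    nuclear_area = mask$table$area,
    nuclear_circularity = mask$table$circularity,
    topro_mean = topro_sum / pmax(exp_n, 1),
    qc_ring_clipped = clipped))
}
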