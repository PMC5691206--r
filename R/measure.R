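# Otsu threshold of an intensity sample (values in [0, 1])
.otsu <- function(x) {
  EBImage::otsu(EBImage::Image(matrix(x, ncol = 1)), range = c(0, 1))
}

# Multi-level threshold detection. Bright-field frames carry up to four
# intensity populations (film brightest, background, particle speckle,
# aureole/aggregate darkest), so a single Otsu split cannot isolate the
# extremes. A 1D Lloyd k-means (k = 4, centers seeded evenly over the
# intensity range, empty clusters dropped, centers closer than `merge_tol`
# merged) recovers the population centers; the bright threshold is the
# midpoint between the two brightest classes and the dark threshold the
# midpoint between the two darkest (or -Inf when no dark class exists).
.threshold_levels <- function(x, k = 4, merge_tol = 0.08, iters = 50) {
  if (length(x) > 2e5) x <- x[seq(1, length(x), length.out = 2e5)]
  centers <- seq(min(x), max(x), length.out = k)
  for (i in seq_len(iters)) {
    assign <- findInterval(x, (centers[-1] + centers[-length(centers)]) / 2) + 1
    new_c <- vapply(seq_along(centers), function(j) {
      v <- x[assign == j]
      if (length(v) == 0) centers[j] else mean(v)
    }, numeric(1))
    if (max(abs(new_c - centers)) < 1e-6) { centers <- new_c; break }
    centers <- new_c
  }
  # drop empty clusters and merge near-coincident centers
  assign <- findInterval(x, (centers[-1] + centers[-length(centers)]) / 2) + 1
  sizes <- tabulate(assign, nbins = length(centers))
  centers <- sort(centers[sizes > 0])
  merged <- centers[1]
  for (c in centers[-1]) {
    if (c - merged[length(merged)] < merge_tol) {
      merged[length(merged)] <- (merged[length(merged)] + c) / 2
    } else merged <- c(merged, c)
  }
  m <- length(merged)
  if (m < 2) stop("empty segmentation: frame has a single intensity class")
  list(bright = (merged[m] + merged[m - 1]) / 2,
       dark = if (m >= 3) (merged[1] + merged[2]) / 2 else -Inf)
}

# Largest connected component of a logical mask, hole-filled
.largest_filled <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(counts)
  EBImage::imageData(EBImage::fillHull(EBImage::Image((lab == keep) * 1))) > 0
}

.check_frame <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  if (is.null(frame$pixel_size_um) || frame$pixel_size_um <= 0) {
    stop("frame has no calibrated pixel size")
  }
  if (diff(range(frame$pixels)) < 0.05) {
    stop("empty segmentation: frame has no contrast")
  }
}

#' Measure the spread-region area
#'
#' Automated analog of tracing the film contour: the spread region (bright
#' cleared film plus the dark aggregate and aureole it encloses) is segmented
#' by cascaded Otsu thresholding, reduced to its largest connected component
#' and hole-filled. The area includes the aureole, matching the film radius
#' used by the conservation model.
#'
#' @param frame An `image_frame`.
#' @return A list with `area_um2` and the equivalent-circle `radius_um`.
#' @export
measure_film_area <- function(frame) {
  .check_frame(frame)
  I <- frame$pixels
  th <- .threshold_levels(as.vector(I))
  mask <- .largest_filled(I >= th$bright | I <= th$dark)
  if (is.null(mask)) stop("empty segmentation: no spread region found")
  area <- sum(mask) * frame$pixel_size_um^2
  list(area_um2 = area, radius_um = sqrt(area / pi))
}

#' Measure the aureole width
#'
#' Segments the spread region with and without the dark peripheral annulus:
#' the outer contour encloses film + aureole, the inner contour is the
#' hole-filled bright film only. The width is the difference of the two
#' equivalent-circle radii, mirroring the area-difference definition of the
#' manual measurement. If the two radii differ by less than one pixel the
#' annulus is declared undetected (`Delta_um = 0`, `found = FALSE`).
#'
#' @param frame An `image_frame`.
#' @return A list of class `aureole_measurement`: `R_outer_um`, `R_inner_um`,
#'   `Delta_um`, `R_um` (the outer film radius used in `Delta/R`), `found`.
#' @export
measure_aureole_width <- function(frame) {
  .check_frame(frame)
  I <- frame$pixels
  th <- .threshold_levels(as.vector(I))
  outer_mask <- .largest_filled(I >= th$bright | I <= th$dark)
  inner_mask <- .largest_filled(I >= th$bright)
  if (is.null(outer_mask) || is.null(inner_mask)) {
    stop("empty segmentation: no spread region found")
  }
  r_out <- sqrt(sum(outer_mask) * frame$pixel_size_um^2 / pi)
  r_in <- sqrt(sum(inner_mask) * frame$pixel_size_um^2 / pi)
  delta <- r_out - r_in
  found <- delta >= frame$pixel_size_um
  structure(list(R_outer_um = r_out, R_inner_um = r_in,
                 Delta_um = if (found) delta else 0,
                 R_um = r_out, found = found),
            class = "aureole_measurement")
}

#' Measure the substrate surface fraction
#'
#' Automated analog of the manual threshold measurement: within the carpet
#' region (outside the spread region by default) an Otsu threshold separates
#' particle speckle from background and the surface fraction is the
#' dark-pixel fraction. Multilayer coatings (true coverage > 1) saturate at
#' 1: optically, stacked layers cover the same projected area.
#'
#' @param frame An `image_frame`.
#' @param region Optional logical matrix marking the carpet region; default
#'   is everything farther than the measured outer radius plus 2 px from the
#'   frame center.
#' @return Estimated surface fraction in \[0, 1\].
#' @export
measure_surface_fraction <- function(frame, region = NULL) {
  .check_frame(frame)
  I <- frame$pixels
  if (is.null(region)) {
    n <- nrow(I)
    ctr <- (n + 1) / 2
    xy <- (seq_len(n) - ctr) * frame$pixel_size_um
    r <- sqrt(outer(xy^2, xy^2, `+`))
    R_out <- tryCatch(measure_film_area(frame)$radius_um, error = function(e) 0)
    region <- r > R_out + 2 * frame$pixel_size_um
  }
  vals <- I[region]
  if (length(vals) == 0) stop("carpet region is empty")
  if (diff(range(vals)) < 0.1) return(0)  # no speckle population
  t <- .otsu(vals)
  sep <- mean(vals[vals > t]) - mean(vals[vals <= t])
  if (!is.finite(sep) || sep < 0.1) return(0)
  mean(vals <= t)
}

#' Volume fractions from a confocal Z-stack
#'
#' For each channel the per-slice segmented area (intensity > 0.5) is summed
#' and multiplied by the slice spacing (rectangle rule over the lower slice,
#' mirroring the elementary-volume summation of the manual procedure).
#' Fractions are bead and nucleus volume over cell volume.
#'
#' @param stack A `zstack`.
#' @return A list with `bead_fraction`, `nucleus_fraction`, and the absolute
#'   volumes `V_cell_um3`, `V_nucleus_um3`, `V_beads_um3`.
#' @export
zstack_volume_fractions <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  for (ch in c("cell", "nucleus", "beads")) {
    if (is.null(stack[[ch]])) stop("missing channel: ", ch)
  }
  slice_vol <- function(arr) {
    areas <- apply(arr > 0.5, 3, sum) * stack$pixel_size_um^2
    sum(areas) * stack$z_step_um
  }
  V_cell <- slice_vol(stack$cell)
  V_nuc <- slice_vol(stack$nucleus)
  V_beads <- slice_vol(stack$beads)
  if (V_cell <= 0) stop("cell channel segments to zero volume")
  list(bead_fraction = V_beads / V_cell,
       nucleus_fraction = V_nuc / V_cell,
       V_cell_um3 = V_cell, V_nucleus_um3 = V_nuc, V_beads_um3 = V_beads)
}

#' Azimuthally averaged radial intensity profile
#'
#' Mean intensity in annular bins of one cell diameter around the frame
#' center — the cell-darkness profile used to verify that the particle
#' density across the aureole is uniform. Intensities are relative
#' (uncalibrated).
#'
#' @param frame An `image_frame`.
#' @param bin_um Radial bin width in um (default one cell diameter, 22 um).
#' @return A data frame with `r_mid_um` and `intensity`, one row per bin out
#'   to half the field of view.
#' @export
radial_darkness_profile <- function(frame, bin_um = 22) {
  stopifnot(inherits(frame, "image_frame"), frame$pixel_size_um > 0,
            bin_um > 0)
  I <- frame$pixels
  n <- nrow(I)
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * frame$pixel_size_um
  r <- sqrt(outer(xy^2, xy^2, `+`))
  r_max <- n / 2 * frame$pixel_size_um
  breaks <- seq(0, ceiling(r_max / bin_um) * bin_um, by = bin_um)
  idx <- cut(as.vector(r), breaks, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(idx) & as.vector(r) <= r_max
  means <- tapply(as.vector(I)[keep], idx[keep], mean)
  bins <- as.integer(names(means))
  data.frame(r_mid_um = (breaks[bins] + breaks[bins + 1]) / 2,
             intensity = as.numeric(means))
}
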