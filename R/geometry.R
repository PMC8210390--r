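#' Planar LV contour
#'
#' An ordered closed polygon in slice-plane mm coordinates. The closing edge
#' (last vertex back to first) is implicit.
#'
#' @param x,y numeric vertex coordinates (mm), >= 3 vertices.
#' @param slice_index integer slice index.
#' @param phase phase label ("ED", "ES" or other).
#' @return object of class `planar_contour` (data.frame of vertices with
#'   attributes).
#' @export
planar_contour <- function(x, y, slice_index = 1L, phase = "other") {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (contour_area(cbind(x, y)) <= 0) stop("contour must enclose a positive area")
  structure(data.frame(x = x, y = y),
            slice_index = as.integer(slice_index), phase = phase,
            class = c("planar_contour", "data.frame"))
}

#' Enclosed polygon area (shoelace)
#'
#' @param xy two-column matrix/data.frame of vertices (mm).
#' @return area in mm^2 (always positive).
#' @export
contour_area <- function(xy) {
  xy <- as.matrix(xy)
  abs(pracma::polyarea(xy[, 1], xy[, 2]))
}

#' Slice geometry: nested endo/epi contours plus stack spacing
#'
#' @param endo,epi `planar_contour`s (or 2-column vertex matrices); epi must
#'   enclose a larger area than endo.
#' @param thickness slice thickness (mm).
#' @param gap inter-slice gap (mm).
#' @return object of class `slice_geometry`.
#' @export
slice_geometry <- function(endo, epi, thickness = 2, gap = 0) {
  endo <- as.matrix(endo)[, 1:2, drop = FALSE]
  epi <- as.matrix(epi)[, 1:2, drop = FALSE]
  if (contour_area(epi) <= contour_area(endo))
    stop("epicardial area must exceed endocardial area")
  stopifnot(thickness > 0, gap >= 0)
  structure(list(endo = endo, epi = epi, thickness = thickness, gap = gap),
            class = "slice_geometry")
}

# Distance from `centroid` to the outermost crossing of the polygon along
# each ray direction. Assumes the contour is star-shaped about the centroid
# (true for LV short-axis borders).
.radius_at_angles <- function(poly, centroid, angles) {
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  rx <- p1[, 1] - centroid[1]; ry <- p1[, 2] - centroid[2]
  vapply(angles, function(th) {
    dx <- cos(th); dy <- sin(th)
    # solve centroid + t*d = p1 + s*e for each edge (Cramer on [d, -e])
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-12
    s <- -(dx * ry - dy * rx)[ok] / den[ok]
    t <- (rx * ey - ex * ry)[ok] / den[ok]
    # closed s-interval with tolerance: rays through a vertex hit both
    # adjacent edges at the same t, and max() absorbs the duplicate
    hit <- s >= -1e-9 & s <= 1 + 1e-9 & t > 0
    if (!any(hit)) return(NA_real_)
    max(t[hit])
  }, numeric(1))
}

#' Move endo/epi borders toward mid-wall by a fraction of wall thickness
#'
#' The endocardial border is pushed outward and the epicardial border pulled
#' inward, each by `offset_fraction` of the local wall thickness measured
#' along radial rays from the wall centroid. This trims the sub-endocardial
#' and sub-epicardial rims that are most affected by partial-volume
#' contamination. Default 15%.
#'
#' @param geometry a [slice_geometry()].
#' @param offset_fraction fraction in \[0, 0.5) trimmed from each border.
#' @param n_theta number of radial rays used to resample the contours.
#' @return a new `slice_geometry` with offset contours (`offset_fraction = 0`
#'   returns the input unchanged).
#' @export
apply_offset <- function(geometry, offset_fraction = 0.15, n_theta = 360L) {
  stopifnot(inherits(geometry, "slice_geometry"))
  if (offset_fraction < 0 || offset_fraction >= 0.5)
    stop("offset_fraction must be in [0, 0.5): borders would cross")
  if (offset_fraction == 0) return(geometry)
  ctr <- pracma::poly_center(geometry$epi[, 1], geometry$epi[, 2])
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  r_endo <- .radius_at_angles(geometry$endo, ctr, th)
  r_epi <- .radius_at_angles(geometry$epi, ctr, th)
  if (any(is.na(r_endo)) || any(is.na(r_epi)) || any(r_epi <= r_endo))
    stop("contours are not star-shaped nested borders about the wall centroid")
  w <- r_epi - r_endo
  r_endo2 <- r_endo + offset_fraction * w
  r_epi2 <- r_epi - offset_fraction * w
  mk <- function(r) cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  slice_geometry(mk(r_endo2), mk(r_epi2), geometry$thickness, geometry$gap)
}

#' Rasterize the LV wall (between endo and epi) onto a pixel grid
#'
#' @param geometry a [slice_geometry()].
#' @param spacing pixel size (mm).
#' @param bbox optional c(xmin, xmax, ymin, ymax) grid extent (mm); defaults
#'   to the epicardial bounding box plus one pixel margin.
#' @return list of class `pixel_grid_mask`: logical `mask` plus pixel-centre
#'   coordinate vectors `x`, `y` and `spacing`. Degenerate geometry (endo
#'   area >= epi area within rasterization) yields an empty mask with a
#'   warning.
#' @export
wall_mask <- function(geometry, spacing = 0.1, bbox = NULL) {
  stopifnot(inherits(geometry, "slice_geometry"), spacing > 0)
  epi <- geometry$epi; endo <- geometry$endo
  if (is.null(bbox))
    bbox <- c(min(epi[, 1]) - spacing, max(epi[, 1]) + spacing,
              min(epi[, 2]) - spacing, max(epi[, 2]) + spacing)
  x <- seq(bbox[1] + spacing / 2, bbox[2], by = spacing)
  y <- seq(bbox[3] + spacing / 2, bbox[4], by = spacing)
  g <- expand.grid(x = x, y = y)
  in_epi <- pracma::inpolygon(g$x, g$y, epi[, 1], epi[, 2])
  in_endo <- pracma::inpolygon(g$x, g$y, endo[, 1], endo[, 2])
  mask <- matrix(in_epi & !in_endo, nrow = length(x), ncol = length(y))
  if (!any(mask)) warning("wall mask is empty (degenerate or sub-pixel wall)")
  structure(list(mask = mask, x = x, y = y, spacing = spacing),
            class = "pixel_grid_mask")
}

#' Divide the LV wall into the four standard short-axis segments
#'
#' Pixels are assigned to contiguous 90-degree angular quadrants about the
#' wall centroid: septal centred on `septal_direction`, anterior at +90,
#' lateral at +180 and inferior at +270 degrees (counter-clockwise).
#'
#' @param wall a `pixel_grid_mask` from [wall_mask()] (typically after
#'   [apply_offset()]).
#' @param centroid c(x, y) wall centre (mm); defaults to the mask centroid.
#' @param septal_direction angle of the septal quadrant centre (radians).
#' @param offset_fraction recorded offset (metadata).
#' @return object of class `segment_model`: character matrix `labels` with
#'   values in {"septal","anterior","lateral","inferior", NA}, plus the grid
#'   coordinates and `offset_fraction`.
#' @export
divide_segments <- function(wall, centroid = NULL, septal_direction = 0,
                            offset_fraction = 0.15) {
  stopifnot(inherits(wall, "pixel_grid_mask"))
  if (!any(wall$mask)) stop("wall mask is empty")
  if (is.null(centroid)) {
    idx <- which(wall$mask, arr.ind = TRUE)
    centroid <- c(mean(wall$x[idx[, 1]]), mean(wall$y[idx[, 2]]))
  }
  labels <- matrix(NA_character_, nrow(wall$mask), ncol(wall$mask))
  idx <- which(wall$mask, arr.ind = TRUE)
  ang <- atan2(wall$y[idx[, 2]] - centroid[2], wall$x[idx[, 1]] - centroid[1])
  rel <- (ang - septal_direction) %% (2 * pi)
  seg <- c("septal", "anterior", "lateral", "inferior")
  quad <- (floor((rel + pi / 4) / (pi / 2)) %% 4) + 1
  labels[wall$mask] <- seg[quad]
  structure(list(labels = labels, x = wall$x, y = wall$y,
                 spacing = wall$spacing, centroid = centroid,
                 offset_fraction = offset_fraction),
            class = "segment_model")
}

#' Circular blood-pool ROI inside the LV cavity
#'
#' Validates the study convention: a round ROI of area < 5 mm^2, entirely
#' inside the endocardial border, avoiding an optional papillary-muscle
#' exclusion polygon.
#'
#' @param center c(x, y) in mm.
#' @param radius_mm circle radius (mm).
#' @param endo endocardial contour (2-column matrix, mm).
#' @param exclude optional polygon to avoid (e.g. papillary muscle).
#' @param n_check number of circle boundary points tested for containment.
#' @return object of class `blood_roi` with `center`, `radius`, `area`.
#' @export
blood_roi <- function(center, radius_mm, endo, exclude = NULL, n_check = 90L) {
  area <- pi * radius_mm^2
  if (area >= 5) stop("blood ROI area must be < 5 mm^2 (got ", round(area, 2), ")")
  endo <- as.matrix(endo)[, 1:2, drop = FALSE]
  th <- seq(0, 2 * pi, length.out = n_check + 1L)[-1L]
  bx <- center[1] + radius_mm * cos(th); by <- center[2] + radius_mm * sin(th)
  if (!all(pracma::inpolygon(bx, by, endo[, 1], endo[, 2])))
    stop("blood ROI crosses the endocardial border")
  if (!is.null(exclude)) {
    exclude <- as.matrix(exclude)[, 1:2, drop = FALSE]
    if (any(pracma::inpolygon(c(center[1], bx), c(center[2], by),
                              exclude[, 1], exclude[, 2])))
      stop("blood ROI overlaps the papillary-muscle exclusion region")
  }
  structure(list(center = center, radius = radius_mm, area = area),
            class = "blood_roi")
}

#' Rasterize a blood ROI onto a map grid
#'
#' @param roi a [blood_roi()].
#' @param x,y pixel-centre coordinate vectors of the target grid (mm).
#' @return logical matrix.
#' @export
blood_roi_mask <- function(roi, x, y) {
  stopifnot(inherits(roi, "blood_roi"))
  d2 <- outer((x - roi$center[1])^2, (y - roi$center[2])^2, `+`)
  d2 <= roi$radius^2
}

#' LV cavity volume by summation of discs
#'
#' Each slice contributes endocardial area times its effective thickness
#' (slice thickness + inter-slice gap).
#'
#' @param slices list of [slice_geometry()] objects at one cardiac phase.
#' @return volume in ml.
#' @export
lv_volumes <- function(slices) {
  stopifnot(length(slices) >= 1L)
  v_mm3 <- sum(vapply(slices, function(s) {
    stopifnot(inherits(s, "slice_geometry"))
    contour_area(s$endo) * (s$thickness + s$gap)
  }, numeric(1)))
  v_mm3 / 1000   # mm^3 -> ml
}

#' LV wall (myocardial) volume by summation of discs
#'
#' @param slices list of [slice_geometry()] objects (end-diastole).
#' @return wall volume in ml.
#' @export
lv_wall_volume <- function(slices) {
  v_mm3 <- sum(vapply(slices, function(s)
    (contour_area(s$epi) - contour_area(s$endo)) * (s$thickness + s$gap),
    numeric(1)))
  v_mm3 / 1000
}

#' Global LV function from end-diastolic and end-systolic volumes
#'
#' SV = EDV - ESV; EF = 100 * SV / EDV; CO = SV * HR / 1000 (l/min);
#' mass = wall volume x 1.05 g/ml (myocardial density convention).
#'
#' @param edv,esv end-diastolic / end-systolic volume (ml).
#' @param hr heart rate (beats/min).
#' @param wall_volume myocardial wall volume (ml) for the mass estimate.
#' @return list of class `lv_function` with `LVEDV`, `LVESV`, `LVSV` (ml),
#'   `LVEF` (%), `CO` (l/min), `LVmass` (g), `HR`.
#' @export
lv_function <- function(edv, esv, hr = NA_real_, wall_volume = NA_real_) {
  stopifnot(edv > 0)
  if (esv < 0 || esv > edv) stop("ESV must satisfy 0 <= ESV <= EDV")
  sv <- edv - esv
  ef <- 100 * sv / edv
  co <- if (is.na(hr)) NA_real_ else sv * hr / 1000
  mass <- if (is.na(wall_volume)) NA_real_ else wall_volume * 1.05
  structure(list(LVEDV = edv, LVESV = esv, LVSV = sv, LVEF = ef,
                 CO = co, LVmass = mass, HR = hr),
            class = "lv_function")
}

#' Pick end-diastolic and end-systolic phases from unlabeled slice stacks
#'
#' ED is the phase with maximal summed endocardial area, ES the minimal.
#'
#' @param phases named list: phase label -> list of `slice_geometry`.
#' @return list with `ED` and `ES` phase labels.
#' @export
select_ed_es <- function(phases) {
  a <- vapply(phases, function(sl)
    sum(vapply(sl, function(s) contour_area(s$endo), numeric(1))), numeric(1))
  list(ED = names(a)[which.max(a)], ES = names(a)[which.min(a)])
}
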