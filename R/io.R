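#' Read an image stack (multi-page TIFF) with a JSON timing sidecar
#'
#' The sidecar carries `delays_ms` (saturation-recovery series) or
#' `echoes_ms` (multi-echo series); without a sidecar a 3-channel TIFF is
#' returned as an RGB stain image array (0-255).
#'
#' @param path TIFF path.
#' @param sidecar optional JSON sidecar path.
#' @return [recovery_series()], [echo_series()], or an RGB array.
#' @export
read_image_stack <- function(path, sidecar = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(sidecar)) {
    img <- pages[[1]]
    if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
      return(img[, , 1:3, drop = FALSE] * 255)
    stop("no timing sidecar given and the TIFF is not a 3-channel stain image")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale
  })
  if (!is.null(meta$delays_ms)) {
    if (length(frames) != length(meta$delays_ms))
      stop("frame count (", length(frames), ") does not match delays_ms (",
           length(meta$delays_ms), ")")
    recovery_series(frames, meta$delays_ms)
  } else if (!is.null(meta$echoes_ms)) {
    if (length(frames) != length(meta$echoes_ms))
      stop("frame count does not match echoes_ms")
    echo_series(frames, meta$echoes_ms)
  } else stop("sidecar must contain delays_ms or echoes_ms")
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Signals are written as 32-bit float after normalization to \[0, 1\]; the
#' normalization scale travels in the sidecar, so a write/read round trip
#' is lossless at single precision.
#'
#' @param series a [recovery_series()] or [echo_series()].
#' @param path output TIFF path.
#' @param sidecar output JSON path; defaults to `path` with `.json`.
#' @return invisibly, the two paths.
#' @export
write_image_stack <- function(series, path, sidecar = sub("\\.tiff?$", ".json", path)) {
  timing <- if (inherits(series, "recovery_series"))
    list(delays_ms = series$delays) else list(echoes_ms = series$echoes)
  scale <- max(vapply(series$frames, max, numeric(1)), 1e-12)
  timing$scale <- scale
  tiff::writeTIFF(lapply(series$frames, function(f) f / scale),
                  path, bits.per.sample = 32L)
  jsonlite::write_json(timing, sidecar, auto_unbox = FALSE, digits = NA)
  invisible(c(path, sidecar))
}

#' Write a parametric map as 32-bit float TIFF plus a JSON summary
#'
#' @param map a `parametric_map`.
#' @param path output TIFF path.
#' @return invisibly, the path.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "parametric_map"))
  v <- map$values
  v[!is.finite(v)] <- 0
  tiff::writeTIFF(v / max(v, 1), path, bits.per.sample = 32L)
  valid <- map$values[is.finite(map$values)]
  jsonlite::write_json(
    list(kind = map$kind, n_valid = length(valid),
         mean = mean(valid), sd = stats::sd(valid), scale = max(map$values, na.rm = TRUE)),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Expected columns follow the per-subject cohort schema (see
#' [make_cohort()]); unknown columns produce a warning, schema violations
#' (group outside 0-5, negative measurements) an error. Missing values stay
#' explicit (`NA`).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- c("subject", "group", "weeks", "cumulative_dose", "hct", "hr",
              "lvedv", "lvesv", "lvsv", "co", "lvef", "lvmass", "native_t1",
              "t2", "ecv", "partition_coefficient", "vacuolar_pct",
              "fibrosis_pct", "inflammation_score", "edema_score")
  extra <- setdiff(names(d), schema)
  if (length(extra)) warning("unknown cohort columns ignored: ",
                             paste(extra, collapse = ", "))
  if (!"group" %in% names(d)) stop("cohort table must have a 'group' column")
  if (!all(d$group %in% 0:5)) stop("group ids must be in 0..5")
  meas <- intersect(schema[-(1:4)], names(d))
  for (v in meas) if (any(d[[v]] < 0, na.rm = TRUE))
    stop("negative values in measurement column: ", v)
  d
}

#' Run configuration for the end-to-end synthetic pipeline
#'
#' Defaults mirror the analysis conventions throughout the package: 15%
#' wall offset, 3-cluster k-means with a 100-iteration cap and 10 restarts,
#' alpha 0.05, power 0.80; one master seed feeds every stage.
#'
#' @param seed master seed.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param offset_fraction wall-trim fraction.
#' @param kmeans_restarts,kmeans_max_iter k-means settings.
#' @param alpha,power statistical defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, offset_fraction = 0.15,
                       kmeans_restarts = 10L, kmeans_max_iter = 100L,
                       alpha = 0.05, power = 0.80) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 offset_fraction = offset_fraction,
                 kmeans_restarts = kmeans_restarts,
                 kmeans_max_iter = kmeans_max_iter,
                 alpha = alpha, power = power),
            class = "run_config")
}

#' Run the full synthetic measurement chain
#'
#' simulate -> relaxometry fit -> segment/ECV -> LV function -> fibrosis
#' quantification -> cohort statistics, all from one master seed. Stages
#' can be skipped; outputs are returned as a bundle and, if `out_dir` is
#' set, written as CSV/JSON alongside the serialized configuration.
#'
#' @param config a [run_config()].
#' @param stages character subset of
#'   c("relaxometry", "function", "ecv", "histology", "stats").
#' @return list of class `pipeline_bundle` with one element per stage run.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("relaxometry", "function", "ecv",
                                    "histology", "stats")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list(config = config)
  seed <- config$seed

  if ("relaxometry" %in% stages) {
    truth_t1 <- matrix(1148, 24, 24); truth_t1[, 13:24] <- 1320
    ph1 <- make_t1_phantom(truth_t1, noise_sd = 20, seed = seed)
    map1 <- fit_t1_map(ph1$series)
    truth_t2 <- matrix(10.3, 24, 24); truth_t2[, 13:24] <- 16.3
    ph2 <- make_t2_phantom(truth_t2, noise_sd = 5, seed = seed + 1L)
    map2 <- fit_t2_map(ph2$series)
    out$relaxometry <- list(
      t1_map = map1, t2_map = map2,
      t1_regions = c(control = map_roi_stats(map1, truth_t1 == 1148)$mean,
                     treated = map_roi_stats(map1, truth_t1 == 1320)$mean),
      t2_regions = c(control = map_roi_stats(map2, truth_t2 == 10.3)$mean,
                     treated = map_roi_stats(map2, truth_t2 == 16.3)$mean))
  }

  if ("function" %in% stages) {
    stk <- make_contour_stack(edv = 0.69, esv = 0.18)
    out$lv_function <- lv_function(lv_volumes(stk$ED), lv_volumes(stk$ES),
                                   hr = 281, wall_volume = stk$truth$wall_volume)
  }

  if ("ecv" %in% stages) {
    # forward-constructed mid-slice maps: uniform myocardial T1 pair with a
    # known partition coefficient, control-like blood pool and Hct
    geom <- slice_geometry(.circle_poly(3), .circle_poly(5), thickness = 1.5)
    wall <- wall_mask(apply_offset(geom, config$offset_fraction), spacing = 0.1)
    segs <- divide_segments(wall, centroid = c(0, 0), septal_direction = 0,
                            offset_fraction = config$offset_fraction)
    grid_dim <- dim(wall$mask)
    pre <- matrix(NA_real_, grid_dim[1], grid_dim[2])
    post <- matrix(NA_real_, grid_dim[1], grid_dim[2])
    pre[wall$mask] <- 1148; post[wall$mask] <- 700
    roi <- blood_roi(c(0, 0), 1.2, geom$endo)
    bmask <- blood_roi_mask(roi, wall$x, wall$y)
    pre[bmask] <- 1800; post[bmask] <- 500
    mk <- function(v) structure(list(values = v, quality = v * 0, kind = "T1"),
                                class = "parametric_map")
    out$ecv <- segmentwise_ecv(mk(pre), mk(post), segs, bmask, hct = 0.588)
  }

  if ("histology" %in% stages) {
    him <- make_histology_image(collagen_pct = 11.0, seed = seed + 2L)
    out$histology <- quantify_fibrosis(him$img, seed = seed + 3L,
                                       restarts = config$kmeans_restarts,
                                       max_iterations = config$kmeans_max_iter)
    out$histology$truth_pct <- him$truth_pct
  }

  if ("stats" %in% stages) {
    coh <- make_cohort(seed = seed + 4L)
    tab <- coh$table
    univ <- sapply(c("vacuolar_pct", "fibrosis_pct", "inflammation_score",
                     "edema_score"),
                   function(x) univariable(tab, x, "native_t1")$R)
    out$stats <- list(
      cohort = tab,
      t1_by_group = compare_groups(tab, "native_t1"),
      univ_t1 = univ,
      fit_t1 = reduce_model(tab, "native_t1",
                            c("vacuolar_pct", "fibrosis_pct",
                              "inflammation_score", "edema_score"), univ),
      fit_ecv = multiple_regression(tab, "ecv",
                                    c("vacuolar_pct", "fibrosis_pct",
                                      "inflammation_score", "edema_score")))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config),
                         file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(out$stats))
      utils::write.csv(out$stats$cohort,
                       file.path(config$out_dir, "cohort.csv"), row.names = FALSE)
    if (!is.null(out$lv_function))
      jsonlite::write_json(unclass(out$lv_function),
                           file.path(config$out_dir, "lv_function.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  structure(out, class = "pipeline_bundle")
}
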