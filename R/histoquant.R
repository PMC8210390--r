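#' Convert an 8-bit RGB stain image to CIE L*a*b*
#'
#' Deterministic sRGB -> CIEXYZ (D65) -> CIELAB conversion. Input is an
#' h x w x 3 array either of 8-bit integers (0-255) or unit-range doubles.
#'
#' @param img h x w x 3 RGB array.
#' @return matrix with one row per pixel and columns L, a, b (row-major over
#'   the image as stored), with attribute `dims = c(h, w)`.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  rgb <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]), as.numeric(img[, , 3]))
  if (max(rgb) > 1) rgb <- rgb / 255
  if (min(rgb) < 0 || max(rgb) > 1) stop("RGB values outside [0, 255]")
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  attr(lab, "dims") <- dim(img)[1:2]
  lab
}

#' k-means clustering of a pixel cloud in L*a*b* space
#'
#' Lloyd-type k-means with an iteration cap and several seeded restarts;
#' the restart with the lowest within-cluster sum of squares is kept.
#' Deterministic given `seed`.
#'
#' @param cloud pixel matrix from [rgb_to_lab()] (columns L, a, b).
#' @param k number of clusters (3: collagen / muscle / background).
#' @param max_iterations iteration cap per restart.
#' @param restarts number of random restarts.
#' @param seed integer seed for the restarts.
#' @param algorithm k-means variant passed to [stats::kmeans()].
#' @return list of class `cluster_result`: `labels` (integer per pixel),
#'   `centroids` (k x 3), `wcss`, `iterations_run`, `seed`, `class_map`
#'   (`NULL` until [label_clusters()]).
#' @export
kmeans_lab <- function(cloud, k = 3L, max_iterations = 100L, restarts = 10L,
                       seed = 1L, algorithm = "Lloyd") {
  cloud <- as.matrix(cloud)
  if (nrow(unique(cloud)) < k)
    stop("degenerate input: fewer distinct pixel colors (",
         nrow(unique(cloud)), ") than clusters (", k, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(cloud, centers = k, iter.max = max_iterations,
                  nstart = restarts, algorithm = algorithm))
  centroids <- km$centers
  colnames(centroids) <- c("L", "a", "b")
  structure(list(labels = km$cluster, centroids = centroids,
                 wcss = km$tot.withinss, iterations_run = km$iter,
                 seed = seed, class_map = NULL, dims = attr(cloud, "dims")),
            class = "cluster_result")
}

#' Assign tissue classes to k-means clusters
#'
#' Background is the centroid with the highest L* (near-white lumen/space);
#' of the remaining two, collagen is the centroid with the higher a*
#' (picrosirius red stains collagen red), muscle the other.
#'
#' @param result a `cluster_result` with 3 centroids.
#' @return the same `cluster_result` with `class_map` set (named character
#'   vector: cluster id -> class).
#' @export
label_clusters <- function(result) {
  stopifnot(inherits(result, "cluster_result"), nrow(result$centroids) == 3L)
  cl <- seq_len(3L)
  bg <- cl[which.max(result$centroids[, "L"])]
  rest <- setdiff(cl, bg)
  collagen <- rest[which.max(result$centroids[rest, "a"])]
  muscle <- setdiff(rest, collagen)
  map <- character(3)
  map[bg] <- "background"; map[collagen] <- "collagen"; map[muscle] <- "muscle"
  names(map) <- as.character(cl)
  result$class_map <- map
  result
}

#' Collagen (fibrosis) fraction from a labelled clustering
#'
#' The fibrosis fraction is the collagen pixel count over the tissue pixel
#' count (collagen + muscle); background/lumen is excluded by default.
#' `denominator = "total"` reproduces the all-pixels reading.
#'
#' @param result a `cluster_result` after [label_clusters()].
#' @param denominator "tissue" (default) or "total".
#' @return list of class `fibrosis_result`: per-class pixel counts and
#'   `fibrosis_pct`.
#' @export
fibrosis_fraction <- function(result, denominator = c("tissue", "total")) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$class_map)) stop("run label_clusters() first")
  denominator <- match.arg(denominator)
  cls <- result$class_map[as.character(result$labels)]
  n_col <- sum(cls == "collagen")
  n_mus <- sum(cls == "muscle")
  n_bg <- sum(cls == "background")
  stopifnot(n_col + n_mus + n_bg == length(result$labels))
  den <- if (denominator == "tissue") n_col + n_mus else length(result$labels)
  structure(list(collagen_pixels = n_col, muscle_pixels = n_mus,
                 background_pixels = n_bg,
                 fibrosis_pct = 100 * n_col / den, denominator = denominator),
            class = "fibrosis_result")
}

#' Quantify one stained image end to end
#'
#' Convenience chain: [rgb_to_lab()] -> [kmeans_lab()] -> [label_clusters()]
#' -> [fibrosis_fraction()].
#'
#' @param img h x w x 3 RGB array.
#' @param seed k-means seed.
#' @param ... passed to [kmeans_lab()] / [fibrosis_fraction()].
#' @param denominator see [fibrosis_fraction()].
#' @return a `fibrosis_result`.
#' @export
quantify_fibrosis <- function(img, seed = 1L, denominator = "tissue", ...) {
  res <- label_clusters(kmeans_lab(rgb_to_lab(img), seed = seed, ...))
  fibrosis_fraction(res, denominator = denominator)
}

#' Subject-level vacuolar change from per-HPF counts
#'
#' Arithmetic mean of vacuolated-cells-per-100 counts over all high-power
#' fields. The complete design is 10 HPFs per LV segment x 4 segments = 40;
#' incomplete designs aggregate with a warning.
#'
#' @param counts numeric vector of per-HPF counts (0-100).
#' @param segments character vector of segment labels, parallel to `counts`.
#' @param hpf_per_segment expected HPFs per segment.
#' @return mean vacuolar change (%).
#' @export
aggregate_vacuolar <- function(counts, segments = NULL, hpf_per_segment = 10L) {
  stopifnot(is.numeric(counts), length(counts) >= 1L)
  if (any(counts < 0 | counts > 100)) stop("per-100-cell counts must be in [0, 100]")
  if (!is.null(segments)) {
    stopifnot(length(segments) == length(counts))
    tab <- table(segments)
    if (length(tab) != 4L || any(tab != hpf_per_segment))
      warning("incomplete HPF design: expected ", hpf_per_segment,
              " HPFs in each of 4 segments, got ",
              paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  mean(counts)
}

#' Subject-level ordinal score from per-segment grades
#'
#' Inflammation and edema are graded 0 (absent) to 4 (severe) per segment;
#' the subject score is the mean over segments, so quarter-step values
#' (0.25, 1.75, ...) arise naturally from 4-segment averaging.
#'
#' @param scores integer vector of per-segment grades in {0,...,4}.
#' @return mean score.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(length(scores) >= 1L)
  if (any(scores != round(scores)) || any(scores < 0 | scores > 4))
    stop("segment grades must be integers in 0..4")
  mean(scores)
}
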