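#!/usr/bin/env Rscript
# Stage 3 — LV function from the stage-1 contour stack (summation of
# discs), then the segment-wise ECV pipeline on forward-constructed
# pre/post-contrast T1 maps with a known partition coefficient.

suppressPackageStartupMessages(library(cmrtox))

ctr <- read.csv("results/contours.csv")
mk_slices <- function(phase) {
  lapply(sort(unique(ctr$slice)), function(i) {
    sl <- ctr[ctr$slice == i & ctr$phase == phase, ]
    slice_geometry(as.matrix(sl[sl$role == "endo", c("x_mm", "y_mm")]),
                   as.matrix(sl[sl$role == "epi", c("x_mm", "y_mm")]),
                   thickness = 2, gap = 0)
  })
}
ed <- mk_slices("ED"); es <- mk_slices("ES")
fn <- lv_function(lv_volumes(ed), lv_volumes(es), hr = 281,
                  wall_volume = lv_wall_volume(ed))
jsonlite::write_json(unclass(fn), "results/lv_function.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("LV function: EDV %.2f ml, ESV %.2f ml, SV %.2f ml, EF %.1f%%, CO %.3f l/min\n",
            fn$LVEDV, fn$LVESV, fn$LVSV, fn$LVEF, fn$CO))

# mid-slice wall, 15% offset, 4 segments, <5 mm^2 blood ROI
th <- seq(0, 2 * pi, length.out = 257)[-257]
geom <- slice_geometry(cbind(3 * cos(th), 3 * sin(th)),
                       cbind(5 * cos(th), 5 * sin(th)), thickness = 1.5)
wall <- wall_mask(apply_offset(geom, 0.15), spacing = 0.1)
segs <- divide_segments(wall, centroid = c(0, 0), septal_direction = 0)
bmask <- blood_roi_mask(blood_roi(c(0, 0), 1.2, geom$endo), wall$x, wall$y)

# forward maps: per-segment partition coefficients around the control value
lam <- c(anterior = 0.34, inferior = 0.36, septal = 0.38, lateral = 0.36)
pre_b <- 1800; post_b <- 450; pre_m <- 1148
dr1_b <- 1 / post_b - 1 / pre_b
dims <- dim(wall$mask)
pre <- matrix(NA_real_, dims[1], dims[2]); post <- pre
for (s in names(lam)) {
  roi <- !is.na(segs$labels) & segs$labels == s
  pre[roi] <- pre_m
  post[roi] <- 1 / (lam[[s]] * dr1_b + 1 / pre_m)
}
pre[bmask] <- pre_b; post[bmask] <- post_b
mk <- function(v) structure(list(values = v, quality = v * 0, kind = "T1"),
                            class = "parametric_map")
out <- segmentwise_ecv(mk(pre), mk(post), segs, bmask, hct = 0.588)
write.csv(out$per_segment, "results/ecv_segments.csv", row.names = FALSE)
cat(sprintf("segment ECV recovered lambda within %.2e of truth; global ECV %.1f%%\n",
            max(abs(out$per_segment$partition_coefficient[
              match(names(lam), out$per_segment$segment)] - lam)),
            out$global$ecv_pct))
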