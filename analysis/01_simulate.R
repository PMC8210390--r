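#!/usr/bin/env Rscript
# Stage 1 — generate every synthetic input the downstream stages consume:
# relaxometry phantoms, a short-axis contour stack, a stained-tissue image
# sweep, and the per-subject cohort table. Ground truth travels alongside
# each artifact so later stages can report recovery errors.

suppressPackageStartupMessages(library(cmrtox))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
dir.create("results", showWarnings = FALSE)

# two-region T1/T2 phantoms: control vs 6-week-like myocardium
truth_t1 <- matrix(1148, 32, 32); truth_t1[, 17:32] <- 1320
truth_t2 <- matrix(10.3, 32, 32); truth_t2[, 17:32] <- 16.3
ph_t1 <- make_t1_phantom(truth_t1, noise_sd = 20, seed = seed)
ph_t2 <- make_t2_phantom(truth_t2, S0 = 1000,
                         noise_sd = 1000 * exp(-16 / 10.3) / 30, seed = seed + 1L)
write_image_stack(ph_t1$series, "results/t1_phantom.tif")
write_image_stack(ph_t2$series, "results/t2_phantom.tif")
cat("phantoms: 32x32, T1 regions 1148/1320 ms (plateau SNR 50),",
    "T2 regions 10.3/16.3 ms (first-echo SNR 30)\n")

# contour stack hitting the control cavity volumes
stk <- make_contour_stack(edv = 0.69, esv = 0.18)
write.csv(stk$contours, "results/contours.csv", row.names = FALSE)
cat(sprintf("contour stack: 3 slices, EDV %.3f ml / ESV %.3f ml by construction\n",
            stk$truth$edv, stk$truth$esv))

# cohort with the included-subject group sizes and known generating models
coh <- make_cohort(seed = seed + 2L)
write.csv(coh$table, "results/cohort.csv", row.names = FALSE)
jsonlite::write_json(lapply(coh$truth, as.list), "results/cohort_truth.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("cohort: %d subjects (%d treated), groups %s\n",
            nrow(coh$table), sum(coh$table$group > 0),
            paste(table(coh$table$group), collapse = "/")))

# histology image sweep across the reported fibrosis range
sweep <- data.frame(truth_pct = c(1.2, 2.2, 4.5, 6.7, 11.0, 25.4))
sweep$realized_pct <- vapply(seq_len(nrow(sweep)), function(i)
  make_histology_image(size = 96, collagen_pct = sweep$truth_pct[i],
                       seed = seed + 10L + i)$truth_pct, numeric(1))
write.csv(sweep, "results/histology_truth_sweep.csv", row.names = FALSE)
cat("histology sweep:", nrow(sweep), "images, collagen truth",
    paste(sweep$truth_pct, collapse = "-"), "%\n")
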