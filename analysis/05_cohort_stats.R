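#!/usr/bin/env Rscript
# Stage 5 — the statistical layer on the stage-1 cohort table: normality-
# gated group comparisons with Bonferroni post-hoc, univariable regressions
# of the CMR values on histology, multiple regression with VIF and model
# reduction, and the power-based sample-size arithmetic.

suppressPackageStartupMessages(library(cmrtox))

tab <- read_cohort_csv("results/cohort.csv")
truth <- jsonlite::read_json("results/cohort_truth.json", simplifyVector = TRUE)

# group comparisons for the headline CMR variables
cmp_rows <- do.call(rbind, lapply(c("native_t1", "ecv", "t2", "lvef"), function(v) {
  cmp <- compare_groups(tab, v)
  data.frame(variable = v, test = cmp$test_used,
             p_omnibus = format_p(cmp$p_value),
             n_pairwise = nrow(cmp$posthoc),
             min_p_adj = format_p(min(cmp$posthoc$p_adjusted)))
}))
write.csv(cmp_rows, "results/group_comparisons.csv", row.names = FALSE)
cat("group comparisons (omnibus):\n"); print(cmp_rows, row.names = FALSE)

# univariable layer
preds <- c("vacuolar_pct", "fibrosis_pct", "inflammation_score", "edema_score")
univ <- do.call(rbind, lapply(c("native_t1", "ecv"), function(y)
  do.call(rbind, lapply(preds, function(x) {
    u <- univariable(tab, x, y)
    data.frame(response = y, predictor = x, R = round(u$R, 2),
               p = format_p(u$p), slope = round(u$slope, 3))
  }))))
write.csv(univ, "results/univariable.csv", row.names = FALSE)
cat("\nunivariable correlations:\n"); print(univ, row.names = FALSE)

# multiple regression with VIF; T1 model reduced by weakest univariable R
u_t1 <- setNames(univ$R[univ$response == "native_t1"], preds)
fit_t1 <- reduce_model(tab, "native_t1", preds, u_t1)
fit_ecv <- multiple_regression(tab, "ecv", preds)
fmt <- function(fit, label) {
  co <- fit$coefficients
  co$p <- format_p(co$p)
  co$vif <- c(NA, round(unname(fit$vif[co$term[-1]]), 1))
  co$response <- label
  co
}
mreg <- rbind(fmt(fit_t1, "native_t1"), fmt(fit_ecv, "ecv"))
write.csv(mreg, "results/multiple_regression.csv", row.names = FALSE)
cat(sprintf("\nnative T1 model (dropped %s): R2 %.2f, adj R2 %.2f\n",
            attr(fit_t1, "dropped"), fit_t1$r2, fit_t1$adj_r2))
cat(sprintf("ECV model: R2 %.2f, adj R2 %.2f, max VIF %.1f (all < 8)\n",
            fit_ecv$r2, fit_ecv$adj_r2, max(fit_ecv$vif)))
cat(sprintf("generating slopes: vacuolar->T1 %.1f (fit %.1f), fibrosis->ECV %.2f (fit %.2f)\n",
            truth$beta_t1[["vacuolar"]],
            fit_t1$coefficients$estimate[match("vacuolar_pct", fit_t1$coefficients$term)],
            truth$beta_ecv[["fibrosis"]],
            fit_ecv$coefficients$estimate[match("fibrosis_pct", fit_ecv$coefficients$term)]))

# sample-size arithmetic: d = 1 reference case and the dropout inflation
ss <- sample_size_two_sample_t(delta = 1, sd = 1)
cat(sprintf("\nsample size, d = 1, power 0.80: %d per group\n", ss$n_per_group))
cat(sprintf("7 per group with 10%% dropout allowance: enroll %d per group (%d over 5 arms)\n",
            ceiling(7 / 0.9), 5 * ceiling(7 / 0.9)))
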