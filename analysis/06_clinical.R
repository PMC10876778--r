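#!/usr/bin/env Rscript
# Clinical statistics: Shapiro-Wilk-gated group comparisons of every
# demographic/clinical variable (t-test or Mann-Whitney; chi-square for
# sex), ROI-clinical correlations with Bonferroni 0.05/7, and the
# covariate-adjusted ROI sensitivity model (group effect with HAMA,
# education and age as nuisance covariates).
# Outputs: results/clinical/{group_comparisons.tsv, roi_correlations.tsv}
library(imgtx)

dir.create("results/clinical", recursive = TRUE, showWarnings = FALSE)
clinical <- read.csv("results/sim/clinical.csv")

comp <- compare_clinical_table(clinical)
write.table(comp, "results/clinical/group_comparisons.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Group comparisons (test chosen by the normality gate):\n")
print(comp, digits = 3)

roi_file <- "results/group/roi_means.tsv"
if (file.exists(roi_file)) {
  roi <- subset(read.delim(roi_file), metric == "reho")
  # align subjects by position within group (group_a = HC, group_b = EM)
  roi_hc <- roi$roi_mean[roi$group == "HC"]
  roi_em <- roi$roi_mean[roi$group == "EM"]
  clin_hc <- clinical[clinical$group == "HC", ][seq_along(roi_hc), ]
  clin_em <- clinical[clinical$group == "EM", ][seq_along(roi_em), ]
  clin <- rbind(clin_hc, clin_em)
  rv <- c(roi_hc, roi_em)

  scales <- c("duration", "hit6", "vas", "hama", "bdi", "bfi_neuroticism",
              "moca")
  rows <- lapply(scales, function(v) {
    res <- roi_clinical_correlation(rv, clin[[v]], n_tests = length(scales))
    data.frame(variable = v, method = res$method, estimate = res$estimate,
               p = res$p, n = res$n,
               sig_uncorrected = res$significant_uncorrected,
               sig_corrected = res$significant_corrected)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, "results/clinical/roi_correlations.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat("\nROI-clinical correlations (corrected threshold 0.05/7 = 0.007):\n")
  print(tab, digits = 3)

  glm <- roi_glm_sensitivity(rv, clin$group,
                             clin[, c("hama", "education", "age")])
  cat(sprintf("\nSensitivity GLM (group term, HAMA/education/age adjusted): F = %.2f, p = %.4f\n",
              glm$F, glm$p))
} else {
  cat("No significant ROI found by 03_group_inference.R; skipping ROI analyses\n")
}
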