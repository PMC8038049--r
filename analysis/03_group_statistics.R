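#!/usr/bin/env Rscript

# Stage 3: cohort statistics.
#
# Joins the covariate table with the per-subject network metrics and runs the
# full analysis plan: demographics (Welch t, Yates chi-square), ANCOVA on
# sigma controlling total GM volume at the global / ICN / regional scopes
# (FDR per family, regions filtered at >= 30 average nodes), partial
# correlations of sigma with the anhedonia scales per group, and the Fisher
# r-to-z group comparison of those correlations.

suppressMessages(library(gmnet))

src_c <- "results/cohort"
src_n <- "results/networks"
out <- "results/statistics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cov <- read_cohort_csv(file.path(src_c, "cohort.csv"))
gl <- read.csv(file.path(src_n, "metrics_global.csv"))
loc <- read.csv(file.path(src_n, "metrics_local.csv"))

cov$sigma <- gl$sigma[match(cov$subject_id, gl$subject_id)]
res <- run_full_statistics(cov, regional = loc)

for (nm in c("demographics", "ancova", "correlations", "posthoc"))
  if (!is.null(res[[nm]]))
    write.csv(res[[nm]], file.path(out, paste0(nm, ".csv")), row.names = FALSE)

message("demographics:")
print(transform(res$demographics, statistic = round(statistic, 2),
                df = round(df, 1), p_unc = signif(p_unc, 3)))
message("ANCOVA on sigma (GM volume controlled):")
print(transform(res$ancova[, c("scope", "F", "p_unc", "p_fdr", "label")],
                F = round(F, 2), p_unc = signif(p_unc, 3),
                p_fdr = signif(p_fdr, 3)))
if (!is.null(res$correlations)) {
  message("sigma-anhedonia correlation comparisons (Fisher r-to-z):")
  print(transform(res$correlations[, c("scope", "scale", "r_patient",
                                       "r_control", "z", "p_unc", "p_fdr",
                                       "label")],
                  r_patient = round(r_patient, 3),
                  r_control = round(r_control, 3), z = round(z, 2),
                  p_unc = signif(p_unc, 3), p_fdr = signif(p_fdr, 3)))
}
message(sprintf("regions retained by the >= 30 average-node filter: %d",
                sum(startsWith(res$retained_scopes, "region:"))))
message("wrote ", out)
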