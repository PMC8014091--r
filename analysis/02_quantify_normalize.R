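#!/usr/bin/env Rscript
# Stage 2 -- quantify peptides and remove injection drift.
#
# Selects the strongest product ions per peptide (top 5 by experiment-wide
# mean area), sums them into peptide quantities, calibrates the drift
# correction on the 0.01x reference isotopologues (4 most linear peptides
# by R^2), applies per-injection correction factors, and rolls corrected
# peptides up to the 390 x 44 protein matrix (impute -> log2 ->
# age/sex/PMI residualization).

source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, RUN_DIR, through = "rollup")

qc <- read.csv(file.path(RUN_DIR, "qc_drift.csv"))
imp <- read.csv(file.path(RUN_DIR, "imputation_report.csv"))
m <- read_matrix_csv(file.path(RUN_DIR, "protein_log2_residualized.csv"))

cat("\n== drift normalization ==\n")
cat(sprintf("drift fit: slope %.5f, intercept %.4f, R^2 %.3f\n",
            qc$slope, qc$intercept, qc$r_squared))
cat(sprintf("reference CV: %.2f%% before -> %.2f%% after correction\n",
            qc$cv_pre, qc$cv_post))
cat("\n== protein matrix ==\n")
cat(sprintf("%d proteins x %d case samples (%d values)\n",
            nrow(m), ncol(m), length(m)))
cat(sprintf("imputed %d of %d values (%.2f%%) at half row minimum\n",
            imp$n_imputed, imp$n_total, 100 * imp$fraction))
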