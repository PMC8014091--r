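#!/usr/bin/env Rscript
# Stage 3 -- differential insolubility across disease groups.
#
# Pairwise volcano tables (Student t, |fold change| > 1.5, p < 0.05, no
# multiple-testing adjustment) for AsymAD/CTL, AD/CTL and PD/CTL, plus
# one-way ANOVA and Kruskal-Wallis omnibus tests per protein.

source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, RUN_DIR, through = "diff")

volc <- read.csv(file.path(RUN_DIR, "volcano.csv"))
omni <- read.csv(file.path(RUN_DIR, "omnibus.csv"))

cat("\n== differential insolubility ==\n")
print(with(volc, table(comparison, flag)))
cat("\nstrongest insoluble-enriched proteins per comparison:\n")
for (cmp in unique(volc$comparison)) {
  sub <- volc[volc$comparison == cmp & volc$flag == "up", ]
  sub <- sub[order(sub$p_t), ]
  cat(sprintf("%s: %s\n", cmp,
              paste(head(sub$entity, 5), collapse = ", ")))
}
cat(sprintf("\nomnibus: %d proteins with ANOVA p < 0.05, %d with KW p < 0.05\n",
            sum(omni$p_anova < 0.05), sum(omni$p_kw < 0.05)))
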