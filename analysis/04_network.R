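#!/usr/bin/env Rscript
# Stage 4 -- signed weighted co-abundance network.
#
# Biweight midcorrelation over the 44 case samples, signed adjacency at
# power 23, mean-denominator topological overlap, average-linkage
# clustering with the adaptive tree cut (min module size 5, deep split 4),
# eigenprotein merging at correlation > 0.93, kME cleanup at 0.30, then
# module-trait correlations and the protein-vs-pathology bicor ranking.

source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, RUN_DIR, through = "network")

mods <- read.csv(file.path(RUN_DIR, "modules.csv"))
mt <- read.csv(file.path(RUN_DIR, "module_trait.csv"))
rk <- read.csv(file.path(RUN_DIR, "pathology_ranking.csv"))
fr <- read.csv(file.path(RUN_DIR, "module_fractions.csv"))

n_mod <- length(setdiff(unique(mods$module), "M0"))
cat("\n== co-abundance network ==\n")
cat(sprintf("%d modules over %d proteins (%d unassigned)\n",
            n_mod, nrow(mods), sum(mods$module == "M0")))
print(head(sort(table(mods$module[mods$module != "M0"]),
                decreasing = TRUE), 10))

cat("\nmodule-trait correlations with |rho| > 0.5 and p < 0.01:\n")
strong <- mt[!is.na(mt$rho) & abs(mt$rho) > 0.5 & mt$p < 0.01, ]
print(strong[order(-abs(strong$rho)), ], row.names = FALSE)

cat("\ntop proteins by bicor to the tau insolubility profile:\n")
print(head(rk[, c("entity", "bicor_tau", "bicor_abeta")], 10),
      row.names = FALSE)

cat("\nmodules with the largest AD/CTL significant-member fractions:\n")
ad <- fr[fr$comparison == "AD/CTL", ]
print(head(ad[order(-ad$fraction), ], 5), row.names = FALSE)
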