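#!/usr/bin/env Rscript
# Stage 5 -- ontology over-representation and macro-clustering.
#
# Fisher exact over-representation of each (synthetic) annotation term in
# each module over the full entity background, Z-score transform
# (significant: Z > 1.96 with >= 3 overlapping symbols), and
# Manhattan/Ward co-clustering of the module x term Z matrix into 6
# macro-clusters.

source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, RUN_DIR, through = "enrich")

enr <- read.csv(file.path(RUN_DIR, "enrichment.csv"))
mc <- read.csv(file.path(RUN_DIR, "macro_clusters.csv"))

cat("\n== ontology enrichment ==\n")
cat(sprintf("%d module x term tests, %d significant (Z > 1.96, overlap >= 3)\n",
            nrow(enr), sum(enr$significant)))
sig <- enr[enr$significant, ]
sig <- sig[order(-sig$z), ]
cat("\nstrongest enrichments:\n")
print(head(sig[, c("module", "term", "overlap", "fisher_p", "z")], 10),
      row.names = FALSE)
cat("\nmacro-cluster sizes:\n")
print(table(mc$macro_cluster))
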