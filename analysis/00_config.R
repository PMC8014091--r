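# Shared configuration for the analysis drivers 01-05.
#
# The study design emulated here: 44 dorsolateral-prefrontal-cortex cases
# (12 control, 8 asymptomatic AD, 12 AD, 12 PD) assayed by targeted PRM on
# their sarkosyl-insoluble fractions; 870 peptides rolling up to 390
# entities (385 RNA-binding proteins plus tau, APP, an amyloid-beta
# roll-up entity and two standard slots); 50 injections including 6 pooled
# standards; a 6-peptide x 5-level tenfold reference spike-in used for
# drift normalization.

library(prminsol)

RUN_DIR <- "results/run"
SEED <- 20260930L

analysis_config <- function(seed = SEED) {
  run_config(sim = sim_config(seed = seed))
}
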