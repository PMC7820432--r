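# Shared settings for the numbered analysis scripts.  Each script can be run
# on its own (later scripts re-use the outputs of earlier ones from disk).
library(lockscape)

SEED <- 1L
COHORT_DIR <- "results/cohort"
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cohort_config <- function() sim_config(seed = SEED)
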