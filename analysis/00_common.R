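# Shared setup for the analysis scripts: output location and master seed.
# Each numbered script is a thin driver over the ringminer package; run them
# from the repository root, in order or independently.

suppressPackageStartupMessages(library(ringminer))

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
SEED <- as.integer(Sys.getenv("RINGMINER_SEED", "1"))

out_path <- function(...) file.path(RESULTS_DIR, ...)
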