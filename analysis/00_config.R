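# Shared settings for the analysis scripts. Source this from each numbered
# script; run the scripts in order from the repository root:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_quality_control.R
#   ...
#
# Every script reads its inputs from and writes its outputs to results/,
# as plain text (TSV/CSV/ESRI-ASCII), so any step can be rerun alone.

library(seasonlap)

SEED <- 20200213          # root seed; all per-stage seeds derive from it
RESULTS <- "results"

# The study population: two monitoring years of deer (20 migratory, 10
# resident), moose (5 nomadic, 1 migratory, 4 resident) and 6 wolves in
# three pack territories plus a floater, all on the shared corridor
# geometry. These are the package defaults, i.e. the study conditions.
POPULATION <- population_config()

QC <- qc_config()
BBMM <- bbmm_params()     # 50-m resolution, 9-h max lag, 20-m GPS error
LEVEL <- 0.95
ALPHA <- 0.05
MRSA_THIN_H <- 48

dir.create(RESULTS, showWarnings = FALSE)

tracks_path <- function(stage) file.path(RESULTS, paste0("tracks_", stage, ".tsv"))
res_path <- function(name) file.path(RESULTS, name)
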