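#!/usr/bin/env Rscript
# Stage 1: simulate a multi-panel elicitation study with the structure the
# downstream analysis assumes (112 panels, 13 experts each, 10-15
# calibration variables, proportion-type items, mixed expert archetypes)
# and write it, with the archetype truth record, under results/.
#
# Usage: Rscript analysis/01_simulate.R [--seed S] [--panels N]

suppressMessages(library(sejcm))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
n_panels <- as.integer(get_arg("--panels", "112"))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_panels = n_panels, seed = seed)
gen <- generate_study(cfg)
v <- validate_study(gen$study)
stopifnot(length(v) == 0)
print(gen$study)

write_study(gen$study, "results/study.json")
utils::write.csv(gen$truth, "results/truth.csv", row.names = FALSE)
message("wrote results/study.json and results/truth.csv")
message(sprintf("archetype mix per panel: %s",
                paste(sprintf("%s=%d", names(table(gen$truth$archetype[
                  gen$truth$panel == gen$truth$panel[1]])),
                  as.integer(table(gen$truth$archetype[
                    gen$truth$panel == gen$truth$panel[1]]))),
                  collapse = ", ")))
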