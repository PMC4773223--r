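#!/usr/bin/env Rscript
# Stage 2: score every expert (statistical accuracy, informativeness,
# combined score) and build the pooled decision makers per panel --
# equal weights (ew), optimised global performance weights (pwg) and
# optimised item performance weights (pwi) -- all scored in-sample on the
# panel's calibration items.  Writes the long score table to results/.
#
# Usage: Rscript analysis/02_score_and_pool.R

suppressMessages(library(sejcm))
if (!file.exists("results/study.json"))
  stop("run analysis/01_simulate.R first")

study <- read_study("results/study.json")
print(study)
message("scoring experts and pooling (ew, pwg, pwi) ...")
t0 <- proc.time()
tab <- score_study(study)
message(sprintf("done in %.1f s", (proc.time() - t0)["elapsed"]))

write_score_table(tab, "results/score_table.csv")
message("wrote results/score_table.csv")

ex <- tab[tab$kind == "expert", ]
for (lab in c("ew", "pwg", "pwi")) {
  d <- tab[tab$kind == lab, ]
  message(sprintf(
    "%s DM: mean accuracy %.3f, mean informativeness %.3f (experts: %.3f / %.3f)",
    lab, mean(d$statistical_accuracy), mean(d$informativeness),
    mean(ex$statistical_accuracy), mean(ex$informativeness)))
}
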