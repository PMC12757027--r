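#!/usr/bin/env Rscript
# Differential RB-TnSeq screen: simulate two parallel screens over a
# 3,744-gene library with a planted hit set (11 activators, 4 inhibitors),
# run the fitness pipeline, and call candidates with the two-screen
# consistency rule. Also reports the time-zero dropout QC with 107 planted
# dropouts.

suppressPackageStartupMessages(library(castworks))
dir.create("results", showWarnings = FALSE)

ex <- experiment_screen(seed = 20260201)
write.table(ex$calls, "results/screen_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ex$planted, "results/screen_planted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("called: %d activators, %d inhibitors (planted 11 + 4)\n",
            ex$n_activators_called, ex$n_inhibitors_called))
cat(sprintf("planted hits recovered with the correct label: %d/15\n",
            ex$recovered))
hits <- ex$calls[ex$calls$call != "none", ]
print(as.data.frame(hits), digits = 3)

qc <- experiment_t0_qc(seed = 20260202)
cat(sprintf("T0 QC: %d of 3744 genes missing at time zero (%.1f%%)\n",
            qc$n_missing, qc$fraction_pct))
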