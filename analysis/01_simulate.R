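#!/usr/bin/env Rscript
# Step 1: simulate the study data.
#
# Builds one typed TF-miRNA regulatory network with 200 planted
# feed-forward loops (20 carrying effects) and a six-tumor cohort of
# matched tumor/normal NB count matrices over it. Ten of the effect loops
# are active in five of the six tumors (the pan-cancer truth), the other
# ten in a single tumor each. Everything downstream (02-05) reads the
# files written here.

suppressPackageStartupMessages(library(panffl))

seed <- 20L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_pairs = 20, seed = seed)
tumors <- sprintf("T%02d", 1:6)
active <- matrix(FALSE, cfg$n_planted_ffls, length(tumors))
active[1:10, 1:5] <- TRUE   # pan-cancer loops: dysregulated in 5 tumors
active[11:20, 1] <- TRUE    # tumor-specific loops

cohort <- simulate_cohort(cfg, tumors, active)
s <- network_summary(cohort$net)
cat(sprintf("network: %d regulations, %d TFs, %d miRNAs, %d genes\n",
            s$n_regulations, s$n_tf, s$n_mirna, s$n_gene))

for (tl in tumors) {
  write_simulation(cohort$studies[[tl]], cohort$net,
                   file.path(out_dir, tl), seed = seed)
  cat(sprintf("wrote %s (%d pairs)\n", file.path(out_dir, tl),
              nrow(cohort$studies[[tl]]$study$pairs)))
}
write_tsv <- function(x, f) utils::write.table(
  x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
write_tsv(cohort$net$edges, "network.tsv")
write_tsv(cohort$truth$ffls, "truth_effect_ffls.tsv")
write_tsv(data.frame(ffl = paste(cohort$truth$ffls$tf,
                                 cohort$truth$ffls$mirna,
                                 cohort$truth$ffls$gene, sep = "|"),
                     active), "truth_active_matrix.tsv")
cat("done\n")
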