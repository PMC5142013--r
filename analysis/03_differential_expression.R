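#!/usr/bin/env Rscript
# Step 3: per-tumor differential expression.
#
# For each simulated tumor type: CPM filter, exact-NB test, BH correction,
# up/down calls at FDR < 0.05 and |log2FC| > 1; then the cross-tumor DE
# frequency tabulation.

suppressPackageStartupMessages(library(panffl))

tumors <- sprintf("T%02d", 1:6)
out_dir <- "results/de"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

calls <- list()
for (tl in tumors) {
  study <- read_expression_study(file.path("results/sim", tl), tl)
  det <- filter_low_expression(study)
  de <- call_de(differential_expression(study, detected = det))
  calls[[tl]] <- de
  utils::write.table(de, file.path(out_dir, paste0(tl, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%s: %d/%d genes and %d/%d miRNAs detected; %d up, %d down\n",
    tl, sum(det$genes), length(det$genes), sum(det$mirnas),
    length(det$mirnas), sum(de$de_call == "up", na.rm = TRUE),
    sum(de$de_call == "down", na.rm = TRUE)))
}

freq <- de_frequency(calls)
utils::write.table(
  data.frame(molecule_id = names(freq$n_tumors_de),
             n_tumors_de = as.integer(freq$n_tumors_de)),
  file.path(out_dir, "de_frequency.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("molecules DE in k tumors:\n")
print(freq$histogram)
cat(sprintf("DE in all %d tumors: %s\n", length(tumors),
            paste(names(freq$n_tumors_de)[freq$n_tumors_de ==
                                            length(tumors)],
                  collapse = ", ")))
cat("done\n")
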