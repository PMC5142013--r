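#!/usr/bin/env Rscript
# Step 5: pan-cancer aggregation and cross-cutting statistics.
#
# Selects loops dysregulated in >= 5 tumors, tests the pan-cancer count
# against within-tumor label shuffles, checks recovery against the planted
# truth, and runs the enrichment/topology statistics with synthetic
# annotation sets (the planted effect genes stand in for a curated
# cancer-gene list; a small synthetic drug table exercises the ATC kernel).

suppressPackageStartupMessages(library(panffl))

seed <- 50L
sig <- read_significance_matrix("results/significance_matrix.tsv")
truth <- utils::read.delim("results/sim/truth_effect_ffls.tsv")
net <- load_regulations("results/sim/network.tsv")
ffls <- read_ffls("results/ffls.tsv")

pan <- select_pancancer(sig, min_tumors = 5)
utils::write.table(pan, "results/pancancer_ffls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("pan-cancer FFLs (>= 5 tumors): %d\n", nrow(pan)))

cnull <- pancancer_count_null(sig, min_tumors = 5, reps = 1000, seed = seed)
cat(sprintf("pan-cancer count %d vs shuffled flags: P = %.4g\n",
            cnull$observed, cnull$p_value))

key <- function(d) paste(d$tf, d$mirna, d$gene)
truth_pan <- key(truth[1:10, ])   # loops planted active in 5 tumors
cat(sprintf("planted pan-cancer loops recovered: %d/10\n",
            sum(truth_pan %in% key(pan))))

# class enrichment among the pan-cancer set
enr <- ffl_type_enrichment(table(pan$ffl_type), table(ffls$ffl_type))
print(enr, row.names = FALSE)

# merged pan-cancer network vs background topology; note the generator
# reserves effect-loop molecules (degree 2 by construction), so unlike
# curated data the selected loops are NOT expected to be hubs here

merged <- merge_ffls(pan)
topo <- topology_report(net)
pan_nodes <- intersect(merged$nodes$id, topo$nodes$id)
for (m in c("degree", "betweenness")) {
  cmp <- topo_comparison(topo, pan_nodes, metric = m)
  cat(sprintf(
    "pan-cancer nodes vs background %s: median %.1f vs %.1f, P = %.3g\n",
    m, cmp$median_group, cmp$median_reference, cmp$p_value))
}

# proportion of "cancer-associated" genes (synthetic annotation: the
# planted effect genes plus background noise genes)
set.seed(seed)
gene_ids <- net$nodes$id[net$nodes$is_gene]
cancer_genes <- union(truth$gene, sample(gene_ids, 20))
pan_genes <- unique(pan$gene)
prop <- set_proportion_test(sum(pan_genes %in% cancer_genes),
                            length(pan_genes),
                            sum(gene_ids %in% cancer_genes),
                            length(gene_ids))
cat(sprintf(
  "cancer-gene proportion: %d/%d in pan-cancer vs %d/%d background, P = %.3g\n",
  prop$table[1, 1], length(pan_genes), prop$table[1, 2], length(gene_ids),
  prop$p_value))

# synthetic drug table: antineoplastic (L01) drugs preferentially target
# the pan-cancer genes
drugs <- data.frame(
  drug_id = sprintf("D%02d", 1:40),
  target_gene_id = c(sample(pan_genes, 12, replace = TRUE),
                     sample(gene_ids, 28, replace = TRUE)),
  stringsAsFactors = FALSE)
atc <- data.frame(
  drug_id = drugs$drug_id,
  atc_code = c(rep("L01XA", 10), rep("N02BA", 30)),
  stringsAsFactors = FALSE)
atc_res <- drug_atc_enrichment(pan_genes, drugs, atc)
cat(sprintf("L01 drugs among pan-cancer targeters: %d/%d vs %d/%d, P = %.3g\n",
            atc_res$k, atc_res$n, atc_res$K, atc_res$N, atc_res$p_value))

# stability of one tumor's results under pair subsampling
study <- read_expression_study("results/sim/T01", "T01")
stab <- stability_subsample(study, net, ffls, pair_counts = c(15, 10),
                            seed = seed, n_perm = 1000)
utils::write.table(stab, "results/stability.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("subsampling stability (vs full 20 pairs):\n")
print(stab, row.names = FALSE)
cat("done\n")
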