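# Shared fixtures, all built in code.

# Minimal hand-built network: one TF-FFL plus extras.
tiny_edges <- function() {
  data.frame(
    source_id = c("A", "A", "m1", "B", "m2"),
    source_type = c("TF", "TF", "miRNA", "TF", "miRNA"),
    target_id = c("m1", "g1", "g1", "g2", "B"),
    target_type = c("miRNA", "gene", "gene", "gene", "TF"),
    stringsAsFactors = FALSE
  )
}

# Random typed network on few nodes for property tests; returns the edge
# data.frame (may contain self-loops/duplicates only if asked).
random_typed_edges <- function(n_tf, n_mir, n_gene, n_edges) {
  tfs <- paste0("T", seq_len(n_tf))
  mirs <- paste0("m", seq_len(n_mir))
  genes <- paste0("g", seq_len(n_gene))
  layers <- list(c("TF", "miRNA"), c("miRNA", "TF"),
                 c("TF", "gene"), c("miRNA", "gene"))
  pools <- list(TF = tfs, miRNA = mirs, gene = genes)
  rows <- lapply(seq_len(n_edges), function(i) {
    ly <- layers[[sample.int(4, 1)]]
    data.frame(source_id = sample(pools[[ly[1]]], 1), source_type = ly[1],
               target_id = sample(pools[[ly[2]]], 1), target_type = ly[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Brute-force FFL enumeration: loop over all (TF, miRNA, gene) triples and
# check edge presence directly. Independent of enumerate_ffls.
brute_force_ffls <- function(net) {
  e <- net$edges
  has <- function(s, t) any(e$source_id == s & e$target_id == t)
  tfs <- net$nodes$id[net$nodes$is_tf]
  mirs <- net$nodes$id[net$nodes$is_mirna]
  genes <- net$nodes$id[net$nodes$is_gene]
  out <- list()
  for (tf in tfs) for (mir in mirs) for (g in genes) {
    if (tf == mir || tf == g || mir == g) next
    if (!has(tf, g) || !has(mir, g)) next
    fwd <- has(tf, mir); rev <- has(mir, tf)
    if (!fwd && !rev) next
    type <- if (fwd && rev) "FB-FFL" else if (fwd) "TF-FFL" else "miRNA-FFL"
    out[[length(out) + 1L]] <- data.frame(
      tf = tf, mirna = mir, gene = g, ffl_type = type,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_type = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$tf, res$mirna, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Small simulated study + network used by several scoring tests.
small_sim <- function(seed = 42, n_planted = 10, n_pairs = 30) {
  cfg <- generator_config(n_tf = 30, n_mirna = 30, n_gene = 100,
                          n_planted_ffls = n_planted,
                          n_null_ffls = 90, n_background_edges = 80,
                          n_pairs = n_pairs, seed = seed)
  gen <- generate_network(cfg)
  sim <- generate_counts(gen, cfg)
  list(cfg = cfg, net = gen$net, truth = gen$truth, sim = sim,
       study = sim$study)
}

# Path to the published pan-cancer FFL table shipped with the package.
pancancer_table_path <- function() {
  system.file("extdata", "pancancer_ffl_table.tsv", package = "panffl")
}
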