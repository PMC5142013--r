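test_that("network construction removes self-loops and duplicates", {
  edges <- data.frame(
    source_id = c("A", "A", "m", "A", "m"),
    source_type = c("TF", "TF", "miRNA", "TF", "miRNA"),
    target_id = c("m", "g", "g", "A", "g"),
    target_type = c("miRNA", "gene", "gene", "TF", "gene"),
    stringsAsFactors = FALSE
  )
  net <- regulatory_network(edges)
  expect_equal(nrow(net$edges), 3)           # self-loop and duplicate dropped
  expect_equal(net$n_removed_self_loops, 1)
  expect_false(any(net$edges$source_id == net$edges$target_id))
  s <- network_summary(net)
  expect_equal(s$n_tf, 1)
  expect_equal(s$n_mirna, 1)
  expect_equal(s$n_gene, 1)
})

test_that("loader reports malformed rows and unknown type tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\tsource_type\ttarget_id\ttarget_type\tevidence",
               "A\tTF\tg\tgene\tdb1",
               "A\tprotein\tg2\tgene\tdb1"), f)
  expect_error(load_regulations(f), "unknown molecule type")
  writeLines(c("source_id\tsource_type\ttarget_id\ttarget_type\tevidence",
               "A\tTF\t\tgene\tdb1"), f)
  expect_error(load_regulations(f), "line")
  expect_error(load_regulations(file.path(tempdir(), "no-such.tsv")),
               "not found")
})

test_that("a regulation table round-trips through TSV", {
  net <- regulatory_network(tiny_edges())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv <- utils::write.table
  write_tsv(net$edges, f, sep = "\t", quote = FALSE, row.names = FALSE)
  net2 <- load_regulations(f)
  expect_equal(net2$edges[order(net2$edges$source_id, net2$edges$target_id), ],
               net$edges[order(net$edges$source_id, net$edges$target_id), ],
               ignore_attr = TRUE)
})

test_that("enumeration finds the minimal motif and applies FB exclusivity", {
  net <- regulatory_network(data.frame(
    source_id = c("A", "A", "m"), source_type = c("TF", "TF", "miRNA"),
    target_id = c("m", "g", "g"), target_type = c("miRNA", "gene", "gene"),
    stringsAsFactors = FALSE))
  ffls <- enumerate_ffls(net)
  expect_equal(nrow(ffls), 1)
  expect_equal(ffls$ffl_type, "TF-FFL")
  expect_equal(unlist(ffls[1, 1:3], use.names = FALSE), c("A", "m", "g"))

  # adding the reverse miRNA->TF edge turns it into FB-FFL, emitted once
  net_fb <- regulatory_network(rbind(net$edges[, 1:4], data.frame(
    source_id = "m", source_type = "miRNA",
    target_id = "A", target_type = "TF")))
  ffls_fb <- enumerate_ffls(net_fb)
  expect_equal(nrow(ffls_fb), 1)
  expect_equal(ffls_fb$ffl_type, "FB-FFL")

  empty <- regulatory_network(tiny_edges()[0, ])
  expect_equal(nrow(enumerate_ffls(empty)), 0)
})

test_that("enumeration matches brute force on random small networks", {
  set.seed(101)
  for (i in 1:25) {
    edges <- random_typed_edges(sample(2:8, 1), sample(2:8, 1),
                                sample(3:12, 1), sample(5:60, 1))
    net <- regulatory_network(edges)
    got <- enumerate_ffls(net)
    want <- brute_force_ffls(net)
    expect_equal(got, want)
    # classification is a partition: no triple appears twice
    expect_false(anyDuplicated(paste(got$tf, got$mirna, got$gene)) > 0)
  }
})

test_that("merging FFLs yields the union network and is idempotent", {
  one <- data.frame(tf = "A", mirna = "m", gene = "g", ffl_type = "TF-FFL",
                    stringsAsFactors = FALSE)
  net1 <- merge_ffls(one)
  expect_equal(nrow(net1$edges), 3)
  expect_equal(nrow(net1$nodes), 3)

  set.seed(7)
  edges <- random_typed_edges(5, 5, 8, 40)
  ffls <- enumerate_ffls(regulatory_network(edges))
  if (nrow(ffls)) {
    merged <- merge_ffls(ffls)
    again <- merge_ffls(enumerate_ffls(merged))
    o <- function(e) e[order(e$source_id, e$target_id), 1:4]
    expect_equal(o(again$edges), o(merged$edges), ignore_attr = TRUE)
  }
  expect_error(merge_ffls(one[0, ]), "empty")
})

test_that("merging the published pan-cancer loops reproduces its network", {
  tab <- utils::read.delim(pancancer_table_path(), comment.char = "#")
  expect_equal(nrow(tab), 26)
  merged <- merge_ffls(tab)
  s <- network_summary(merged)
  expect_equal(s$n_tf, 11)
  expect_equal(s$n_mirna, 15)
  expect_equal(s$n_gene, 15)
  topo <- topology_report(merged)
  expect_equal(topo$nodes$degree[topo$nodes$id == "E2F1"], 15)
})

test_that("topology metrics behave on canonical graphs", {
  # directed 3-cycle: all nodes equivalent
  cyc <- regulatory_network(data.frame(
    source_id = c("A", "B", "C"), source_type = "TF",
    target_id = c("B", "C", "A"), target_type = "TF",
    stringsAsFactors = FALSE))
  topo <- topology_report(cyc)
  expect_true(all(topo$nodes$degree == 2))
  expect_equal(length(unique(topo$nodes$betweenness)), 1)
  expect_equal(topo$nodes$degree,
               topo$nodes$in_degree + topo$nodes$out_degree)

  # star: hub regulates 5 genes
  star <- regulatory_network(data.frame(
    source_id = "H", source_type = "TF",
    target_id = paste0("g", 1:5), target_type = "gene",
    stringsAsFactors = FALSE))
  ts <- topology_report(star)
  expect_equal(ts$nodes$out_degree[ts$nodes$id == "H"], 5)
  expect_true(all(ts$nodes$in_degree[ts$nodes$id != "H"] == 1))
  # leaves have betweenness 0
  expect_true(all(ts$nodes$betweenness[ts$nodes$id != "H"] == 0))
  # too few distinct degrees for a fit
  expect_match(ts$fits$degree$skipped, "fewer than 3")
})

test_that("power-law fit equals an independent log-log regression", {
  cfg <- generator_config(n_tf = 40, n_mirna = 30, n_gene = 130,
                          n_planted_ffls = 0, n_null_ffls = 60,
                          n_background_edges = 300, pa_strength = 0.5,
                          seed = 9)
  net <- generate_network(cfg)$net
  topo <- topology_report(net)
  deg <- topo$nodes$degree
  # independent oracle: plain least squares on the log-log histogram
  tab <- table(deg[deg > 0])
  fit <- stats::lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
  expect_lt(abs(topo$fits$degree$b - unname(coef(fit)[2])), 0.05)
  expect_equal(topo$fits$degree$a, 10^unname(coef(fit)[1]), tolerance = 1e-8)
})

test_that("regulator/target histograms count correctly", {
  net <- regulatory_network(data.frame(
    source_id = c("A", "B"), source_type = "TF",
    target_id = c("g", "g"), target_type = "gene",
    stringsAsFactors = FALSE))
  h <- degree_frequency_tables(net)
  expect_equal(h$tfs_per_gene, c("2" = 1L))
  expect_equal(length(h$mirnas_per_gene), 0)

  empty <- regulatory_network(tiny_edges()[0, ])
  expect_true(all(lengths(degree_frequency_tables(empty)) == 0))

  # counting identity: histogram sums to the number of regulated molecules
  set.seed(5)
  rnet <- regulatory_network(random_typed_edges(6, 6, 15, 80))
  hr <- degree_frequency_tables(rnet)
  e <- rnet$edges
  n_genes_with_tf <- length(unique(
    e$target_id[e$source_type == "TF" & e$target_type == "gene"]))
  expect_equal(sum(hr$tfs_per_gene), n_genes_with_tf)
  n_tfs_with_gene <- length(unique(
    e$source_id[e$source_type == "TF" & e$target_type == "gene"]))
  expect_equal(sum(hr$genes_per_tf), n_tfs_with_gene)
})

test_that("FFL tables round-trip through TSV", {
  ffls <- data.frame(tf = c("A", "B"), mirna = c("m1", "m2"),
                     gene = c("g1", "g2"),
                     ffl_type = c("TF-FFL", "FB-FFL"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ffls(ffls, f)
  expect_equal(read_ffls(f), ffls, ignore_attr = TRUE)
})
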