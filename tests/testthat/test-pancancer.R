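make_sig <- function(p, types = NULL) {
  n <- nrow(p)
  if (is.null(types)) types <- rep("TF-FFL", n)
  ffls <- data.frame(tf = paste0("T", seq_len(n)),
                     mirna = paste0("m", seq_len(n)),
                     gene = paste0("g", seq_len(n)),
                     ffl_type = types, stringsAsFactors = FALSE)
  rownames(p) <- paste(ffls$tf, ffls$mirna, ffls$gene, sep = "|")
  structure(list(p = p, ffls = ffls, alpha = 0.05),
            class = "ffl_sig_matrix")
}

test_that("pan-cancer selection applies the tumor-count threshold", {
  p <- matrix(1, 4, 9)
  p[1, 1:9] <- 0.01   # dysregulated in 9 tumors
  p[2, 1:4] <- 0.01   # only 4
  p[3, 1:5] <- NA     # untestable cells do not count as dysregulated
  p[3, 6:9] <- 0.01
  sel <- select_pancancer(make_sig(p), min_tumors = 5)
  expect_equal(sel$tf, "T1")
  expect_equal(sel$n_tumors_dysregulated, 9)
  counts <- attr(sel, "counts")
  expect_equal(counts$n_tumors_dysregulated, c(9, 4, 4, 0))
  expect_equal(counts$n_tumors_untestable[3], 5)

  # k = 1 returns exactly the union of per-tumor dysregulated sets
  sel1 <- select_pancancer(make_sig(p), min_tumors = 1)
  union_ids <- which(rowSums(p < 0.05, na.rm = TRUE) > 0)
  expect_setequal(match(sel1$tf, paste0("T", 1:4)), union_ids)

  empty <- select_pancancer(make_sig(matrix(1, 3, 2)), min_tumors = 1)
  expect_equal(nrow(empty), 0)
})

test_that("the pan-cancer count permutation preserves per-tumor flags", {
  # all-flags matrix: observed count can never be exceeded
  sig_all <- make_sig(matrix(0.001, 6, 7))
  res <- pancancer_count_null(sig_all, min_tumors = 5, reps = 50, seed = 1)
  expect_equal(res$observed, 6)
  expect_true(all(res$null_counts == 6))
  expect_equal(res$p_value, 1)  # ties count as >= observed

  # determinism
  set.seed(99)
  p <- matrix(runif(200 * 6), 200, 6)
  sig <- make_sig(p)
  r1 <- pancancer_count_null(sig, reps = 100, seed = 4)
  r2 <- pancancer_count_null(sig, reps = 100, seed = 4)
  expect_identical(r1$null_counts, r2$null_counts)

  # planted concentration of flags on 20 loops is detected
  set.seed(7)
  p2 <- matrix(1, 200, 8)
  for (j in 1:8) p2[sample(21:200, 4), j] <- 0.01  # background flags
  p2[1:20, 1:6] <- 0.01                            # concentrated flags
  res2 <- pancancer_count_null(make_sig(p2), min_tumors = 5, reps = 1000,
                               seed = 11)
  expect_gte(res2$observed, 20)
  expect_lt(res2$p_value, 0.01)
})

test_that("hypergeometric kernel matches exact enumeration", {
  # closed-form small case: C(5,2)/C(10,2)
  expect_equal(hypergeom_upper(2, 5, 2, 10), 2 / 9)
  expect_equal(hypergeom_upper(0, 5, 2, 10), 1)
  expect_error(hypergeom_upper(3, 2, 3, 10), "inconsistent")

  exact_upper <- function(k, K, n, N) {
    ks <- k:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
  }
  set.seed(13)
  for (i in 1:50) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper(k, K, n, N), exact_upper(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("the published FFL-class counts give the reported enrichment", {
  res <- ffl_type_enrichment(
    pan_counts = c("TF-FFL" = 18, "miRNA-FFL" = 7, "FB-FFL" = 1),
    background_counts = c("TF-FFL" = 244, "miRNA-FFL" = 226, "FB-FFL" = 35))
  expect_equal(res$p_value[res$ffl_type == "TF-FFL"], 0.023,
               tolerance = 0.03)
  expect_equal(round(res$p_value[res$ffl_type == "TF-FFL"], 3), 0.023)
  # the other classes are depleted, not enriched
  expect_gt(res$p_value[res$ffl_type == "miRNA-FFL"], 0.5)
})

test_that("proportion tests use Fisher's exact distribution", {
  res <- set_proportion_test(3, 4, 1, 4)
  expect_equal(res$p_value, 0.4857143, tolerance = 1e-6)
  # identical proportions: odds ratio 1 (conditional MLE), P = 1
  res_eq <- set_proportion_test(5, 10, 10, 20)
  expect_equal(res_eq$p_value, 1)
  expect_equal(res_eq$odds_ratio, 1, tolerance = 0.01)
  # extreme table attains the minimal P for its marginals
  res_x <- set_proportion_test(10, 10, 0, 10)
  # both extreme tables (10/0 and 0/10) are equally likely: P = 2/C(20,10)
  expect_equal(res_x$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  # zero marginal is flagged and P forced to 1
  res_z <- set_proportion_test(0, 0, 3, 10)
  expect_true(res_z$flagged)
  expect_equal(res_z$p_value, 1)
})

test_that("hub/bottleneck comparisons separate high-degree groups", {
  cfg <- generator_config(n_tf = 60, n_mirna = 60, n_gene = 380,
                          n_planted_ffls = 0, n_null_ffls = 100,
                          n_background_edges = 700, pa_strength = 0.5,
                          seed = 31)
  net <- generate_network(cfg)$net
  topo <- topology_report(net)
  ord <- order(-topo$nodes$degree)
  top <- topo$nodes$id[ord[seq_len(ceiling(0.1 * nrow(topo$nodes)))]]
  expect_lt(topo_comparison(topo, top, metric = "degree")$p_value, 0.01)
  expect_lt(topo_comparison(topo, top, metric = "betweenness")$p_value, 0.05)

  # identical groups: no difference, one-sided P ~ 0.5
  res_id <- topo_comparison(topo, topo$nodes$id, metric = "degree")
  expect_lt(abs(res_id$p_value - 0.5), 0.05)

  # calibration: random groups give roughly uniform P
  set.seed(17)
  ps <- replicate(100, {
    g <- sample(topo$nodes$id, 40)
    topo_comparison(topo, g, metric = "degree")$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_error(topo_comparison(topo, "no-such-node"), "absent")
})

test_that("DE frequency across tumors counts and tabulates correctly", {
  tumors <- paste0("T", 1:13)
  calls <- lapply(seq_along(tumors), function(j) {
    data.frame(molecule_id = c("always", "never", "half"),
               de_call = c("up", "neutral",
                           if (j <= 6) "down" else "neutral"),
               stringsAsFactors = FALSE)
  })
  names(calls) <- tumors
  freq <- de_frequency(calls)
  expect_equal(unname(freq$n_tumors_de["always"]), 13)
  expect_equal(unname(freq$n_tumors_de["never"]), 0)
  expect_equal(unname(freq$n_tumors_de["half"]), 6)
  expect_equal(sum(freq$histogram), 3)  # sums to number of molecules
  expect_equal(freq$pattern["always", "T1"], "up")
})

test_that("drug ATC enrichment shares the hypergeometric kernel", {
  targets <- data.frame(
    drug_id = paste0("D", 1:30),
    target_gene_id = c(rep("panG", 12), rep("otherG", 18)),
    stringsAsFactors = FALSE)
  atc <- data.frame(
    drug_id = paste0("D", 1:28),  # two drugs lack ATC codes
    atc_code = c(rep("L01XX", 14), rep("N02BA", 14)),
    stringsAsFactors = FALSE)
  res <- drug_atc_enrichment("panG", targets, atc)
  expect_equal(res$n_excluded_no_atc, 2)
  expect_equal(res$p_value,
               hypergeom_upper(res$k, res$K, res$n, res$N))
  # zero marked drugs in the sample
  targets2 <- targets
  targets2$target_gene_id[1:14] <- "otherG"
  targets2$target_gene_id[15:20] <- "panG"
  res2 <- drug_atc_enrichment("panG", targets2, atc)
  expect_equal(res2$k, 0)
  expect_equal(res2$p_value, 1)
  # sample = population is degenerate: P = 1
  res3 <- drug_atc_enrichment(c("panG", "otherG"), targets, atc)
  expect_equal(res3$n, res3$N)
  expect_equal(res3$p_value, 1)
})

test_that("results are stable under subsampling of matched pairs", {
  fx <- small_sim(seed = 52, n_planted = 10, n_pairs = 24)
  ffls <- enumerate_ffls(fx$net)
  rep1 <- stability_subsample(fx$study, fx$net, ffls,
                              pair_counts = c(24, 14, 8), seed = 3,
                              n_perm = 200)
  # full data reproduces itself exactly
  expect_equal(rep1$rho_de[1], 1)
  expect_equal(rep1$rho_ffl[1], 1)
  # subsamples stay strongly, significantly correlated
  expect_true(all(rep1$rho_de > 0))
  expect_true(all(rep1$rho_ffl > 0))
  expect_true(all(rep1$p_de < 0.01))
  expect_true(all(rep1$p_ffl < 0.01))
  # determinism
  rep2 <- stability_subsample(fx$study, fx$net, ffls,
                              pair_counts = c(24, 14, 8), seed = 3,
                              n_perm = 200)
  expect_equal(rep1, rep2)
  expect_error(stability_subsample(fx$study, fx$net, ffls, 3), "below 4")
  expect_error(stability_subsample(fx$study, fx$net, ffls, 50), "exceeds")
})

test_that("an 86-pair study stays rank-stable at 60, 40 and 20 pairs", {
  cfg <- generator_config(n_pairs = 86, seed = 86)
  gen <- generate_network(cfg)
  sim <- generate_counts(gen, cfg)
  ffls <- enumerate_ffls(gen$net)
  rep <- stability_subsample(sim$study, gen$net, ffls,
                             pair_counts = c(60, 40, 20), seed = 9,
                             n_perm = 500)
  expect_true(all(rep$rho_de > 0))
  expect_true(all(rep$rho_ffl > 0))
  expect_true(all(rep$p_de < 0.01))
  expect_true(all(rep$p_ffl < 0.01))
  # deeper subsampling can only blur the ranking
  expect_true(all(diff(rep$rho_de) < 0.1))
})

test_that("significance matrices round-trip through TSV", {
  set.seed(2)
  p <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("AA", "BB", "CC")))
  p[2, 1] <- NA
  sig <- make_sig(p)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_significance_matrix(sig, f)
  sig2 <- read_significance_matrix(f)
  expect_equal(sig2$p, sig$p, tolerance = 1e-12)
  expect_equal(sig2$ffls, sig$ffls, ignore_attr = TRUE)
})
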