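#' Configuration for the synthetic regulatory-network / expression generator
#'
#' Defaults describe the standard simulation study used throughout the
#' package: a typed network of 50 TFs, 50 miRNAs and 200 genes containing
#' 200 planted feed-forward loops of which 20 carry effects (node
#' |log2 fold change| of 2 and an edge Spearman-correlation shift from 0 in
#' normal to 0.8 in tumor), negative-binomial counts (dispersion 0.1,
#' log-normal baseline means) for 50 matched sample pairs.
#'
#' @param n_tf,n_mirna,n_gene Node counts per role.
#' @param n_planted_ffls Number of effect-carrying planted FFLs. Their
#'   molecules are reserved (disjoint from all other loops and background
#'   edges) so planted truth is unambiguous.
#' @param n_null_ffls Structurally planted loops without any effect.
#' @param n_background_edges Extra edges added by preferential attachment.
#' @param pa_strength Smoothing constant added to degrees when sampling
#'   preferential-attachment endpoints (larger = more uniform).
#' @param ffl_type_mix Named probabilities for planted loop classes.
#' @param n_pairs Matched tumor/normal sample pairs.
#' @param nb_dispersion NB dispersion phi (var = mu + phi mu^2); 0 =
#'   Poisson.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-molecule baseline mean.
#' @param node_log2fc Planted |log2 fold change| for members of effect
#'   loops (applied + for TF and gene, - for the repressing miRNA).
#' @param edge_r_tumor,edge_r_normal Latent Gaussian-copula correlation
#'   among the three members of an effect loop, per condition.
#' @param lib_factor_range Per-sample library scale factors are drawn
#'   uniformly from this range (default keeps library sizes within 2x).
#' @param seed Integer seed used by [generate_network()] and
#'   [generate_counts()].
#' @return A list of class `ffl_generator_config`.
#' @export
generator_config <- function(n_tf = 50, n_mirna = 50, n_gene = 200,
                             n_planted_ffls = 20, n_null_ffls = 180,
                             n_background_edges = 150, pa_strength = 1,
                             ffl_type_mix = c("TF-FFL" = 0.5,
                                              "miRNA-FFL" = 0.43,
                                              "FB-FFL" = 0.07),
                             n_pairs = 50, nb_dispersion = 0.1,
                             baseline_meanlog = log(300),
                             baseline_sdlog = 1,
                             node_log2fc = 2, edge_r_tumor = 0.8,
                             edge_r_normal = 0,
                             lib_factor_range = c(0.75, 1.5),
                             seed = 1L) {
  cfg <- list(n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
              n_planted_ffls = n_planted_ffls, n_null_ffls = n_null_ffls,
              n_background_edges = n_background_edges,
              pa_strength = pa_strength, ffl_type_mix = ffl_type_mix,
              n_pairs = n_pairs, nb_dispersion = nb_dispersion,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              node_log2fc = node_log2fc, edge_r_tumor = edge_r_tumor,
              edge_r_normal = edge_r_normal,
              lib_factor_range = lib_factor_range, seed = seed)
  stopifnot(cfg$n_tf > 0, cfg$n_mirna > 0, cfg$n_gene > 0,
            cfg$n_planted_ffls >= 0, cfg$n_null_ffls >= 0,
            cfg$nb_dispersion >= 0,
            abs(cfg$edge_r_tumor) < 1, abs(cfg$edge_r_normal) < 1,
            diff(range(cfg$lib_factor_range)) >= 0,
            min(cfg$lib_factor_range) > 0,
            max(cfg$lib_factor_range) / min(cfg$lib_factor_range) <= 2)
  class(cfg) <- "ffl_generator_config"
  cfg
}

plant_ffl_edges <- function(tf, mir, gene, type) {
  e <- list(c(tf, "TF", gene, "gene"), c(mir, "miRNA", gene, "gene"))
  if (type %in% c("TF-FFL", "FB-FFL")) e <- c(e, list(c(tf, "TF", mir, "miRNA")))
  if (type %in% c("miRNA-FFL", "FB-FFL")) e <- c(e, list(c(mir, "miRNA", tf, "TF")))
  e
}

#' Generate a typed regulatory network with planted FFLs
#'
#' Plants `n_planted_ffls` effect loops on reserved molecules (each loop
#' uses its own TF, miRNA and gene, untouched by any other edge) and
#' `n_null_ffls` further loops on the remaining molecules, then adds
#' background edges by degree-preferential attachment to approximate a
#' scale-free degree distribution. No self-loops are produced.
#'
#' @param cfg An [generator_config()].
#' @return A list with `net` (an `ffl_network`) and `truth` (list with
#'   `ffls`, the effect loops; `null_ffls`, the no-effect planted loops).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "ffl_generator_config"))
  n_eff <- cfg$n_planted_ffls
  if (n_eff > min(cfg$n_tf, cfg$n_mirna, cfg$n_gene)) {
    stop("infeasible: more effect loops than reserved molecules available")
  }
  if (cfg$n_null_ffls >
        (cfg$n_tf - n_eff) * (cfg$n_mirna - n_eff) * (cfg$n_gene - n_eff)) {
    stop("infeasible: more null loops than available triples")
  }
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tf))
  mirs <- sprintf("hsa-miR-sim-%03d", seq_len(cfg$n_mirna))
  genes <- sprintf("G%04d", seq_len(cfg$n_gene))

  with_seed(cfg$seed, {
    draw_type <- function(n) {
      if (n == 0) return(character(0))
      sample(names(cfg$ffl_type_mix), n, replace = TRUE,
             prob = cfg$ffl_type_mix)
    }
    # effect loops on reserved molecules, one private triple each
    eff <- data.frame(tf = tfs[seq_len(n_eff)],
                      mirna = mirs[seq_len(n_eff)],
                      gene = genes[seq_len(n_eff)],
                      ffl_type = draw_type(n_eff),
                      stringsAsFactors = FALSE)
    pool_tf <- tfs[setdiff(seq_along(tfs), seq_len(n_eff))]
    pool_mir <- mirs[setdiff(seq_along(mirs), seq_len(n_eff))]
    pool_gene <- genes[setdiff(seq_along(genes), seq_len(n_eff))]

    # null loops: distinct triples from the unreserved pools
    seen <- character(0)
    null_rows <- vector("list", cfg$n_null_ffls)
    i <- 0L
    while (i < cfg$n_null_ffls) {
      tf <- sample(pool_tf, 1); mir <- sample(pool_mir, 1)
      g <- sample(pool_gene, 1)
      key <- paste(tf, mir, g)
      if (key %in% seen) next
      seen <- c(seen, key)
      i <- i + 1L
      null_rows[[i]] <- data.frame(tf = tf, mirna = mir, gene = g,
                                   ffl_type = draw_type(1),
                                   stringsAsFactors = FALSE)
    }
    nul <- if (cfg$n_null_ffls) do.call(rbind, null_rows) else
      data.frame(tf = character(), mirna = character(), gene = character(),
                 ffl_type = character(), stringsAsFactors = FALSE)

    planted <- rbind(eff, nul)
    edge_list <- list()
    for (r in seq_len(nrow(planted))) {
      edge_list <- c(edge_list,
                     plant_ffl_edges(planted$tf[r], planted$mirna[r],
                                     planted$gene[r], planted$ffl_type[r]))
    }

    # background edges by preferential attachment on unreserved molecules;
    # degree weights and the seen-edge set are maintained incrementally
    all_ids <- c(tfs, mirs, genes)
    deg <- stats::setNames(rep(0, length(all_ids)), all_ids)
    seen_edges <- new.env(hash = TRUE, size = 4L * cfg$n_background_edges + 64L)
    for (e in edge_list) {
      deg[e[1]] <- deg[e[1]] + 1
      deg[e[3]] <- deg[e[3]] + 1
      assign(paste(e[1], e[3]), TRUE, envir = seen_edges)
    }
    layers <- list(
      c("TF", "gene"), c("miRNA", "gene"), c("TF", "miRNA"),
      c("miRNA", "TF")
    )
    layer_prob <- c(0.55, 0.25, 0.12, 0.08)  # roughly the curated layers' mix
    pools <- list(TF = pool_tf, miRNA = pool_mir, gene = pool_gene)
    bg_list <- vector("list", cfg$n_background_edges)
    n_bg <- 0L
    guard <- 0L
    while (n_bg < cfg$n_background_edges && guard < 50 * cfg$n_background_edges) {
      guard <- guard + 1L
      ly <- layers[[sample.int(4, 1, prob = layer_prob)]]
      src_pool <- pools[[ly[1]]]; tgt_pool <- pools[[ly[2]]]
      src <- sample(src_pool, 1, prob = deg[src_pool] + cfg$pa_strength)
      tgt <- sample(tgt_pool, 1, prob = deg[tgt_pool] + cfg$pa_strength)
      if (src == tgt) next
      key <- paste(src, tgt)
      if (!is.null(seen_edges[[key]])) next
      assign(key, TRUE, envir = seen_edges)
      n_bg <- n_bg + 1L
      bg_list[[n_bg]] <- c(src, ly[1], tgt, ly[2])
      deg[src] <- deg[src] + 1
      deg[tgt] <- deg[tgt] + 1
    }
    edge_list <- c(edge_list, bg_list[seq_len(n_bg)])

    m <- do.call(rbind, edge_list)
    edges <- data.frame(source_id = m[, 1], source_type = m[, 2],
                        target_id = m[, 3], target_type = m[, 4],
                        evidence = "synthetic", stringsAsFactors = FALSE)
    net <- regulatory_network(edges)
    list(net = net, truth = list(ffls = eff, null_ffls = nul))
  })
}

# Cholesky factor of the 3x3 exchangeable correlation matrix.
exch_chol <- function(rho) {
  chol(matrix(c(1, rho, rho, rho, 1, rho, rho, rho, 1), 3))
}

nb_quantile <- function(u, mu, phi) {
  if (phi <= 0) stats::qpois(u, lambda = mu)
  else stats::qnbinom(u, size = 1 / phi, mu = mu)
}

#' Generate matched tumor/normal counts with planted truth
#'
#' Counts are negative binomial with log-normal baseline means and
#' per-sample library scale factors. Members of effect loops get their
#' tumor mean shifted by the planted log2 fold change (positive for TF and
#' gene, negative for the miRNA) and, within each effect loop, a
#' condition-specific rank correlation induced by a Gaussian copula: latent
#' trivariate normals with exchangeable correlation `edge_r_tumor`
#' (tumor) / `edge_r_normal` (normal) are mapped through the NB quantile
#' function. All other molecules are independent with equal means in both
#' conditions.
#'
#' @param net_truth Output of [generate_network()].
#' @param cfg The same [generator_config()].
#' @param active Optional logical vector (length `n_planted_ffls`): which
#'   effect loops carry their effects in this study (default: all). Used to
#'   make a loop dysregulated in some tumor types only.
#' @param tumor_label Label for the generated study.
#' @param seed Seed for the count draw (defaults to `cfg$seed + 1`).
#' @return A list with `study` (an `expression_study`) and `truth` (lists
#'   `ffls`, `nodes` with signed true log2fc, `edges` with target
#'   correlations).
#' @export
generate_counts <- function(net_truth, cfg, active = NULL,
                            tumor_label = "SIM", seed = NULL) {
  stopifnot(inherits(cfg, "ffl_generator_config"))
  net <- net_truth$net
  eff <- net_truth$truth$ffls
  if (is.null(active)) active <- rep(TRUE, nrow(eff))
  stopifnot(length(active) == nrow(eff))
  if (is.null(seed)) seed <- cfg$seed + 1L

  nodes <- net$nodes
  gene_ids <- nodes$id[!nodes$is_mirna]   # TFs + target genes: RNA-seq assay
  mir_ids <- nodes$id[nodes$is_mirna]
  all_ids <- c(gene_ids, mir_ids)
  n_mol <- length(all_ids)
  np <- cfg$n_pairs
  n_smp <- 2L * np

  with_seed(seed, {
    base_mean <- stats::rlnorm(n_mol, cfg$baseline_meanlog,
                               cfg$baseline_sdlog)
    names(base_mean) <- all_ids
    lib_fac <- stats::runif(n_smp, cfg$lib_factor_range[1],
                            cfg$lib_factor_range[2])

    # signed planted log2fc per molecule
    lfc <- stats::setNames(rep(0, n_mol), all_ids)
    eff_act <- eff[active, , drop = FALSE]
    if (nrow(eff_act)) {
      lfc[eff_act$tf] <- cfg$node_log2fc
      lfc[eff_act$gene] <- cfg$node_log2fc
      lfc[eff_act$mirna] <- -cfg$node_log2fc
    }

    # latent normals: independent by default, correlated inside effect loops
    z <- matrix(stats::rnorm(n_mol * n_smp), n_mol, n_smp,
                dimnames = list(all_ids, NULL))
    cond <- rep(c("tumor", "normal"), each = np)
    if (nrow(eff_act)) {
      cht <- exch_chol(cfg$edge_r_tumor)
      chn <- exch_chol(cfg$edge_r_normal)
      for (r in seq_len(nrow(eff_act))) {
        trio <- c(eff_act$tf[r], eff_act$mirna[r], eff_act$gene[r])
        raw <- matrix(stats::rnorm(3 * n_smp), n_smp, 3)
        zt <- raw[cond == "tumor", , drop = FALSE] %*% cht
        zn <- raw[cond == "normal", , drop = FALSE] %*% chn
        z[trio, cond == "tumor"] <- t(zt)
        z[trio, cond == "normal"] <- t(zn)
      }
    }

    u <- stats::pnorm(z)
    counts <- matrix(0L, n_mol, n_smp, dimnames = list(all_ids, NULL))
    for (i in seq_len(n_mol)) {
      mu <- base_mean[i] * lib_fac *
        ifelse(cond == "tumor", 2^lfc[i], 1)
      counts[i, ] <- nb_quantile(u[i, ], mu, cfg$nb_dispersion)
    }

    sample_ids <- c(sprintf("P%03dT", seq_len(np)),
                    sprintf("P%03dN", seq_len(np)))
    colnames(counts) <- sample_ids
    meta <- data.frame(
      sample_id = sample_ids,
      patient_id = rep(sprintf("P%03d", seq_len(np)), 2),
      condition = cond,
      stringsAsFactors = FALSE
    )
    study <- expression_study(tumor_label,
                              counts[gene_ids, , drop = FALSE],
                              counts[mir_ids, , drop = FALSE],
                              meta)

    truth_nodes <- data.frame(molecule_id = all_ids,
                              true_log2fc = unname(lfc),
                              stringsAsFactors = FALSE)
    truth_edges <- if (nrow(eff_act)) {
      do.call(rbind, lapply(seq_len(nrow(eff_act)), function(r) {
        trio <- c(eff_act$tf[r], eff_act$mirna[r], eff_act$gene[r])
        pairs <- rbind(trio[c(1, 2)], trio[c(1, 3)], trio[c(2, 3)])
        data.frame(mol_a = pairs[, 1], mol_b = pairs[, 2],
                   r_tumor = cfg$edge_r_tumor, r_normal = cfg$edge_r_normal,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(mol_a = character(), mol_b = character(),
                 r_tumor = numeric(), r_normal = numeric())
    }
    list(study = study,
         truth = list(ffls = eff_act, nodes = truth_nodes,
                      edges = truth_edges))
  })
}

#' Simulate a multi-tumor cohort over one shared network
#'
#' Generates one background network with planted loops, then one matched
#' tumor/normal study per tumor label. `active_matrix` controls in which
#' tumors each effect loop carries its effects (rows: planted loops,
#' columns: tumors), emulating loops dysregulated in many vs few tumor
#' types; default: active everywhere.
#'
#' @param cfg An [generator_config()].
#' @param tumor_labels Character vector of tumor codes.
#' @param active_matrix Logical matrix `n_planted_ffls x length(tumor_labels)`.
#' @return List with `net`, `truth` (network-level) and `studies`, a named
#'   list of [generate_counts()] outputs.
#' @export
simulate_cohort <- function(cfg, tumor_labels, active_matrix = NULL) {
  gen <- generate_network(cfg)
  n_eff <- nrow(gen$truth$ffls)
  if (is.null(active_matrix)) {
    active_matrix <- matrix(TRUE, n_eff, length(tumor_labels))
  }
  stopifnot(nrow(active_matrix) == n_eff,
            ncol(active_matrix) == length(tumor_labels))
  studies <- lapply(seq_along(tumor_labels), function(j) {
    generate_counts(gen, cfg, active = active_matrix[, j],
                    tumor_label = tumor_labels[j],
                    seed = cfg$seed + j)
  })
  names(studies) <- tumor_labels
  list(net = gen$net, truth = gen$truth, studies = studies)
}

#' Write a simulated study to TSV files
#'
#' Emits the exact formats the loaders consume: `network.tsv` (regulation
#' table), `counts_genes.tsv`, `counts_mirnas.tsv`, `sample_meta.tsv`,
#' `truth_ffls.tsv`, `truth_nodes.tsv`, `truth_edges.tsv`, plus
#' `manifest.tsv` with the seed and an md5 digest per file.
#'
#' @param sim Output of [generate_counts()].
#' @param net The `ffl_network` the study was generated on.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the manifest data.frame.
#' @export
write_simulation <- function(sim, net, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  study <- sim$study
  counts_df <- function(m) {
    cbind(data.frame(molecule_id = rownames(m), stringsAsFactors = FALSE),
          as.data.frame(m))
  }
  files <- c(network = "network.tsv", counts_genes = "counts_genes.tsv",
             counts_mirnas = "counts_mirnas.tsv",
             sample_meta = "sample_meta.tsv", truth_ffls = "truth_ffls.tsv",
             truth_nodes = "truth_nodes.tsv", truth_edges = "truth_edges.tsv")
  write_tsv_table(net$edges, file.path(dir, files["network"]))
  write_tsv_table(counts_df(study$counts_genes),
                  file.path(dir, files["counts_genes"]))
  write_tsv_table(counts_df(study$counts_mirnas),
                  file.path(dir, files["counts_mirnas"]))
  write_tsv_table(study$sample_meta, file.path(dir, files["sample_meta"]))
  write_tsv_table(sim$truth$ffls, file.path(dir, files["truth_ffls"]))
  write_tsv_table(sim$truth$nodes, file.path(dir, files["truth_nodes"]))
  write_tsv_table(sim$truth$edges, file.path(dir, files["truth_edges"]))
  manifest <- data.frame(
    file = unname(files),
    md5 = unname(tools::md5sum(file.path(dir, files))),
    seed = seed,
    stringsAsFactors = FALSE
  )
  write_tsv_table(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read an expression study from TSV files
#'
#' Counterpart of [write_simulation()] for the expression part: reads
#' `counts_genes.tsv`, `counts_mirnas.tsv` and `sample_meta.tsv` from a
#' directory.
#'
#' @param dir Directory holding the three files.
#' @param tumor_label Tumor code for the study.
#' @return An `expression_study`.
#' @export
read_expression_study <- function(dir, tumor_label = basename(dir)) {
  read_counts <- function(path) {
    tab <- read_tsv_table(path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    storage.mode(m) <- "numeric"
    m
  }
  expression_study(
    tumor_label,
    read_counts(file.path(dir, "counts_genes.tsv")),
    read_counts(file.path(dir, "counts_mirnas.tsv")),
    read_tsv_table(file.path(dir, "sample_meta.tsv"))
  )
}
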