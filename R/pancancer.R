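ffl_id <- function(ffls) paste(ffls$tf, ffls$mirna, ffls$gene, sep = "|")

#' Build the FFL x tumor significance matrix
#'
#' Collects per-tumor scoring results into one matrix of empirical
#' P-values (rows: FFLs, columns: tumor types). Untestable FFL-tumor cells
#' (a member molecule not detected in that tumor) are `NA`.
#'
#' @param results A list of per-tumor data.frames from [score_all_ffls()],
#'   all scored on the same FFL set.
#' @return An object of class `ffl_sig_matrix`: list with `p` (numeric
#'   matrix), `ffls` (the FFL table) and `alpha` (significance level taken
#'   from the first result).
#' @export
significance_matrix <- function(results) {
  stopifnot(length(results) >= 1)
  first <- results[[1]]
  ids <- ffl_id(first)
  tumors <- unname(vapply(results, function(r) r$tumor[1], character(1)))
  p <- matrix(NA_real_, nrow = length(ids), ncol = length(tumors),
              dimnames = list(ids, tumors))
  for (j in seq_along(results)) {
    r <- results[[j]]
    if (!identical(ffl_id(r), ids)) {
      stop("all results must be scored on the same FFL set, in order")
    }
    p[, j] <- r$empirical_p
  }
  alpha <- attr(first, "alpha")
  structure(
    list(p = p, ffls = first[, c("tf", "mirna", "gene", "ffl_type")],
         alpha = if (is.null(alpha)) 0.05 else alpha),
    class = "ffl_sig_matrix"
  )
}

sig_flags <- function(sig, alpha = NULL) {
  if (is.null(alpha)) alpha <- sig$alpha
  flags <- sig$p < alpha
  flags[is.na(flags)] <- FALSE  # untestable cells count as not dysregulated
  flags
}

#' Select pan-cancer FFLs
#'
#' A loop is pan-cancer when it is dysregulated (empirical P below `alpha`)
#' in at least `min_tumors` tumor types. Untestable cells count as not
#' dysregulated but remain distinguishable in the returned table.
#'
#' @param sig An `ffl_sig_matrix`.
#' @param min_tumors Minimum number of tumor types (default 5).
#' @param alpha Significance level; defaults to the matrix's own.
#' @return A data.frame of the selected FFLs with `n_tumors_dysregulated`
#'   and `n_tumors_untestable`, ordered by decreasing tumor count. The full
#'   per-FFL counts (all loops) are attached as attribute `"counts"`.
#' @export
select_pancancer <- function(sig, min_tumors = 5, alpha = NULL) {
  stopifnot(inherits(sig, "ffl_sig_matrix"))
  flags <- sig_flags(sig, alpha)
  n_dys <- rowSums(flags)
  n_unt <- rowSums(is.na(sig$p))
  counts <- cbind(sig$ffls,
                  n_tumors_dysregulated = n_dys,
                  n_tumors_untestable = n_unt)
  sel <- counts[counts$n_tumors_dysregulated >= min_tumors, , drop = FALSE]
  sel <- sel[order(-sel$n_tumors_dysregulated, sel$tf, sel$mirna, sel$gene),
             , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "counts") <- counts
  sel
}

#' Permutation P-value for the pan-cancer FFL count
#'
#' Each replicate shuffles, within every tumor type, which tested FFLs
#' carry that tumor's dysregulated flags (per-tumor flag counts are
#' preserved exactly), then recounts how many FFLs are flagged in at least
#' `min_tumors` tumors. The P-value is the fraction of replicates whose
#' count is at least the observed count.
#'
#' @param sig An `ffl_sig_matrix`.
#' @param min_tumors Pan-cancer threshold (default 5).
#' @param reps Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level; defaults to the matrix's own.
#' @return List with `observed`, `p_value`, `null_counts` (length `reps`).
#' @export
pancancer_count_null <- function(sig, min_tumors = 5, reps = 1000,
                                 seed = NULL, alpha = NULL) {
  stopifnot(inherits(sig, "ffl_sig_matrix"))
  flags <- sig_flags(sig, alpha)
  tested <- !is.na(sig$p)
  observed <- sum(rowSums(flags) >= min_tumors)
  null_counts <- with_seed(seed, {
    vapply(seq_len(reps), function(rep) {
      perm <- flags
      for (j in seq_len(ncol(flags))) {
        idx <- which(tested[, j])
        perm[idx, j] <- flags[idx, j][sample.int(length(idx))]
      }
      sum(rowSums(perm) >= min_tumors)
    }, numeric(1))
  })
  list(observed = observed,
       p_value = mean(null_counts >= observed),
       null_counts = null_counts)
}

#' Hypergeometric upper-tail test
#'
#' `P(X >= k)` for drawing `k` marked items in a sample of `n` from a
#' population of `N` items of which `K` are marked; the observed value is
#' included in the tail.
#'
#' @param k Observed marked items in the sample.
#' @param K Marked items in the population.
#' @param n Sample size.
#' @param N Population size.
#' @return The upper-tail P-value.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0) {
    stop("inconsistent hypergeometric counts (k > min(K, n) or K, n > N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' FFL-class enrichment among pan-cancer FFLs
#'
#' For each FFL class, a one-sided hypergeometric test of whether the
#' pan-cancer set contains more loops of that class than expected from the
#' background FFL set.
#'
#' @param pan_counts Named counts of pan-cancer FFLs per class (e.g.
#'   `c("TF-FFL" = 18, ...)`).
#' @param background_counts Named counts of all FFLs per class.
#' @return A data.frame: one row per class with `k`, `K`, `n`, `N`,
#'   `p_value`.
#' @export
ffl_type_enrichment <- function(pan_counts, background_counts) {
  types <- names(background_counts)
  stopifnot(!is.null(types))
  N <- sum(background_counts)
  n <- sum(pan_counts)
  rows <- lapply(types, function(tp) {
    k <- if (tp %in% names(pan_counts)) pan_counts[[tp]] else 0
    K <- background_counts[[tp]]
    data.frame(ffl_type = tp, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sided Fisher test of annotated proportions
#'
#' Compares the proportion of annotated molecules (e.g. cancer-gene or
#' drug-target membership) between two sets via Fisher's exact test on the
#' 2x2 table.
#'
#' @param in_annotated,in_total Annotated count and size of the focal set.
#' @param out_annotated,out_total Annotated count and size of the
#'   comparison set.
#' @return A list with `table`, `odds_ratio`, `p_value`, and `flagged`
#'   (TRUE when a zero marginal made the test degenerate, P forced to 1).
#' @export
set_proportion_test <- function(in_annotated, in_total, out_annotated,
                                out_total) {
  stopifnot(in_annotated <= in_total, out_annotated <= out_total)
  tab <- matrix(c(in_annotated, in_total - in_annotated,
                  out_annotated, out_total - out_annotated),
                nrow = 2,
                dimnames = list(c("annotated", "not"), c("in", "out")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1,
                flagged = TRUE))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, flagged = FALSE)
}

#' Compare topology metrics between node groups
#'
#' One-sided Wilcoxon rank-sum test of whether `group` nodes have larger
#' degree or betweenness than `reference` nodes on the background network.
#'
#' @param topo A [topology_report()] result.
#' @param group Character vector of node ids (must exist in the network).
#' @param reference Node ids to compare against (default: all network
#'   nodes).
#' @param metric `"degree"` or `"betweenness"`.
#' @return A list with `p_value`, `median_group`, `median_reference`,
#'   `n_group`, `n_reference`.
#' @export
topo_comparison <- function(topo, group, reference = NULL,
                            metric = c("degree", "betweenness")) {
  metric <- match.arg(metric)
  nodes <- topo$nodes
  if (is.null(reference)) reference <- nodes$id
  if (!all(group %in% nodes$id) || !all(reference %in% nodes$id)) {
    stop("group/reference contain node(s) absent from the network")
  }
  x <- nodes[[metric]][match(group, nodes$id)]
  y <- nodes[[metric]][match(reference, nodes$id)]
  wt <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)
  list(p_value = wt$p.value,
       median_group = stats::median(x),
       median_reference = stats::median(y),
       n_group = length(x), n_reference = length(y))
}

#' Differential-expression frequency across tumor types
#'
#' Tabulates, for every molecule, the number of tumor types in which it was
#' called differentially expressed, plus the up/down pattern matrix and the
#' histogram of those counts.
#'
#' @param de_calls Named list (by tumor code) of data.frames from
#'   [call_de()].
#' @return A list with `pattern` (molecule x tumor character matrix of
#'   calls), `n_tumors_de` (named integer vector) and `histogram` (table of
#'   `n_tumors_de`; sums to the number of molecules).
#' @export
de_frequency <- function(de_calls) {
  stopifnot(length(de_calls) >= 1)
  ids <- sort(unique(unlist(lapply(de_calls, `[[`, "molecule_id"))))
  tumors <- names(de_calls)
  if (is.null(tumors)) tumors <- paste0("tumor", seq_along(de_calls))
  pattern <- matrix(NA_character_, length(ids), length(tumors),
                    dimnames = list(ids, tumors))
  for (j in seq_along(de_calls)) {
    d <- de_calls[[j]]
    pattern[match(d$molecule_id, ids), j] <- d$de_call
  }
  is_de <- pattern %in% c("up", "down")
  dim(is_de) <- dim(pattern)
  n_de <- rowSums(is_de, na.rm = TRUE)
  names(n_de) <- ids
  list(pattern = pattern, n_tumors_de = n_de,
       histogram = table(factor(n_de, levels = 0:length(tumors))))
}

#' Anticancer (ATC class) enrichment of drugs hitting pan-cancer FFL genes
#'
#' Hypergeometric upper-tail test of whether drugs that target gene
#' products in pan-cancer FFLs are enriched for a given ATC prefix
#' (default `L01`, antineoplastic agents) relative to all drugs with an ATC
#' code. Drugs without an ATC code are excluded and counted.
#'
#' @param pan_genes Character vector of pan-cancer FFL gene ids.
#' @param drug_targets data.frame `drug_id`, `target_gene_id`.
#' @param drug_atc data.frame `drug_id`, `atc_code` (a drug may have
#'   several rows).
#' @param atc_prefix ATC code prefix defining the drug class of interest.
#' @return A list with `k`, `K`, `n`, `N`, `p_value`,
#'   `drugs_in_sample` and `n_excluded_no_atc`.
#' @export
drug_atc_enrichment <- function(pan_genes, drug_targets, drug_atc,
                                atc_prefix = "L01") {
  stopifnot(all(c("drug_id", "target_gene_id") %in% names(drug_targets)))
  stopifnot(all(c("drug_id", "atc_code") %in% names(drug_atc)))
  all_drugs <- unique(drug_targets$drug_id)
  has_atc <- all_drugs %in% drug_atc$drug_id[!is.na(drug_atc$atc_code) &
                                               drug_atc$atc_code != ""]
  excluded <- all_drugs[!has_atc]
  pop <- all_drugs[has_atc]
  marked <- vapply(pop, function(d) {
    any(startsWith(drug_atc$atc_code[drug_atc$drug_id == d], atc_prefix))
  }, logical(1))
  sample_drugs <- unique(
    drug_targets$drug_id[drug_targets$target_gene_id %in% pan_genes])
  sample_drugs <- intersect(sample_drugs, pop)
  k <- sum(sample_drugs %in% pop[marked])
  res <- list(k = k, K = sum(marked), n = length(sample_drugs),
              N = length(pop),
              p_value = hypergeom_upper(k, sum(marked),
                                        length(sample_drugs), length(pop)),
              drugs_in_sample = sample_drugs,
              n_excluded_no_atc = length(excluded))
  res
}

#' Stability of results under sample subsampling
#'
#' Re-runs differential expression and FFL scoring on random subsets of the
#' matched pairs and reports the Spearman correlation (with P-values) of
#' (a) molecule DE P-value ranks and (b) FFL composite-score ranks against
#' the full-data run.
#'
#' @param study An `expression_study`.
#' @param net The background `ffl_network`.
#' @param ffls FFL table to score.
#' @param pair_counts Integer vector of pair counts to subsample to.
#' @param seed Integer seed (one draw per pair count, in order).
#' @param lambda,n_perm Scoring parameters (the permutation null is only
#'   needed for significance, not for the rank comparison, so `n_perm` may
#'   be small).
#' @return data.frame: one row per pair count with `rho_de`, `p_de`,
#'   `rho_ffl`, `p_ffl`, `n_common_molecules`, `n_common_ffls`.
#' @export
stability_subsample <- function(study, net, ffls, pair_counts, seed = NULL,
                                lambda = 0.5, n_perm = 1000) {
  stopifnot(inherits(study, "expression_study"))
  if (any(pair_counts > nrow(study$pairs))) {
    stop("requested pair count exceeds available pairs")
  }
  if (any(pair_counts < 4)) {
    stop("pair counts below 4 leave the edge score undefined")
  }
  run_on <- function(st) {
    de <- differential_expression(st)
    ctx <- build_score_context(st, de, net)
    sc <- score_all_ffls(ffls, ctx, lambda = lambda, n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + 1L)
    list(de = de, scores = sc)
  }
  full <- run_on(study)
  rows <- with_seed(seed, {
    lapply(pair_counts, function(np) {
      keep <- if (np == nrow(study$pairs)) seq_len(nrow(study$pairs))
      else sample.int(nrow(study$pairs), np)
      pairs <- study$pairs[keep, , drop = FALSE]
      samples <- c(pairs$tumor_sample, pairs$normal_sample)
      sub <- expression_study(
        study$tumor_label,
        study$counts_genes[, samples, drop = FALSE],
        study$counts_mirnas[, samples, drop = FALSE],
        study$sample_meta[study$sample_meta$sample_id %in% samples, ]
      )
      res <- run_on(sub)
      de_ids <- intersect(full$de$molecule_id[!is.na(full$de$pvalue)],
                          res$de$molecule_id[!is.na(res$de$pvalue)])
      ct_de <- stats::cor.test(
        full$de$pvalue[match(de_ids, full$de$molecule_id)],
        res$de$pvalue[match(de_ids, res$de$molecule_id)],
        method = "spearman", exact = FALSE)
      ok <- full$scores$testable & res$scores$testable
      ct_ffl <- stats::cor.test(full$scores$S[ok], res$scores$S[ok],
                                method = "spearman", exact = FALSE)
      data.frame(n_pairs = np,
                 rho_de = unname(ct_de$estimate), p_de = ct_de$p.value,
                 rho_ffl = unname(ct_ffl$estimate), p_ffl = ct_ffl$p.value,
                 n_common_molecules = length(de_ids),
                 n_common_ffls = sum(ok))
    })
  })
  do.call(rbind, rows)
}

#' Write / read a significance matrix
#'
#' TSV layout: first column `ffl_id` (`tf|mirna|gene`), then `tf`, `mirna`,
#' `gene`, `ffl_type`, then one column per tumor code holding the empirical
#' P-value or `NA` for untestable cells.
#'
#' @param sig An `ffl_sig_matrix`.
#' @param path File path.
#' @param alpha Significance level stored on reading (default 0.05).
#' @return `read_significance_matrix` returns an `ffl_sig_matrix`.
#' @export
write_significance_matrix <- function(sig, path) {
  tab <- cbind(data.frame(ffl_id = rownames(sig$p),
                          stringsAsFactors = FALSE),
               sig$ffls, as.data.frame(sig$p))
  write_tsv_table(tab, path)
  invisible(path)
}

#' @rdname write_significance_matrix
#' @export
read_significance_matrix <- function(path, alpha = 0.05) {
  tab <- read_tsv_table(path)
  meta <- c("ffl_id", "tf", "mirna", "gene", "ffl_type")
  stopifnot(all(meta %in% names(tab)))
  tumors <- setdiff(names(tab), meta)
  p <- as.matrix(tab[, tumors, drop = FALSE])
  rownames(p) <- tab$ffl_id
  structure(list(p = p, ffls = tab[, c("tf", "mirna", "gene", "ffl_type")],
                 alpha = alpha),
            class = "ffl_sig_matrix")
}
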