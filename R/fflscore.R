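#' Node score: inverse-normal transform of a differential-expression P-value
#'
#' `N = qnorm(1 - p)`: small P-values map to large positive scores, p = 0.5
#' maps to 0. P-values are clipped to `[1e-16, 1 - 1e-16]` first, bounding
#' scores at about +/- 8.22.
#'
#' @param p P-value(s) in (0, 1); values outside are clipped with a warning.
#' @return Numeric score(s), strictly decreasing in `p`.
#' @export
node_score <- function(p) {
  stats::qnorm(1 - clip_prob(p))
}

#' Fisher z-transformation of a correlation
#'
#' `F(r) = 0.5 * ln((1 + r) / (1 - r))` = atanh(r). `|r|` is clipped to
#' `1 - 1e-12` so the transform stays finite.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  atanh(r)
}

# Spearman correlation via Pearson on average ranks; a constant vector has
# undefined correlation and yields 0 (flagged via attribute).
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    out <- 0
    attr(out, "constant") <- TRUE
    return(out)
  }
  stats::cor(rx, ry)
}

# Standardized Fisher-z difference of tumor vs normal correlations.
# Variance terms 1.06/(n - 3) per condition.
fisher_z_diff <- function(r_tumor, r_normal, n_tumor, n_normal) {
  (fisher_z(r_tumor) - fisher_z(r_normal)) /
    sqrt(1.06 / (n_tumor - 3) + 1.06 / (n_normal - 3))
}

# Quantile transform of the two-sided normal P-value of |D|:
# E = qnorm(1 - 2 * (1 - pnorm(|D|))), with probability clipping.
# |D| below 1e-8 is treated as exactly 0: near the clipped lower bound the
# transform is steep, and correlation differences that small are pure
# floating-point noise.
edge_score_from_d <- function(d) {
  d[abs(d) < 1e-8] <- 0
  p_two <- 2 * (1 - stats::pnorm(abs(d)))
  stats::qnorm(1 - clip_prob(p_two, warn = FALSE))
}

#' Edge score: differential co-expression of one regulatory edge
#'
#' Spearman correlations of the two endpoint molecules are computed
#' separately in tumor and normal samples (on normalized counts), Fisher-z
#' transformed, and their difference standardized with `1.06/(n - 3)`
#' variance terms. The score is the inverse-normal transform of the
#' two-sided normal P-value of `|D|`, so it depends on `D` only through its
#' magnitude and increases with `|D|`.
#'
#' @param x_tumor,y_tumor Normalized expression of the two molecules in
#'   tumor samples (aligned vectors, length >= 4).
#' @param x_normal,y_normal Same for normal samples.
#' @return A list with `r_tumor`, `r_normal`, `D`, `E` and a logical
#'   `constant_flagged` (a constant vector forced its correlation to 0).
#' @export
edge_score <- function(x_tumor, y_tumor, x_normal, y_normal) {
  n_t <- length(x_tumor); n_n <- length(x_normal)
  stopifnot(length(y_tumor) == n_t, length(y_normal) == n_n)
  if (n_t < 4 || n_n < 4) {
    stop("edge score requires at least 4 samples per condition (n - 3 > 0)")
  }
  r_t <- spearman_rho(x_tumor, y_tumor)
  r_n <- spearman_rho(x_normal, y_normal)
  flagged <- isTRUE(attr(r_t, "constant")) || isTRUE(attr(r_n, "constant"))
  d <- fisher_z_diff(as.numeric(r_t), as.numeric(r_n), n_t, n_n)
  list(r_tumor = as.numeric(r_t), r_normal = as.numeric(r_n), D = d,
       E = edge_score_from_d(d), constant_flagged = flagged)
}

#' Composite FFL score
#'
#' `S = lambda * mean(node scores) + (1 - lambda) * mean(edge scores)` with
#' three node scores and three edge scores per loop (an FB-FFL has four
#' regulatory edges but only three distinct molecule pairs; the TF--miRNA
#' pair is scored once).
#'
#' @param node_scores Numeric vector of 3 node scores.
#' @param edge_scores Numeric vector of 3 edge scores.
#' @param lambda Weight in `[0, 1]` on the node component (default 0.5).
#' @return The composite score S.
#' @export
ffl_score <- function(node_scores, edge_scores, lambda = 0.5) {
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  stopifnot(length(node_scores) == 3, length(edge_scores) == 3)
  lambda * mean(node_scores) + (1 - lambda) * mean(edge_scores)
}

# Row-wise standardized average ranks of a molecules-x-samples matrix.
# Constant rows become all-zero (so any correlation with them is 0).
standardized_ranks <- function(mat) {
  if (!nrow(mat)) return(mat)
  z <- t(apply(mat, 1, rank))
  mu <- rowMeans(z)
  s <- sqrt(rowSums((z - mu)^2) / (ncol(z) - 1))
  z <- (z - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Precomputed per-tumor scoring context
#'
#' Bundles everything FFL scoring needs for one tumor type: clipped node
#' P-values, standardized rank matrices of normalized counts (CPM) per
#' condition (so each Spearman correlation is a dot product), and the
#' detected molecules available for each role in the network.
#'
#' @param study An `expression_study`.
#' @param de Result of [differential_expression()] on `study`.
#' @param net The background `ffl_network` (for role pools).
#' @param detected Optional masks from [filter_low_expression()].
#' @return An object of class `ffl_score_context`.
#' @export
build_score_context <- function(study, de, net, detected = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(detected)) detected <- filter_low_expression(study)
  if (nrow(study$pairs) < 4) {
    stop("scoring requires at least 4 sample pairs (n - 3 > 0)")
  }
  det_ids <- c(names(detected$genes)[detected$genes],
               names(detected$mirnas)[detected$mirnas])
  # a detected molecule without a P-value (e.g. absent from an external DE
  # table) cannot be scored and is dropped from the context
  has_p <- !is.na(de$pvalue[match(det_ids, de$molecule_id)])
  det_ids <- det_ids[has_p]
  norm_all <- rbind(cpm(study$counts_genes), cpm(study$counts_mirnas))
  norm_det <- norm_all[det_ids, , drop = FALSE]
  tum <- tumor_samples(study); nrm <- normal_samples(study)

  p_lookup <- de$pvalue[match(det_ids, de$molecule_id)]
  node_p <- clip_prob(p_lookup, warn = FALSE)
  names(node_p) <- det_ids

  roles <- list(
    tf = intersect(net$nodes$id[net$nodes$is_tf], det_ids),
    mirna = intersect(net$nodes$id[net$nodes$is_mirna], det_ids),
    gene = intersect(net$nodes$id[net$nodes$is_gene], det_ids)
  )

  structure(
    list(
      tumor_label = study$tumor_label,
      ids = det_ids,
      node_p = node_p,
      node_scores = stats::qnorm(1 - node_p),
      z_tumor = standardized_ranks(norm_det[, tum, drop = FALSE]),
      z_normal = standardized_ranks(norm_det[, nrm, drop = FALSE]),
      n_tumor = length(tum),
      n_normal = length(nrm),
      roles = roles
    ),
    class = "ffl_score_context"
  )
}

# Vectorized edge scores for index pairs (rows of the context matrices).
context_edge_scores <- function(ctx, i, j) {
  r_t <- rowSums(ctx$z_tumor[i, , drop = FALSE] *
                   ctx$z_tumor[j, , drop = FALSE]) / (ctx$n_tumor - 1)
  r_n <- rowSums(ctx$z_normal[i, , drop = FALSE] *
                   ctx$z_normal[j, , drop = FALSE]) / (ctx$n_normal - 1)
  r_t <- pmin(pmax(r_t, -1), 1)
  r_n <- pmin(pmax(r_n, -1), 1)
  d <- fisher_z_diff(r_t, r_n, ctx$n_tumor, ctx$n_normal)
  list(r_tumor = r_t, r_normal = r_n, D = d, E = edge_score_from_d(d))
}

# Composite scores for triples given as index vectors into ctx$ids.
context_triple_scores <- function(ctx, i_tf, i_mir, i_gene, lambda = 0.5) {
  ns <- (ctx$node_scores[i_tf] + ctx$node_scores[i_mir] +
           ctx$node_scores[i_gene]) / 3
  e1 <- context_edge_scores(ctx, i_tf, i_mir)$E
  e2 <- context_edge_scores(ctx, i_tf, i_gene)$E
  e3 <- context_edge_scores(ctx, i_mir, i_gene)$E
  lambda * ns + (1 - lambda) * (e1 + e2 + e3) / 3
}

#' Permutation null distribution of FFL scores
#'
#' Draws `n_perm` random molecule triples from the detected molecules and
#' scores each with the same node/edge machinery as a real loop (the three
#' pairs TF--miRNA, TF--gene, miRNA--gene are scored whether or not a
#' regulation exists). In `"role"` mode (default) the triple respects roles
#' (one detected TF, one miRNA, one gene, drawn uniformly with
#' replacement); in `"uniform"` mode three distinct detected molecules are
#' drawn irrespective of role.
#'
#' @param ctx An `ffl_score_context`.
#' @param n_perm Number of random triples (paper-scale default 1e5).
#' @param seed Integer seed; the same seed reproduces the null exactly.
#' @param lambda Node/edge weight, as in [ffl_score()].
#' @param null_mode `"role"` or `"uniform"`.
#' @return An object of class `ffl_permutation_null`: list with `scores`
#'   (length `n_perm`), `n_perm`, `seed`, `lambda`, `null_mode`.
#' @export
permutation_null <- function(ctx, n_perm = 1e5, seed = NULL, lambda = 0.5,
                             null_mode = c("role", "uniform")) {
  stopifnot(inherits(ctx, "ffl_score_context"))
  null_mode <- match.arg(null_mode)
  scores <- with_seed(seed, {
    if (null_mode == "role") {
      pools <- lapply(ctx$roles, function(ids) match(ids, ctx$ids))
      if (any(lengths(pools) < 1)) {
        stop("need at least one detected molecule per role (TF, miRNA, gene)")
      }
      draw <- function(pool) pool[sample.int(length(pool), n_perm,
                                             replace = TRUE)]
      i_tf <- draw(pools$tf)
      i_mir <- draw(pools$mirna)
      i_gene <- draw(pools$gene)
      # a molecule holding two roles must not appear twice in one triple
      bad <- which(i_tf == i_mir | i_tf == i_gene | i_mir == i_gene)
      while (length(bad)) {
        i_tf[bad] <- pools$tf[sample.int(length(pools$tf), length(bad),
                                         replace = TRUE)]
        i_mir[bad] <- pools$mirna[sample.int(length(pools$mirna),
                                             length(bad), replace = TRUE)]
        i_gene[bad] <- pools$gene[sample.int(length(pools$gene),
                                             length(bad), replace = TRUE)]
        bad <- bad[i_tf[bad] == i_mir[bad] | i_tf[bad] == i_gene[bad] |
                     i_mir[bad] == i_gene[bad]]
      }
    } else {
      n_mol <- length(ctx$ids)
      if (n_mol < 3) stop("need at least 3 detected molecules")
      m <- t(replicate(n_perm, sample.int(n_mol, 3)))
      i_tf <- m[, 1]; i_mir <- m[, 2]; i_gene <- m[, 3]
    }
    context_triple_scores(ctx, i_tf, i_mir, i_gene, lambda)
  })
  structure(
    list(scores = as.numeric(scores), n_perm = n_perm, seed = seed,
         lambda = lambda, null_mode = null_mode,
         tumor_label = ctx$tumor_label),
    class = "ffl_permutation_null"
  )
}

#' Empirical P-value of an observed FFL score
#'
#' Default (`"paper"`): the fraction of null scores strictly greater than
#' the observed score, `P = N(S_random > S) / N_p` (can be exactly 0). The
#' `"pseudocount"` variant returns `(N + 1) / (N_p + 1)`, strictly
#' positive.
#'
#' @param s Observed score(s).
#' @param null An `ffl_permutation_null` (or numeric vector of null scores).
#' @param variant `"paper"` or `"pseudocount"`.
#' @return Empirical P-value(s) in `[0, 1]`.
#' @export
empirical_p <- function(s, null, variant = c("paper", "pseudocount")) {
  variant <- match.arg(variant)
  scores <- if (inherits(null, "ffl_permutation_null")) null$scores else null
  n_gt <- vapply(s, function(si) sum(scores > si), numeric(1))
  if (variant == "paper") n_gt / length(scores)
  else (n_gt + 1) / (length(scores) + 1)
}

#' Score all FFLs of one tumor type
#'
#' For every loop whose TF, miRNA and gene are all detected, computes the
#' three node scores, the three edge scores, the composite score S and the
#' permutation-based empirical P-value; loops with an undetected member are
#' reported as untestable (not as non-significant).
#'
#' @param ffls FFL data.frame from [enumerate_ffls()].
#' @param ctx An `ffl_score_context` from [build_score_context()].
#' @param null Optional precomputed `ffl_permutation_null`; built with
#'   `n_perm` and `seed` if missing.
#' @param lambda Node/edge weight (default 0.5).
#' @param n_perm Permutations for the null when `null` is missing.
#' @param seed Seed for the null when `null` is missing.
#' @param alpha Significance level for the dysregulated flag (default 0.05).
#' @param null_mode Passed to [permutation_null()].
#' @param variant Passed to [empirical_p()].
#' @return A data.frame, one row per FFL: identifiers, `tumor`, `testable`,
#'   node and edge scores, `S`, `empirical_p`, `dysregulated`.
#' @export
score_all_ffls <- function(ffls, ctx, null = NULL, lambda = 0.5,
                           n_perm = 1e5, seed = NULL, alpha = 0.05,
                           null_mode = c("role", "uniform"),
                           variant = c("paper", "pseudocount")) {
  stopifnot(inherits(ctx, "ffl_score_context"))
  null_mode <- match.arg(null_mode)
  variant <- match.arg(variant)
  if (is.null(null)) {
    null <- permutation_null(ctx, n_perm = n_perm, seed = seed,
                             lambda = lambda, null_mode = null_mode)
  }
  i_tf <- match(ffls$tf, ctx$ids)
  i_mir <- match(ffls$mirna, ctx$ids)
  i_gene <- match(ffls$gene, ctx$ids)
  testable <- !is.na(i_tf) & !is.na(i_mir) & !is.na(i_gene)

  out <- data.frame(
    tf = ffls$tf, mirna = ffls$mirna, gene = ffls$gene,
    ffl_type = ffls$ffl_type, tumor = ctx$tumor_label,
    testable = testable,
    node_score_tf = NA_real_, node_score_mirna = NA_real_,
    node_score_gene = NA_real_,
    edge_score_tf_mirna = NA_real_, edge_score_tf_gene = NA_real_,
    edge_score_mirna_gene = NA_real_,
    S = NA_real_, empirical_p = NA_real_, dysregulated = NA,
    stringsAsFactors = FALSE
  )
  if (any(testable)) {
    ti <- i_tf[testable]; mi <- i_mir[testable]; gi <- i_gene[testable]
    out$node_score_tf[testable] <- ctx$node_scores[ti]
    out$node_score_mirna[testable] <- ctx$node_scores[mi]
    out$node_score_gene[testable] <- ctx$node_scores[gi]
    out$edge_score_tf_mirna[testable] <- context_edge_scores(ctx, ti, mi)$E
    out$edge_score_tf_gene[testable] <- context_edge_scores(ctx, ti, gi)$E
    out$edge_score_mirna_gene[testable] <- context_edge_scores(ctx, mi, gi)$E
    node_mean <- (out$node_score_tf[testable] +
                    out$node_score_mirna[testable] +
                    out$node_score_gene[testable]) / 3
    edge_mean <- (out$edge_score_tf_mirna[testable] +
                    out$edge_score_tf_gene[testable] +
                    out$edge_score_mirna_gene[testable]) / 3
    out$S[testable] <- lambda * node_mean + (1 - lambda) * edge_mean
    out$empirical_p[testable] <- empirical_p(out$S[testable], null, variant)
    out$dysregulated[testable] <- out$empirical_p[testable] < alpha
  }
  attr(out, "null") <- null
  attr(out, "alpha") <- alpha
  attr(out, "lambda") <- lambda
  out
}
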