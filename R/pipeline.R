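#' Run the full per-tumor analysis
#'
#' Executes the pipeline stages for one tumor type in order: expression
#' filter, differential expression, scoring context, permutation null, FFL
#' scoring. FFLs are enumerated from the network unless supplied.
#'
#' @param study An `expression_study`.
#' @param net The background `ffl_network`.
#' @param ffls Optional FFL table (default: [enumerate_ffls()] on `net`).
#' @param lambda Node/edge weight (default 0.5, balancing both parts).
#' @param n_perm Permutations for the null (paper-scale default 1e5).
#' @param seed Integer seed for the permutation null.
#' @param alpha Dysregulation significance level (default 0.05).
#' @param de_method,external Passed to [differential_expression()].
#' @param null_mode,variant Passed to [permutation_null()] /
#'   [empirical_p()].
#' @param verbose Log per-stage counts.
#' @return A list with `de`, `detected`, `context`, `null`, `scores`
#'   (the [score_all_ffls()] table) and `tumor_label`.
#' @export
run_tumor_study <- function(study, net, ffls = NULL, lambda = 0.5,
                            n_perm = 1e5, seed = NULL, alpha = 0.05,
                            de_method = c("exact-nb", "external"),
                            external = NULL,
                            null_mode = c("role", "uniform"),
                            variant = c("paper", "pseudocount"),
                            verbose = FALSE) {
  de_method <- match.arg(de_method)
  if (is.null(ffls)) ffls <- enumerate_ffls(net)
  detected <- filter_low_expression(study)
  if (verbose) {
    message(sprintf("[%s] detected: %d/%d genes, %d/%d miRNAs",
                    study$tumor_label,
                    sum(detected$genes), length(detected$genes),
                    sum(detected$mirnas), length(detected$mirnas)))
  }
  de <- differential_expression(study, method = de_method,
                                detected = detected, external = external)
  de <- call_de(de)
  ctx <- build_score_context(study, de, net, detected = detected)
  null <- permutation_null(ctx, n_perm = n_perm, seed = seed,
                           lambda = lambda, null_mode = null_mode)
  scores <- score_all_ffls(ffls, ctx, null = null, lambda = lambda,
                           alpha = alpha, variant = variant)
  if (verbose) {
    message(sprintf(
      "[%s] FFLs: %d total, %d testable, %d dysregulated (alpha=%g)",
      study$tumor_label, nrow(scores), sum(scores$testable),
      sum(scores$dysregulated, na.rm = TRUE), alpha))
  }
  list(tumor_label = study$tumor_label, de = de, detected = detected,
       context = ctx, null = null, scores = scores)
}

#' Run the pan-cancer aggregation over several tumor studies
#'
#' Scores the same FFL set in every study (one permutation null per tumor,
#' seeded `seed + tumor index`), builds the significance matrix, selects
#' pan-cancer FFLs and tests the pan-cancer count against within-tumor
#' label shuffles. A study that fails is logged and excluded rather than
#' aborting the rest.
#'
#' @param studies Named list of `expression_study` objects.
#' @param net Background `ffl_network`.
#' @param ffls Optional FFL table (default enumerated from `net`).
#' @param min_tumors Pan-cancer threshold (default 5).
#' @param count_null_reps Permutations for the pan-cancer count test
#'   (0 disables it).
#' @param seed Base seed.
#' @param ... Further arguments to [run_tumor_study()].
#' @return A list with `runs` (per-tumor results), `sig`
#'   (`ffl_sig_matrix`), `pan` (selected pan-cancer FFLs), `count_null`,
#'   `de_freq` (DE frequency across tumors) and `failed` (labels of tumors
#'   that errored).
#' @export
run_pancancer <- function(studies, net, ffls = NULL, min_tumors = 5,
                          count_null_reps = 1000, seed = NULL, ...) {
  stopifnot(length(studies) >= 1)
  if (is.null(ffls)) ffls <- enumerate_ffls(net)
  labels <- names(studies)
  if (is.null(labels)) labels <- vapply(studies, `[[`, "", "tumor_label")
  runs <- list(); failed <- character(0)
  for (j in seq_along(studies)) {
    seed_j <- if (is.null(seed)) NULL else seed + j
    res <- tryCatch(
      run_tumor_study(studies[[j]], net, ffls = ffls, seed = seed_j, ...),
      error = function(e) {
        warning("tumor '", labels[j], "' failed and was excluded: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(res)) failed <- c(failed, labels[j]) else
      runs[[labels[j]]] <- res
  }
  if (!length(runs)) stop("all tumor studies failed")
  sig <- significance_matrix(lapply(runs, `[[`, "scores"))
  pan <- select_pancancer(sig, min_tumors = min_tumors)
  cnull <- if (count_null_reps > 0) {
    pancancer_count_null(sig, min_tumors = min_tumors,
                         reps = count_null_reps,
                         seed = if (is.null(seed)) NULL else seed)
  } else NULL
  de_freq <- de_frequency(lapply(runs, `[[`, "de"))
  list(runs = runs, sig = sig, pan = pan, count_null = cnull,
       de_freq = de_freq, failed = failed)
}
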