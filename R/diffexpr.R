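#' Paired tumor/normal expression study
#'
#' Bundles gene and mature-miRNA read-count matrices with sample metadata
#' for one tumor type. The design is matched: every patient contributes one
#' tumor and one normal sample, so the two groups have equal size.
#'
#' @param tumor_label Tumor-type code (e.g. `"BRCA"`).
#' @param counts_genes Integer matrix, genes x samples; rownames are gene
#'   ids, colnames sample ids.
#' @param counts_mirnas Integer matrix, mature miRNAs x samples, same
#'   samples as `counts_genes`.
#' @param sample_meta data.frame with columns `sample_id`, `patient_id`,
#'   `condition` (`"tumor"` or `"normal"`).
#' @return An object of class `expression_study` with the above fields plus
#'   `pairs`, a data.frame of (patient_id, tumor_sample, normal_sample).
#' @export
expression_study <- function(tumor_label, counts_genes, counts_mirnas,
                             sample_meta) {
  stopifnot(is.matrix(counts_genes), is.matrix(counts_mirnas))
  stopifnot(all(c("sample_id", "patient_id", "condition") %in%
                  names(sample_meta)))
  sample_meta$condition <- match.arg(sample_meta$condition,
                                     c("tumor", "normal"),
                                     several.ok = TRUE)
  samples <- sample_meta$sample_id
  if (anyDuplicated(samples)) stop("duplicated sample ids in metadata")
  if (!identical(sort(colnames(counts_genes)), sort(samples)) ||
      !identical(sort(colnames(counts_mirnas)), sort(samples))) {
    stop("count matrix columns must match sample metadata exactly")
  }
  counts_genes <- counts_genes[, samples, drop = FALSE]
  counts_mirnas <- counts_mirnas[, samples, drop = FALSE]
  if (any(counts_genes < 0) || any(counts_mirnas < 0)) {
    stop("counts must be non-negative")
  }
  tum <- sample_meta[sample_meta$condition == "tumor", ]
  nrm <- sample_meta[sample_meta$condition == "normal", ]
  if (nrow(tum) != nrow(nrm)) {
    stop("matched design requires equal numbers of tumor and normal samples")
  }
  if (!setequal(tum$patient_id, nrm$patient_id) ||
      anyDuplicated(tum$patient_id) || anyDuplicated(nrm$patient_id)) {
    stop("every patient must contribute exactly one tumor and one normal sample")
  }
  pairs <- data.frame(
    patient_id = tum$patient_id,
    tumor_sample = tum$sample_id,
    normal_sample = nrm$sample_id[match(tum$patient_id, nrm$patient_id)],
    stringsAsFactors = FALSE
  )
  structure(
    list(tumor_label = tumor_label, counts_genes = counts_genes,
         counts_mirnas = counts_mirnas, sample_meta = sample_meta,
         pairs = pairs),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study '%s': %d genes, %d miRNAs, %d sample pairs\n",
    x$tumor_label, nrow(x$counts_genes), nrow(x$counts_mirnas),
    nrow(x$pairs)))
  invisible(x)
}

tumor_samples <- function(study) study$pairs$tumor_sample
normal_samples <- function(study) study$pairs$normal_sample

#' Counts per million
#'
#' Library-size normalization: each entry divided by its column (library)
#' sum, times 1e6.
#'
#' @param counts Non-negative count matrix (molecules x samples).
#' @return Numeric matrix of the same shape.
#' @export
cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size: cannot compute CPM")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Low-expression filter
#'
#' A molecule is detected when its CPM exceeds 1 in at least half of all
#' samples (tumor and normal together): the threshold is
#' `ceiling(n_samples / 2)`, e.g. 19 qualifying samples out of 38.
#'
#' @param study An `expression_study`.
#' @param min_cpm CPM cutoff (default 1).
#' @return A list with logical vectors `genes` and `mirnas`, named by
#'   molecule id.
#' @export
filter_low_expression <- function(study, min_cpm = 1) {
  stopifnot(inherits(study, "expression_study"))
  mask_of <- function(counts) {
    n <- ncol(counts)
    thresh <- ceiling(n / 2)
    rowSums(cpm(counts) > min_cpm) >= thresh
  }
  list(genes = mask_of(study$counts_genes),
       mirnas = mask_of(study$counts_mirnas))
}

# Exact two-sided NB test of tumor vs normal group totals, conditional on
# the overall total, for one molecule. Counts are pre-scaled to a common
# library size so totals are comparable. phi is the NB dispersion
# (var = mu + phi * mu^2); phi = 0 falls back to the Poisson/binomial
# conditional.
nb_exact_test <- function(y_tumor, y_normal, n_tumor, n_normal, phi) {
  t_total <- y_tumor + y_normal
  if (t_total == 0) return(1)
  prop <- n_tumor / (n_tumor + n_normal)
  if (phi <= 0) {
    f <- function(y) stats::dbinom(y, t_total, prop)
    lo <- stats::qbinom(1e-13, t_total, prop)
    hi <- stats::qbinom(1 - 1e-13, t_total, prop)
  } else {
    mu <- t_total / (n_tumor + n_normal)
    size_a <- n_tumor / phi
    size_b <- n_normal / phi
    f <- function(y) {
      stats::dnbinom(y, size = size_a, mu = n_tumor * mu) *
        stats::dnbinom(t_total - y, size = size_b, mu = n_normal * mu)
    }
    lo <- stats::qnbinom(1e-13, size = size_a, mu = n_tumor * mu)
    hi <- stats::qnbinom(1 - 1e-13, size = size_a, mu = n_tumor * mu)
  }
  lo <- max(0, min(lo, y_tumor))
  hi <- min(t_total, max(hi, y_tumor))
  ys <- lo:hi
  dens <- f(ys)
  total_mass <- sum(dens)
  obs <- f(y_tumor)
  p <- sum(dens[dens <= obs * (1 + 1e-8)]) / total_mass
  min(1, p)
}

# Method-of-moments NB dispersion for one assay on library-scaled counts.
# Per-molecule raw estimates are shrunk toward the median (common) value
# with a prior weight of `prior_df` residual degrees of freedom; negative
# estimates are clamped to 0 (Poisson limit).
mom_dispersion <- function(scaled, group, prior_df = 10) {
  groups <- unique(group)
  num <- 0; den <- 0
  phi_num <- rep(0, nrow(scaled)); phi_den <- rep(0, nrow(scaled))
  for (g in groups) {
    m <- scaled[, group == g, drop = FALSE]
    n_g <- ncol(m)
    if (n_g < 2) next
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    ok <- mu > 0
    phi_raw <- rep(NA_real_, nrow(scaled))
    phi_raw[ok] <- (v[ok] - mu[ok]) / mu[ok]^2
    w <- n_g - 1
    phi_num <- phi_num + ifelse(ok, w * phi_raw, 0)
    phi_den <- phi_den + ifelse(ok, w, 0)
  }
  phi_mol <- ifelse(phi_den > 0, phi_num / phi_den, NA_real_)
  common <- stats::median(phi_mol[is.finite(phi_mol)], na.rm = TRUE)
  if (!is.finite(common)) common <- 0
  common <- max(common, 0)
  shrunk <- (prior_df * common + phi_den * ifelse(is.finite(phi_mol),
                                                 phi_mol, 0)) /
    (prior_df + phi_den)
  n_clamped <- sum(shrunk < 0, na.rm = TRUE)
  shrunk <- pmax(shrunk, 0)
  shrunk[!is.finite(shrunk)] <- common
  attr(shrunk, "common") <- common
  attr(shrunk, "n_clamped") <- n_clamped
  shrunk
}

de_one_assay <- function(counts, study, detected, type, prior_df = 10) {
  tum <- tumor_samples(study); nrm <- normal_samples(study)
  group <- ifelse(colnames(counts) %in% tum, "tumor", "normal")
  n_t <- length(tum); n_n <- length(nrm)

  cpm_mat <- cpm(counts)
  mean_cpm_t <- rowMeans(cpm_mat[, tum, drop = FALSE])
  mean_cpm_n <- rowMeans(cpm_mat[, nrm, drop = FALSE])
  log2fc <- log2((mean_cpm_t + 0.5) / (mean_cpm_n + 0.5))

  # scale all libraries to their geometric mean so group totals compare
  lib <- colSums(counts)
  ref <- exp(mean(log(lib)))
  scaled <- sweep(counts, 2, ref / lib, "*")

  phi <- mom_dispersion(scaled[detected, , drop = FALSE], group,
                        prior_df = prior_df)
  y_t <- round(rowSums(scaled[detected, group == "tumor", drop = FALSE]))
  y_n <- round(rowSums(scaled[detected, group == "normal", drop = FALSE]))

  pvals <- vapply(seq_along(y_t), function(i) {
    nb_exact_test(y_t[i], y_n[i], n_t, n_n, phi[i])
  }, numeric(1))

  res <- data.frame(
    molecule_id = rownames(counts),
    type = type,
    detected = detected,
    mean_cpm = rowMeans(cpm_mat),
    log2fc = ifelse(detected, log2fc, NA_real_),
    pvalue = NA_real_,
    fdr = NA_real_,
    dispersion = NA_real_,
    stringsAsFactors = FALSE
  )
  res$pvalue[detected] <- pvals
  res$fdr[detected] <- stats::p.adjust(pvals, method = "BH")
  res$dispersion[detected] <- as.numeric(phi)
  rownames(res) <- NULL
  attr(res, "common_dispersion") <- attr(phi, "common")
  attr(res, "n_dispersion_clamped") <- attr(phi, "n_clamped")
  res
}

#' Differential expression, tumor vs normal
#'
#' The built-in method (`"exact-nb"`) is a two-group exact negative-binomial
#' test: libraries are scaled to their geometric-mean size, per-molecule
#' dispersions are estimated by method of moments and shrunk toward the
#' common (median) value, and the two-sided P-value is the exact probability
#' mass of group totals at most as likely as the observed split, conditional
#' on the overall total. `log2fc` is
#' `log2((mean tumor CPM + 0.5) / (mean normal CPM + 0.5))`; FDR is
#' Benjamini-Hochberg across detected molecules, computed separately for
#' genes and miRNAs (separate assays). Alternatively an external
#' differential-expression table (any engine) can be supplied.
#'
#' @param study An `expression_study`.
#' @param method `"exact-nb"` (built-in) or `"external"`.
#' @param detected Optional detection masks as from
#'   [filter_low_expression()]; computed if missing.
#' @param external For `method = "external"`: data.frame or TSV path with
#'   columns `molecule_id`, `pvalue`, `log2fc`.
#' @param prior_df Prior weight (residual d.f.) for dispersion shrinkage.
#' @return A data.frame (one row per molecule, genes then miRNAs) with
#'   columns `molecule_id`, `type`, `detected`, `mean_cpm`, `log2fc`,
#'   `pvalue`, `fdr`, `dispersion`. Undetected molecules carry NA test
#'   results.
#' @export
differential_expression <- function(study,
                                    method = c("exact-nb", "external"),
                                    detected = NULL, external = NULL,
                                    prior_df = 10) {
  stopifnot(inherits(study, "expression_study"))
  method <- match.arg(method)
  if (is.null(detected)) detected <- filter_low_expression(study)
  if (method == "exact-nb") {
    if (nrow(study$pairs) < 2) stop("built-in test requires >= 2 sample pairs")
    res <- rbind(
      de_one_assay(study$counts_genes, study, detected$genes, "gene",
                   prior_df),
      de_one_assay(study$counts_mirnas, study, detected$mirnas, "miRNA",
                   prior_df)
    )
  } else {
    if (is.null(external)) stop("method = 'external' requires `external`")
    if (is.character(external)) external <- read_tsv_table(external)
    stopifnot(all(c("molecule_id", "pvalue", "log2fc") %in% names(external)))
    ids <- c(rownames(study$counts_genes), rownames(study$counts_mirnas))
    det <- c(detected$genes, detected$mirnas)
    idx <- match(ids, external$molecule_id)
    missing_ids <- ids[det & is.na(idx)]
    if (length(missing_ids)) {
      warning("external DE table lacks ", length(missing_ids),
              " detected molecule(s): ",
              paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    all_cpm <- rbind(cpm(study$counts_genes), cpm(study$counts_mirnas))
    res <- data.frame(
      molecule_id = ids,
      type = rep(c("gene", "miRNA"),
                 c(nrow(study$counts_genes), nrow(study$counts_mirnas))),
      detected = det,
      mean_cpm = rowMeans(all_cpm),
      log2fc = ifelse(det, external$log2fc[idx], NA_real_),
      pvalue = ifelse(det, external$pvalue[idx], NA_real_),
      fdr = NA_real_,
      dispersion = NA_real_,
      stringsAsFactors = FALSE
    )
    for (tp in c("gene", "miRNA")) {
      sel <- res$type == tp & res$detected & !is.na(res$pvalue)
      res$fdr[sel] <- stats::p.adjust(res$pvalue[sel], method = "BH")
    }
  }
  rownames(res) <- NULL
  res
}

#' Call differential-expression status
#'
#' Labels each tested molecule `up` (FDR below `fdr_cut` and log2
#' fold-change above `lfc_cut`), `down` (FDR below cut and log2FC below
#' `-lfc_cut`) or `neutral`; untested molecules get `NA`.
#'
#' @param de Result of [differential_expression()].
#' @param fdr_cut FDR threshold (default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @return The input data.frame with an added `de_call` column.
#' @export
call_de <- function(de, fdr_cut = 0.05, lfc_cut = 1) {
  lab <- rep(NA_character_, nrow(de))
  tested <- !is.na(de$fdr) & !is.na(de$log2fc)
  lab[tested] <- "neutral"
  lab[tested & de$fdr < fdr_cut & de$log2fc > lfc_cut] <- "up"
  lab[tested & de$fdr < fdr_cut & de$log2fc < -lfc_cut] <- "down"
  de$de_call <- lab
  de
}
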