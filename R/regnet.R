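#' Build a typed regulatory network from a table of regulations
#'
#' Constructs the background TF--miRNA regulatory network used for
#' feed-forward-loop (FFL) enumeration. Self-loops are removed first, then
#' duplicate (source, target) pairs are collapsed; node role sets (TF,
#' miRNA, gene) are derived from the type tokens of the edges a node
#' participates in, so a molecule may hold several roles (e.g. a TF that is
#' also another loop's target gene).
#'
#' @param edges A data.frame with columns `source_id`, `source_type`,
#'   `target_id`, `target_type` and optionally `evidence`. Types must be
#'   `"TF"` or `"miRNA"` for sources and `"TF"`, `"miRNA"` or `"gene"` for
#'   targets.
#' @return An object of class `ffl_network`: a list with `edges` (the
#'   deduplicated edge table), `nodes` (id plus logical role columns
#'   `is_tf`, `is_mirna`, `is_gene`) and `n_removed_self_loops`.
#' @export
regulatory_network <- function(edges) {
  required <- c("source_id", "source_type", "target_id", "target_type")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"evidence" %in% names(edges)) {
    edges[["evidence"]] <- rep(NA_character_, nrow(edges))
  }
  edges <- edges[, c(required, "evidence")]
  edges$evidence <- as.character(edges$evidence)
  edges$source_id <- as.character(edges$source_id)
  edges$target_id <- as.character(edges$target_id)
  edges$source_type <- normalize_type(edges$source_type, "source")
  edges$target_type <- normalize_type(edges$target_type, "target")

  bad <- which(is.na(edges$source_id) | is.na(edges$target_id) |
                 edges$source_id == "" | edges$target_id == "")
  if (length(bad)) {
    stop("malformed regulation row(s) at line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }

  self <- edges$source_id == edges$target_id
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]

  key <- paste(edges$source_id, edges$target_id, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL

  ids <- unique(c(edges$source_id, edges$target_id))
  nodes <- data.frame(
    id = ids,
    is_tf = ids %in% c(edges$source_id[edges$source_type == "TF"],
                       edges$target_id[edges$target_type == "TF"]),
    is_mirna = ids %in% c(edges$source_id[edges$source_type == "miRNA"],
                          edges$target_id[edges$target_type == "miRNA"]),
    is_gene = ids %in% edges$target_id[edges$target_type == "gene"],
    stringsAsFactors = FALSE
  )

  structure(
    list(edges = edges, nodes = nodes, n_removed_self_loops = n_self),
    class = "ffl_network"
  )
}

normalize_type <- function(x, position) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[tolower(x) == "tf"] <- "TF"
  out[tolower(x) %in% c("mirna", "mir", "microrna")] <- "miRNA"
  out[tolower(x) == "gene"] <- "gene"
  if (anyNA(out)) {
    stop("unknown molecule type token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  allowed <- if (position == "source") c("TF", "miRNA") else
    c("TF", "miRNA", "gene")
  if (any(!out %in% allowed)) {
    stop("type '", setdiff(out, allowed)[1], "' is not a valid ", position,
         " type")
  }
  out
}

#' Load a curated regulation table
#'
#' Reads a tab-separated regulation table (columns `source_id`,
#' `source_type`, `target_id`, `target_type`, `evidence`; `#` lines are
#' comments) and builds the background network via [regulatory_network()].
#'
#' @param path Path to a TSV file.
#' @param verbose Print a summary line with node and edge counts.
#' @return An `ffl_network`.
#' @export
load_regulations <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("regulation table not found: ", path)
  tab <- read_tsv_table(path)
  net <- regulatory_network(tab)
  if (verbose) {
    s <- network_summary(net)
    message(sprintf(
      "loaded %d regulations among %d TFs, %d miRNAs, %d target genes (%d self-loops removed)",
      s$n_regulations, s$n_tf, s$n_mirna, s$n_gene, net$n_removed_self_loops))
  }
  net
}

#' Summarize a regulatory network
#'
#' @param net An `ffl_network`.
#' @return A list with `n_regulations`, `n_tf`, `n_mirna`, `n_gene`
#'   (role counts; roles may overlap) and `n_nodes`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "ffl_network"))
  list(
    n_regulations = nrow(net$edges),
    n_tf = sum(net$nodes$is_tf),
    n_mirna = sum(net$nodes$is_mirna),
    n_gene = sum(net$nodes$is_gene),
    n_nodes = nrow(net$nodes)
  )
}

#' @export
print.ffl_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "ffl_network: %d regulations | %d TFs, %d miRNAs, %d target genes (%d nodes)\n",
    s$n_regulations, s$n_tf, s$n_mirna, s$n_gene, s$n_nodes))
  invisible(x)
}

#' Enumerate and classify three-node feed-forward loops
#'
#' Finds every (TF, miRNA, gene) triple in which the TF and the miRNA both
#' regulate the gene and at least one of them regulates the other.
#' Classification by the TF--miRNA relation is exclusive:
#' \describe{
#'   \item{TF-FFL}{TF regulates the miRNA (and not vice versa).}
#'   \item{miRNA-FFL}{miRNA represses the TF (and not vice versa).}
#'   \item{FB-FFL}{TF and miRNA mutually regulate each other; such a triple
#'     is emitted once, as FB-FFL only.}
#' }
#'
#' @param net An `ffl_network`.
#' @return A data.frame with columns `tf`, `mirna`, `gene`, `ffl_type`,
#'   sorted by (tf, mirna, gene).
#' @export
enumerate_ffls <- function(net) {
  stopifnot(inherits(net, "ffl_network"))
  e <- net$edges
  if (!nrow(e)) {
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_type = character(),
                      stringsAsFactors = FALSE))
  }
  tf2mir <- e[e$source_type == "TF" & e$target_type == "miRNA", ]
  mir2tf <- e[e$source_type == "miRNA" & e$target_type == "TF", ]
  tf2gene <- e[e$source_type == "TF" & e$target_type == "gene", ]
  mir2gene <- e[e$source_type == "miRNA" & e$target_type == "gene", ]

  targets_of <- function(edges_df) {
    split(edges_df$target_id, edges_df$source_id)
  }
  t2g <- targets_of(tf2gene)
  m2g <- targets_of(mir2gene)

  pair_key <- function(tf, mir) paste(tf, mir, sep = "\r")
  fwd <- pair_key(tf2mir$source_id, tf2mir$target_id)
  rev <- pair_key(mir2tf$target_id, mir2tf$source_id)
  pairs <- unique(c(fwd, rev))
  if (!length(pairs)) {
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_type = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  tf_ids <- vapply(parts, `[`, character(1), 1L)
  mir_ids <- vapply(parts, `[`, character(1), 2L)
  has_fwd <- pairs %in% fwd
  has_rev <- pairs %in% rev

  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    tf <- tf_ids[i]; mir <- mir_ids[i]
    shared <- intersect(t2g[[tf]], m2g[[mir]])
    shared <- shared[shared != tf & shared != mir]
    if (!length(shared)) next
    type <- if (has_fwd[i] && has_rev[i]) "FB-FFL" else
      if (has_fwd[i]) "TF-FFL" else "miRNA-FFL"
    out[[i]] <- data.frame(tf = tf, mirna = mir, gene = shared,
                           ffl_type = type, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_type = character(),
                      stringsAsFactors = FALSE))
  }
  res <- res[order(res$tf, res$mirna, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Constituent edges of a set of FFLs
#'
#' Expands each loop into its regulatory edges: a TF-FFL contributes
#' TF->miRNA, TF->gene, miRNA->gene; a miRNA-FFL contributes miRNA->TF,
#' TF->gene, miRNA->gene; a FB-FFL contributes all four (both TF->miRNA
#' and miRNA->TF).
#'
#' @param ffls A data.frame as returned by [enumerate_ffls()].
#' @return An edge data.frame suitable for [regulatory_network()].
#' @export
ffl_edges <- function(ffls) {
  stopifnot(all(c("tf", "mirna", "gene", "ffl_type") %in% names(ffls)))
  rows <- lapply(seq_len(nrow(ffls)), function(i) {
    tf <- ffls$tf[i]; mir <- ffls$mirna[i]; g <- ffls$gene[i]
    type <- ffls$ffl_type[i]
    e <- list(
      c(tf, "TF", g, "gene"),
      c(mir, "miRNA", g, "gene")
    )
    if (type %in% c("TF-FFL", "FB-FFL")) {
      e <- c(e, list(c(tf, "TF", mir, "miRNA")))
    }
    if (type %in% c("miRNA-FFL", "FB-FFL")) {
      e <- c(e, list(c(mir, "miRNA", tf, "TF")))
    }
    do.call(rbind, e)
  })
  m <- do.call(rbind, rows)
  data.frame(source_id = m[, 1], source_type = m[, 2],
             target_id = m[, 3], target_type = m[, 4],
             evidence = "ffl_merge", stringsAsFactors = FALSE)
}

#' Merge FFLs into a (pan-cancer) regulatory network
#'
#' Takes the union of all constituent edges of the given loops,
#' deduplicated, with node roles derived from the positions each molecule
#' holds. Mutual TF--miRNA regulation (FB-FFL) contributes two directed
#' edges, so such a pair adds 2 to each endpoint's degree.
#'
#' @param ffls A data.frame with columns `tf`, `mirna`, `gene`, `ffl_type`.
#' @return An `ffl_network`.
#' @export
merge_ffls <- function(ffls) {
  if (!nrow(ffls)) stop("cannot merge an empty FFL set")
  regulatory_network(ffl_edges(ffls))
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "ffl_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("source_id", "target_id")],
    directed = TRUE,
    vertices = net$nodes$id
  )
}

#' Node-level topology and power-law fits
#'
#' Computes per-node degree, in-degree, out-degree and (directed,
#' unnormalized) betweenness, and fits a power law `y = a * x^b` to each
#' degree distribution by least squares of log10(count) on log10(degree)
#' over non-empty bins of the raw integer degree histogram.
#'
#' @param net An `ffl_network`.
#' @return A list with `nodes` (data.frame: id, degree, in_degree,
#'   out_degree, betweenness) and `fits` (named list for degree/in_degree/
#'   out_degree, each either a list `a`, `b`, `r_squared`, `n_bins` or a
#'   list with a `skipped` reason when fewer than 3 distinct values exist).
#' @export
topology_report <- function(net) {
  stopifnot(inherits(net, "ffl_network"))
  if (!nrow(net$edges)) stop("topology_report requires a non-empty network")
  g <- as_igraph(net)
  deg_all <- igraph::degree(g, mode = "all")
  deg_in <- igraph::degree(g, mode = "in")
  deg_out <- igraph::degree(g, mode = "out")
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  nodes <- data.frame(
    id = igraph::V(g)$name,
    degree = as.numeric(deg_all),
    in_degree = as.numeric(deg_in),
    out_degree = as.numeric(deg_out),
    betweenness = as.numeric(btw),
    stringsAsFactors = FALSE
  )
  fits <- list(
    degree = powerlaw_fit(nodes$degree),
    in_degree = powerlaw_fit(nodes$in_degree),
    out_degree = powerlaw_fit(nodes$out_degree)
  )
  list(nodes = nodes, fits = fits)
}

#' Least-squares power-law fit to a degree histogram
#'
#' Tabulates raw integer values (zeros dropped: they have no log), drops
#' empty bins, and regresses log10(count) on log10(value). Mirrors the
#' functional form `y = a * x^b` commonly reported for biological-network
#' degree distributions.
#'
#' @param values Integer-valued vector (e.g. node degrees).
#' @return A list `a`, `b`, `r_squared`, `n_bins`, or a list holding only a
#'   `skipped` reason when fewer than 3 distinct positive values exist.
#' @export
powerlaw_fit <- function(values) {
  values <- values[values > 0]
  tab <- table(values)
  x <- as.numeric(names(tab))
  y <- as.numeric(tab)
  if (length(x) < 3) {
    return(list(skipped = "fewer than 3 distinct degree values"))
  }
  fit <- stats::lm(log10(y) ~ log10(x))
  list(
    a = 10^unname(stats::coef(fit)[1]),
    b = unname(stats::coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_bins = length(x)
  )
}

#' Regulator/target count histograms
#'
#' For each regulation layer, tabulates how many regulators each target has
#' and how many targets each regulator has: TFs-per-gene and genes-per-TF
#' (from TF->gene edges), miRNAs-per-gene and genes-per-miRNA (miRNA->gene),
#' TFs-per-miRNA and miRNAs-per-TF (TF->miRNA).
#'
#' @param net An `ffl_network`.
#' @return A named list of six histograms (named integer vectors: names are
#'   the count, values how many molecules have that count).
#' @export
degree_frequency_tables <- function(net) {
  stopifnot(inherits(net, "ffl_network"))
  e <- net$edges
  layer <- function(st, tt) e[e$source_type == st & e$target_type == tt, ]
  hist_of <- function(ids) {
    if (!length(ids)) return(integer(0))
    tab <- table(table(ids))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  }
  t2g <- layer("TF", "gene")
  m2g <- layer("miRNA", "gene")
  t2m <- layer("TF", "miRNA")
  list(
    tfs_per_gene = hist_of(t2g$target_id),
    genes_per_tf = hist_of(t2g$source_id),
    mirnas_per_gene = hist_of(m2g$target_id),
    genes_per_mirna = hist_of(m2g$source_id),
    tfs_per_mirna = hist_of(t2m$target_id),
    mirnas_per_tf = hist_of(t2m$source_id)
  )
}

#' Write / read an FFL table
#'
#' @param ffls FFL data.frame (`tf`, `mirna`, `gene`, `ffl_type`).
#' @param path File path for the TSV.
#' @return `read_ffls` returns the FFL data.frame.
#' @export
write_ffls <- function(ffls, path) {
  write_tsv_table(ffls[, c("tf", "mirna", "gene", "ffl_type")], path)
  invisible(path)
}

#' @rdname write_ffls
#' @export
read_ffls <- function(path) {
  tab <- read_tsv_table(path)
  stopifnot(all(c("tf", "mirna", "gene", "ffl_type") %in% names(tab)))
  tab
}
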