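#' Pairwise Pearson correlation matrix of genes
#'
#' Correlates every gene pair across samples. Genes with zero variance have
#' undefined correlations; their entries are set to \code{NA} and their ids
#' recorded in the \code{constant_genes} attribute so downstream steps can
#' exclude them.
#'
#' @param expr Expression matrix (genes x samples); correlations are computed
#'   on the values as given.
#' @return Symmetric correlation matrix with unit diagonal (NA rows/columns
#'   for constant genes) and attribute \code{constant_genes}.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3)
    stop("need at least 3 samples to estimate correlations (got ", ncol(expr), ")")
  sds <- apply(expr, 1, stats::sd)
  constant <- rownames(expr)[sds == 0]
  cm <- suppressWarnings(stats::cor(t(expr), method = "pearson"))
  diag(cm) <- 1
  if (length(constant)) {
    cm[constant, ] <- NA_real_
    cm[, constant] <- NA_real_
  }
  attr(cm, "constant_genes") <- constant
  cm
}

#' Build a co-expression network from a correlation matrix
#'
#' Keeps an undirected edge for every gene pair whose correlation reaches
#' the cutoff; genes without any qualifying edge are excluded from the node
#' set. The threshold applies to the signed correlation (top positively
#' correlated pairs), not its absolute value. Alternatively, quantile mode
#' keeps the top \code{q} fraction of pairs by correlation.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @param cutoff Correlation threshold (default 0.99).
#' @param mode \code{"threshold"} (keep pairs with r >= cutoff) or
#'   \code{"quantile"} (keep the top \code{cutoff} fraction of pairs, e.g.
#'   0.01 for the top 1\%).
#' @return An \code{igraph} undirected graph with edge attribute
#'   \code{weight} (the correlation) and graph attribute \code{cutoff}.
#' @export
build_network <- function(cm, cutoff = 0.99, mode = c("threshold", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(nrow(cm) == ncol(cm))
  ut <- upper.tri(cm)
  vals <- cm[ut]
  thr <- if (mode == "threshold") cutoff
  else stats::quantile(vals, 1 - cutoff, na.rm = TRUE, type = 7, names = FALSE)
  idx <- which(ut & !is.na(cm) & cm >= thr, arr.ind = TRUE)
  edges <- data.frame(from = rownames(cm)[idx[, 1]],
                      to = colnames(cm)[idx[, 2]],
                      weight = cm[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "cutoff", thr)
  g
}

#' Detect gene communities by short random walks
#'
#' Applies the Walktrap algorithm: node distances derived from short
#' random-walk transition probabilities are merged agglomeratively and the
#' partition with maximum modularity is returned. Deterministic for a given
#' network.
#'
#' @param network Graph from [build_network()].
#' @param walk_length Random-walk length (default 4, the algorithm's
#'   customary setting).
#' @return Named integer vector: community membership per gene.
#' @export
walktrap_communities <- function(network, walk_length = 4) {
  if (igraph::vcount(network) == 0) stop("empty network")
  wt <- igraph::cluster_walktrap(network, steps = walk_length,
                                 weights = igraph::E(network)$weight)
  igraph::membership(wt)
}

#' Filter communities into reportable gene clusters
#'
#' Keeps communities with at least \code{min_size} members whose mean
#' pairwise Pearson correlation — computed on the full correlation matrix,
#' not just network edges — exceeds \code{min_corr}.
#'
#' @param partition Membership vector from [walktrap_communities()].
#' @param cm Correlation matrix from [correlation_matrix()].
#' @param min_size Minimum cluster size (default 5).
#' @param min_corr Minimum mean pairwise correlation (default 0.5).
#' @return List of clusters, each a list with \code{id}, \code{genes},
#'   \code{mean_correlation}.
#' @export
filter_clusters <- function(partition, cm, min_size = 5, min_corr = 0.5) {
  out <- list()
  for (k in sort(unique(partition))) {
    genes <- names(partition)[partition == k]
    if (length(genes) < min_size) next
    sub <- cm[genes, genes]
    mc <- mean(sub[upper.tri(sub)], na.rm = TRUE)
    if (!is.na(mc) && mc > min_corr)
      out[[length(out) + 1L]] <- list(id = k, genes = genes, mean_correlation = mc)
  }
  out
}

#' Most correlated partners of a gene
#'
#' Ranks the other genes by correlation with the query and returns up to
#' \code{n} of them above \code{min_corr}, descending — e.g. the "eight most
#' correlated genes above 0.9" view used to interpret a candidate target.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @param gene Query gene id.
#' @param n Maximum number of partners (default 8).
#' @param min_corr Correlation floor (default 0.9).
#' @return Named numeric vector of correlations, sorted descending.
#' @export
top_neighbors <- function(cm, gene, n = 8, min_corr = 0.9) {
  if (!gene %in% rownames(cm)) stop("gene '", gene, "' not in correlation matrix")
  r <- cm[gene, ]
  r <- r[names(r) != gene & !is.na(r) & r > min_corr]
  r <- sort(r, decreasing = TRUE)
  utils::head(r, n)
}

#' Export a network for external visualization
#'
#' GraphML (full attributes) or SIF (Cytoscape-compatible triples).
#'
#' @param network Graph from [build_network()].
#' @param path Output path.
#' @param format \code{"graphml"} or \code{"sif"}.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    writeLines(paste(el[, 1], "co", el[, 2], sep = "\t"), path)
  }
  invisible(path)
}

#' Export cluster membership as TSV
#'
#' @param clusters List from [filter_clusters()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster = cl$id, gene = cl$genes,
               mean_correlation = cl$mean_correlation,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(cluster = integer(), gene = character(),
                       mean_correlation = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
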