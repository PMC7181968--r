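#' The default currency metabolite list
#'
#' Twenty ubiquitous cofactors and small molecules (water, ATP/ADP/AMP, the
#' NAD and FAD redox pairs, phosphate species, CoA, and friends) that connect
#' so many reactions that they blur network topology; reporter analyses drop
#' them before scoring.
#'
#' @return Character vector of 20 metabolite names.
#' @export
currency_metabolites <- function() {
  c("H2O", "CO2", "O2", "H+", "HCO3-", "Na+", "CoA", "Pi", "PPi", "AMP",
    "ADP", "ATP", "NAD+", "NADH", "NADP+", "NADPH", "PAP", "PAPS", "FAD",
    "FADH2")
}

# case-insensitive name normalization: unify the unicode minus homoglyph and
# strip a trailing compartment tag ("[c]" or "_c" for a known compartment)
normalize_met_name <- function(name, compartments = character()) {
  x <- tolower(gsub("−", "-", name))
  x <- sub("\\s*\\[[^]]+\\]$", "", x)
  if (length(compartments)) {
    suffix <- paste0("_(", paste(tolower(unique(compartments)), collapse = "|"), ")$")
    x <- sub(suffix, "", x)
  }
  trimws(x)
}

#' Build the gene-metabolite bipartite graph of a model
#'
#' A gene is adjacent to a metabolite iff some reaction involving the
#' metabolite carries that gene in its GPR. With \code{remove_currency},
#' metabolites whose name matches the currency list (case-insensitive,
#' compartment tags stripped) are dropped before the adjacency is formed.
#'
#' @param model A \code{gem} object.
#' @param remove_currency Drop currency metabolites (default TRUE)?
#' @param currency_list Names to drop; defaults to [currency_metabolites()].
#' @return A \code{gene_met_graph}: list with \code{met_genes} (named list:
#'   metabolite id -> adjacent gene ids), \code{genes}, \code{metabolites},
#'   and \code{currency_removed}.
#' @export
build_graph <- function(model, remove_currency = TRUE,
                        currency_list = currency_metabolites()) {
  validate_gem(model)
  keep <- rep(TRUE, nrow(model$mets))
  if (remove_currency) {
    norm_cur <- normalize_met_name(currency_list)
    norm_names <- normalize_met_name(model$mets$name, model$mets$compartment)
    keep <- !(norm_names %in% norm_cur)
  }
  mets_kept <- model$mets$id[keep]
  met_genes <- stats::setNames(vector("list", length(mets_kept)), mets_kept)
  for (i in seq_len(nrow(model$rxns))) {
    genes <- gpr_genes(model$gprs[[i]])
    if (!length(genes)) next
    for (met in intersect(names(model$stoich[[i]]), mets_kept)) {
      met_genes[[met]] <- union(met_genes[[met]], genes)
    }
  }
  met_genes <- met_genes[vapply(met_genes, length, integer(1)) > 0]
  met_genes <- lapply(met_genes, sort)
  structure(list(met_genes = met_genes,
                 genes = sort(unique(unlist(met_genes))),
                 metabolites = names(met_genes),
                 currency_removed = remove_currency),
            class = "gene_met_graph")
}

#' Convert a differential-expression p-value to a directional z-score
#'
#' The reporter statistic aggregates per-gene evidence as standard-normal
#' quantiles. For the "up" run, a gene changed in the up direction gets the
#' directional p-value \eqn{p/2}, a gene changed the other way \eqn{1 - p/2};
#' the "down" run is symmetric. The directional p is clamped to
#' \eqn{[10^{-15}, 1 - 10^{-15}]} before inversion, and
#' \eqn{z = \Phi^{-1}(1 - p_{dir})}.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param up Logical vector: is the gene changed in the "up" direction of the
#'   declared contrast?
#' @param direction Which run: \code{"up"} or \code{"down"}.
#' @return Numeric z-scores.
#' @export
gene_z <- function(p, up, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  aligned <- if (direction == "up") up else !up
  pdir <- ifelse(aligned, p / 2, 1 - p / 2)
  pdir <- pmin(pmax(pdir, 1e-15), 1 - 1e-15)
  stats::qnorm(1 - pdir)
}

# Monte-Carlo background for size-k neighbor sums: mean and sd of
# sum(z)/sqrt(k) over random gene draws from the scored pool
reporter_background <- function(pool_z, ks, n_background) {
  out <- list()
  for (k in sort(unique(ks))) {
    draws <- matrix(sample(pool_z, n_background * k, replace = TRUE),
                    nrow = k)
    stat <- colSums(draws) / sqrt(k)
    out[[as.character(k)]] <- c(mu = mean(stat), sigma = stats::sd(stat))
  }
  out
}

#' Score reporter metabolites
#'
#' For each metabolite, aggregates the z-scores of its neighbor genes as
#' \eqn{Z_{raw} = \sum z_i / \sqrt{k}} and corrects against a Monte-Carlo
#' background of random size-\eqn{k} gene sets drawn from all scored genes:
#' \eqn{Z_{corr} = (Z_{raw} - \mu_k) / \sigma_k}, with upper-tail normal
#' p-value. The analysis is run twice — once for genes changed in the "up"
#' direction of the contrast, once for "down" — and both rankings returned,
#' each sorted by p ascending.
#'
#' Orientation note: with scores from [simple_de()] (\code{high_vs_low}
#' contrast), "up" means upregulated in the low-survival group, i.e.
#' \code{log2fc < 0}.
#'
#' @param graph A \code{gene_met_graph} from [build_graph()].
#' @param scores Data frame with columns \code{gene}, \code{log2fc},
#'   \code{p}; orientation as in [split_de()].
#' @param orientation Contrast orientation of \code{scores}.
#' @param n_background Monte-Carlo draws per neighbor-count (default 10000).
#' @param seed Integer seed for the background sampling.
#' @return List with elements \code{up} and \code{down}, each a data frame
#'   with columns \code{metabolite}, \code{k}, \code{z_raw}, \code{mu_k},
#'   \code{sigma_k}, \code{z_corr}, \code{p}, sorted by \code{p}.
#' @export
reporter_metabolites <- function(graph, scores,
                                 orientation = c("high_vs_low", "low_vs_high"),
                                 n_background = 10000L, seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(graph, "gene_met_graph"),
            all(c("gene", "log2fc", "p") %in% names(scores)))
  missing <- setdiff(graph$genes, scores$gene)
  if (length(missing))
    warning(length(missing), " graph gene(s) lack scores and are dropped")
  scores <- scores[order(scores$gene), , drop = FALSE]
  fc <- scores$log2fc
  if (orientation == "low_vs_high") fc <- -fc
  up_in_low <- fc < 0

  one_run <- function(direction) {
    z <- stats::setNames(gene_z(scores$p, up_in_low, direction), scores$gene)
    met_genes <- lapply(graph$met_genes, intersect, y = scores$gene)
    met_genes <- met_genes[vapply(met_genes, length, integer(1)) > 0]
    k <- vapply(met_genes, length, integer(1))
    z_raw <- vapply(met_genes, function(g) sum(z[g]) / sqrt(length(g)), numeric(1))
    bg <- reporter_background(unname(z), k, n_background)
    mu <- vapply(as.character(k), function(kk) bg[[kk]]["mu"], numeric(1))
    sigma <- vapply(as.character(k), function(kk) bg[[kk]]["sigma"], numeric(1))
    z_corr <- (z_raw - mu) / sigma
    df <- data.frame(metabolite = names(met_genes), k = unname(k),
                     z_raw = unname(z_raw), mu_k = unname(mu),
                     sigma_k = unname(sigma), z_corr = unname(z_corr),
                     p = stats::pnorm(unname(z_corr), lower.tail = FALSE),
                     stringsAsFactors = FALSE)
    df[order(df$p, df$metabolite), , drop = FALSE]
  }
  set.seed(seed)
  up <- one_run("up")
  down <- one_run("down")
  list(up = up, down = down)
}

# gene-projection adjacency of the bipartite graph: genes sharing a metabolite
gene_projection <- function(graph) {
  adj <- stats::setNames(vector("list", length(graph$genes)), graph$genes)
  for (genes in graph$met_genes) {
    for (g in genes) adj[[g]] <- union(adj[[g]], setdiff(genes, g))
  }
  adj
}

#' Extract a high-scoring connected reporter subnetwork
#'
#' Searches for a connected set of genes (connected through shared
#' metabolites) maximizing the background-corrected aggregate score
#' \eqn{(\sum z - k\mu_1)/(\sigma_1\sqrt{k})}. The search is a greedy seeded
#' expansion from the top-scoring gene — repeatedly adding the neighboring
#' gene that most improves the score, up to \code{size_budget} genes —
#' followed by simulated-annealing refinement (random add/swap/drop moves
#' that preserve connectivity, geometric temperature schedule from 1.0 with
#' factor 0.95, 60 moves per temperature, floor 0.01). Deterministic given
#' the seed. The returned subnetwork contains the member genes plus every
#' metabolite adjacent to them, which supports neighborhood summaries such
#' as a metabolite's gene degree within the subnetwork.
#'
#' @param graph A \code{gene_met_graph} from [build_graph()].
#' @param z Named numeric vector of gene z-scores (one run's direction).
#' @param size_budget Maximum number of member genes.
#' @param seed Integer seed.
#' @return A \code{reporter_subnetwork}: list with \code{genes},
#'   \code{metabolites}, \code{score}, \code{size}, and
#'   \code{met_gene_degree} (named integer).
#' @export
reporter_subnetwork <- function(graph, z, size_budget = 20L, seed = 1L) {
  stopifnot(inherits(graph, "gene_met_graph"))
  genes <- intersect(graph$genes, names(z))
  if (!length(genes)) stop("empty graph: no scored genes")
  z <- z[genes]
  adj <- gene_projection(graph)
  mu <- mean(z); sigma <- stats::sd(z)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  score_of <- function(set) (sum(z[set]) - length(set) * mu) / (sigma * sqrt(length(set)))

  set.seed(seed)
  current <- names(which.max(z))
  # greedy expansion
  repeat {
    if (length(current) >= size_budget) break
    frontier <- setdiff(unique(unlist(adj[current])), current)
    frontier <- intersect(frontier, genes)
    if (!length(frontier)) break
    gains <- vapply(frontier, function(g) score_of(c(current, g)), numeric(1))
    best <- which.max(gains)
    if (gains[best] <= score_of(current)) break
    current <- c(current, frontier[best])
  }
  best_set <- current
  best_score <- score_of(current)

  connected_without <- function(set, drop) {
    rest <- setdiff(set, drop)
    if (length(rest) <= 1) return(TRUE)
    seen <- rest[1]
    repeat {
      nxt <- union(seen, intersect(unique(unlist(adj[seen])), rest))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == length(rest)
  }

  temp <- 1
  while (temp > 0.01) {
    for (step in seq_len(60L)) {
      cur_score <- score_of(current)
      frontier <- intersect(setdiff(unique(unlist(adj[current])), current), genes)
      grow <- length(current) < size_budget && length(frontier) &&
        (length(current) <= 1 || stats::runif(1) < 0.5)
      if (grow) {
        cand <- c(current, sample(frontier, 1))
      } else if (length(current) > 1) {
        drop <- sample(current, 1)
        if (!connected_without(current, drop)) next
        cand <- setdiff(current, drop)
      } else next
      delta <- score_of(cand) - cur_score
      if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
        current <- cand
        if (score_of(current) > best_score) {
          best_score <- score_of(current)
          best_set <- current
        }
      }
    }
    temp <- temp * 0.95
  }

  member_mets <- names(graph$met_genes)[vapply(graph$met_genes,
                                               function(g) any(g %in% best_set),
                                               logical(1))]
  deg <- vapply(graph$met_genes[member_mets],
                function(g) length(intersect(g, best_set)), integer(1))
  structure(list(genes = sort(best_set), metabolites = member_mets,
                 score = best_score, size = length(best_set),
                 met_gene_degree = deg),
            class = "reporter_subnetwork")
}

#' Gene degree of a metabolite within a reporter subnetwork
#'
#' The number of member genes directly connected to the metabolite — the
#' count behind summaries like "this metabolite is directly connected to 28
#' genes in the network".
#'
#' @param subnetwork A \code{reporter_subnetwork}.
#' @param metabolite Metabolite id present in the subnetwork.
#' @return Integer count.
#' @export
metabolite_gene_degree <- function(subnetwork, metabolite) {
  stopifnot(inherits(subnetwork, "reporter_subnetwork"))
  if (!metabolite %in% subnetwork$metabolites)
    stop("metabolite '", metabolite, "' not in subnetwork")
  unname(subnetwork$met_gene_degree[metabolite])
}

#' Write reporter scores to TSV
#'
#' @param result List from [reporter_metabolites()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reporter_scores <- function(result, path) {
  up <- cbind(result$up, direction = "up")
  down <- cbind(result$down, direction = "down")
  utils::write.table(rbind(up, down), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
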