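#' Hamming distance between two models
#'
#' The number of reactions present in exactly one of the two models — the
#' symmetric difference of their reaction-id sets. Used to compare
#' patient-derived models that share a reaction namespace.
#'
#' @param m1,m2 \code{gem} objects.
#' @return Nonnegative integer count.
#' @export
hamming_distance <- function(m1, m2) {
  r1 <- model_reactions(m1); r2 <- model_reactions(m2)
  length(setdiff(r1, r2)) + length(setdiff(r2, r1))
}

#' Pairwise Hamming distance matrix of a model ensemble
#'
#' @param models List of \code{gem} objects with distinct ids.
#' @return Symmetric integer matrix with model ids as dimnames.
#' @export
distance_matrix <- function(models) {
  stopifnot(length(models) >= 1)
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate model ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rsets <- lapply(models, model_reactions)
  n <- length(models)
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- length(setdiff(rsets[[i]], rsets[[j]])) +
        length(setdiff(rsets[[j]], rsets[[i]]))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Split an ensemble at the top of the dendrogram
#'
#' Agglomerative hierarchical clustering of the distance matrix, cut into two
#' groups at the top split. Ties are resolved by the deterministic
#' agglomeration order of \code{stats::hclust}, so repeated calls on the same
#' matrix give the same partition.
#'
#' @param D Symmetric distance matrix (from [distance_matrix()]).
#' @param linkage Linkage criterion: \code{"complete"} (default),
#'   \code{"average"}, or \code{"single"}.
#' @return List with \code{labels} (named integer vector, values 1/2, cluster
#'   1 = the cluster containing the first model), \code{clusters} (list of
#'   two id vectors), and \code{tree} (the \code{hclust} object).
#' @export
top_split_clusters <- function(D, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(nrow(D) >= 2, identical(rownames(D), colnames(D)))
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  cut <- stats::cutree(hc, k = 2)
  # canonical numbering: cluster 1 holds the first model
  if (cut[1] != 1L) cut <- 3L - cut
  list(labels = cut,
       clusters = list(rownames(D)[cut == 1L], rownames(D)[cut == 2L]),
       tree = hc)
}

#' Merge an ensemble into a generic model
#'
#' Union of metabolites, reactions and genes across members. A reaction
#' present in several members must have identical stoichiometry everywhere;
#' its merged bounds are the widest interval across members and its merged
#' GPR is the OR over the distinct member rules (a reaction is available if
#' any member context supports it). If member objectives disagree, the most
#' frequent objective id wins with a warning and the others remain ordinary
#' reactions. The merge is order-invariant: components are sorted
#' canonically.
#'
#' @param models List of \code{gem} objects.
#' @return A merged \code{gem}.
#' @export
merge_models <- function(models) {
  stopifnot(length(models) >= 1)
  if (length(models) == 1) return(models[[1]])

  met_tab <- unique(do.call(rbind, lapply(models, `[[`, "mets")))
  if (anyDuplicated(met_tab$id))
    stop("merge conflict: metabolite id(s) with differing annotation: ",
         paste(unique(met_tab$id[duplicated(met_tab$id)]), collapse = ", "))
  met_tab <- met_tab[order(met_tab$id), , drop = FALSE]

  all_rids <- sort(unique(unlist(lapply(models, model_reactions))))
  lb <- stats::setNames(rep(Inf, length(all_rids)), all_rids)
  ub <- stats::setNames(rep(-Inf, length(all_rids)), all_rids)
  stoich <- list()
  gpr_sets <- stats::setNames(vector("list", length(all_rids)), all_rids)
  for (m in models) {
    for (i in seq_len(nrow(m$rxns))) {
      rid <- m$rxns$id[i]
      s <- m$stoich[[rid]]
      s <- s[order(names(s))]
      if (is.null(stoich[[rid]])) stoich[[rid]] <- s
      else if (!isTRUE(all.equal(stoich[[rid]], s)))
        stop("merge conflict: reaction '", rid,
             "' has differing stoichiometry across models")
      lb[rid] <- min(lb[rid], m$rxns$lb[i])
      ub[rid] <- max(ub[rid], m$rxns$ub[i])
      norm <- deparse_gpr(m$gprs[[i]])
      gpr_sets[[rid]] <- union(gpr_sets[[rid]], if (nzchar(norm)) norm else character())
    }
  }
  gpr <- vapply(all_rids, function(rid) {
    rules <- sort(gpr_sets[[rid]])
    if (!length(rules)) return("")
    if (length(rules) == 1) return(rules)
    paste(paste0("(", rules, ")"), collapse = " or ")
  }, character(1))

  objs <- vapply(models, `[[`, character(1), "objective")
  tab <- sort(table(objs), decreasing = TRUE)
  objective <- names(tab)[1]
  if (length(tab) > 1)
    warning("member objectives disagree; keeping the most frequent ('",
            objective, "')")

  out <- gem(id = "merged",
             metabolites = met_tab,
             reactions = data.frame(id = all_rids, lb = unname(lb[all_rids]),
                                    ub = unname(ub[all_rids]), gpr = unname(gpr),
                                    stringsAsFactors = FALSE),
             stoichiometry = stoich[all_rids],
             objective = objective)
  pw <- attr(models[[1]], "pathways")
  if (!is.null(pw)) attr(out, "pathways") <- pw
  out
}

#' Write a distance matrix to TSV
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(data.frame(model = rownames(D), D, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare mean survival between two model clusters
#'
#' Joins cluster labels to a clinical table and runs a two-sample t-test of
#' days survived.
#'
#' @param labels Named cluster labels from [top_split_clusters()]; names must
#'   match \code{clinical$sample_id}.
#' @param clinical Clinical table with \code{sample_id} and \code{days}.
#' @return List with per-cluster means and the \code{htest} object.
#' @export
cluster_survival_test <- function(labels, clinical) {
  days <- clinical$days[match(names(labels), clinical$sample_id)]
  if (anyNA(days)) stop("cluster labels name samples absent from the clinical table")
  g1 <- days[labels == 1L]; g2 <- days[labels == 2L]
  tt <- stats::t.test(g1, g2)
  list(mean_cluster1 = mean(g1), mean_cluster2 = mean(g2), test = tt)
}
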