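#' Stratify a cohort into low and high survival groups
#'
#' Keeps only patients with vital status "dead", computes the low and high
#' quantiles of days survived (linear-interpolation quantiles, the common
#' type-7 rule), and forms the low group from patients strictly below the low
#' cut and the high group from patients strictly above the high cut. The
#' middle tertile is discarded. With the defaults this is the lowest-33% /
#' highest-33% survival split.
#'
#' @param clinical Data frame with columns \code{sample_id},
#'   \code{vital_status} (\code{"dead"}/\code{"alive"}), \code{days}.
#' @param low_q,high_q Quantile cut points (defaults 1/3 and 2/3).
#' @return List with \code{low}, \code{high} (sample-id vectors),
#'   \code{cut_low}, \code{cut_high} (in days), and \code{n_dead}.
#' @export
stratify_survival <- function(clinical, low_q = 1/3, high_q = 2/3) {
  stopifnot(all(c("sample_id", "vital_status", "days") %in% names(clinical)))
  dead <- clinical[clinical$vital_status == "dead", , drop = FALSE]
  if (nrow(dead) == 0) stop("empty cohort: no samples with vital status 'dead'")
  if (anyNA(dead$days)) stop("missing days for dead sample(s)")
  if (nrow(dead) < 3)
    stop("need at least 3 dead samples to stratify (got ", nrow(dead), ")")
  cuts <- stats::quantile(dead$days, c(low_q, high_q), type = 7, names = FALSE)
  if (cuts[1] >= cuts[2])
    stop("degenerate survival distribution: cut points coincide (",
         cuts[1], ", ", cuts[2], ")")
  list(low = dead$sample_id[dead$days < cuts[1]],
       high = dead$sample_id[dead$days > cuts[2]],
       cut_low = cuts[1], cut_high = cuts[2], n_dead = nrow(dead))
}

#' Split differential-expression results into up/down gene sets
#'
#' Thresholds on p-value and separates significant genes by fold-change
#' sign. With the default \code{"high_vs_low"} orientation (the contrast
#' compares the high-survival group against the low-survival group), genes
#' upregulated in the low-survival group have negative log2 fold change, so
#' \code{up_in_low} collects significant genes with \code{log2fc < 0} and
#' \code{down_in_low} those with \code{log2fc > 0}. The opposite orientation
#' flips the signs. Genes with log2fc exactly 0 join neither set.
#'
#' @param table Data frame with columns \code{gene}, \code{log2fc}, \code{p}.
#' @param alpha Significance threshold on \code{p} (default 0.05).
#' @param orientation \code{"high_vs_low"} or \code{"low_vs_high"}; must be
#'   stated explicitly when the table comes from an external tool.
#' @return List with \code{up_in_low} and \code{down_in_low} gene-id vectors.
#' @export
split_de <- function(table, alpha = 0.05,
                     orientation = c("high_vs_low", "low_vs_high")) {
  if (missing(orientation) && !is.null(attr(table, "orientation")))
    orientation <- attr(table, "orientation")
  orientation <- match.arg(orientation)
  stopifnot(all(c("gene", "log2fc", "p") %in% names(table)))
  if (any(table$p <= 0 | table$p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  sig <- !is.na(table$p) & table$p < alpha
  fc <- table$log2fc
  if (orientation == "low_vs_high") fc <- -fc
  list(up_in_low = table$gene[sig & fc < 0],
       down_in_low = table$gene[sig & fc > 0])
}

#' Two-group differential expression (Welch t-test)
#'
#' A deliberately simple stand-in for a full count-model DE analysis, meant
#' for synthetic runs: per-gene Welch t-test on log2 expression with
#' \code{log2fc = mean(high) - mean(low)} (the \code{"high_vs_low"}
#' orientation). When users supply an externally computed DE table the
#' pipeline consumes it as-is and never recomputes it. Genes with zero
#' variance in both groups and equal means get p = 1 by convention.
#'
#' @param expr Expression matrix (genes x samples, linear scale).
#' @param low,high Sample-id vectors (columns of \code{expr}).
#' @return Data frame with columns \code{gene}, \code{log2fc}, \code{p};
#'   attribute \code{orientation = "high_vs_low"}.
#' @export
simple_de <- function(expr, low, high) {
  stopifnot(length(low) > 0, length(high) > 0)
  missing <- setdiff(c(low, high), colnames(expr))
  if (length(missing))
    stop("sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  lx <- log2(expr[, low, drop = FALSE])
  hx <- log2(expr[, high, drop = FALSE])
  n1 <- length(low); n2 <- length(high)
  m1 <- rowMeans(lx); m2 <- rowMeans(hx)
  v1 <- apply(lx, 1, stats::var); v2 <- apply(hx, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(m1 == m2, 1, .Machine$double.xmin))
  out <- data.frame(gene = rownames(expr), log2fc = unname(m2 - m1),
                    p = unname(pmin(pmax(p, .Machine$double.xmin), 1)),
                    stringsAsFactors = FALSE)
  attr(out, "orientation") <- "high_vs_low"
  out
}

#' Validate candidate targets against gene dependency scores
#'
#' For each target gene, reports its median dependency score across cell
#' lines and a two-sided one-sample t-test of its per-cell-line scores
#' against the mean of all genes' median scores (the cohort-wide reference
#' level). Strongly negative medians indicate essentiality in the screened
#' cell lines.
#'
#' @param mat Dependency score matrix (genes x cell lines).
#' @param targets Gene ids to test.
#' @return Data frame with columns \code{gene}, \code{median_score},
#'   \code{t}, \code{p}; attribute \code{reference_mean} (mean of all
#'   genes' medians) and \code{skipped} (targets absent from the matrix).
#' @export
dependency_validation <- function(mat, targets) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  skipped <- setdiff(targets, rownames(mat))
  if (length(skipped))
    warning("target(s) absent from dependency matrix: ",
            paste(skipped, collapse = ", "))
  targets <- intersect(targets, rownames(mat))
  med_all <- apply(mat, 1, stats::median)
  mu0 <- mean(med_all)
  rows <- lapply(targets, function(g) {
    x <- mat[g, ]
    if (stats::sd(x) == 0) {
      tt <- list(statistic = if (mean(x) == mu0) 0 else sign(mean(x) - mu0) * Inf,
                 p.value = if (mean(x) == mu0) 1 else 0)
    } else {
      tt <- stats::t.test(x, mu = mu0)
    }
    data.frame(gene = g, median_score = stats::median(x),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(), median_score = numeric(),
                  t = numeric(), p = numeric(), stringsAsFactors = FALSE)
  attr(out, "reference_mean") <- mu0
  attr(out, "skipped") <- skipped
  out
}

#' Export a gene list as plain text
#'
#' One gene id per line, the format external enrichment tools ingest.
#'
#' @param genes Character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
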