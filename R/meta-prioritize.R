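# Gene prioritization across cohorts: per-gene concordance z-scores,
# Stouffer meta-z combination, Benjamini-Hochberg selection.

#' Per-gene concordance z-scores, one column per cohort
#'
#' For each gene and cohort, the gene's percentile-rank values are used as
#' a risk score and tested with [cindex_ztest()]. Positive z means higher
#' expression associates with shorter survival. Genes constant within a
#' cohort get z = 0 there (with a warning); a perfectly separating gene in
#' a tiny cohort can yield an infinite z, which survives Stouffer
#' combination and simply ranks first.
#'
#' @param collection `cohort_collection` in percentile-rank space.
#' @return numeric genes x cohorts matrix of z-scores.
#' @export
per_gene_z <- function(collection) {
  stopifnot(inherits(collection, "cohort_collection"))
  genes <- collection$gene_universe
  K <- length(collection$cohorts)
  z <- matrix(NA_real_, length(genes), K,
              dimnames = list(genes, names(collection$cohorts)))
  n_const <- 0L
  for (k in seq_len(K)) {
    co <- collection$cohorts[[k]]
    pairs <- comparable_pairs(co$clinical$time, co$clinical$event)
    if (pairs$m == 0L)
      stop("cohort '", co$name, "' has no comparable pairs", call. = FALSE)
    X <- co$expression
    for (g in seq_along(genes)) {
      x <- X[g, ]
      if (all(x == x[1L])) {
        z[g, k] <- 0
        n_const <- n_const + 1L
      } else {
        z[g, k] <- cindex_ztest(x, pairs = pairs)$z
      }
    }
  }
  if (n_const > 0L)
    warning(n_const, " constant gene/cohort combination(s) set to z = 0",
            call. = FALSE)
  z
}

#' Stouffer combination of per-cohort z-scores
#'
#' meta_z(g) = sum_k z(g, k) / sqrt(K) by default (the standard unweighted
#' Stouffer statistic); `denominator = "K"` divides by K instead, a pure
#' rescaling that changes meta-p values (and hence how many genes pass the
#' BH cut) but not the gene ranking.
#'
#' @param z_matrix genes x cohorts matrix of z-scores, no missing entries.
#' @param denominator `"sqrtK"` (default) or `"K"`.
#' @return named numeric vector of meta-z scores.
#' @export
stouffer_combine <- function(z_matrix, denominator = c("sqrtK", "K")) {
  denominator <- match.arg(denominator)
  z_matrix <- as.matrix(z_matrix)
  if (anyNA(z_matrix)) stop("z matrix contains missing values", call. = FALSE)
  K <- ncol(z_matrix)
  if (K < 1L) stop("need at least one cohort", call. = FALSE)
  den <- if (denominator == "sqrtK") sqrt(K) else K
  rowSums(z_matrix) / den
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Build the gene priority table
#'
#' Combines [per_gene_z()], [stouffer_combine()] and [bh_adjust()] into one
#' table: per-cohort z, meta-z, two-sided meta-p from |meta-z| (set
#' `one_sided = TRUE` for the upper-tail reading), BH-adjusted p, rank by
#' |meta-z| (ties broken lexicographically by gene id) and the selection
#' flag `adj_p < alpha`.
#'
#' @param collection `cohort_collection` in percentile-rank space.
#' @param alpha BH significance threshold (default 0.05).
#' @param denominator Stouffer denominator, see [stouffer_combine()].
#' @param one_sided use the literal upper-tail meta-p instead of two-sided.
#' @return data.frame of class `gene_priority_table`, one row per gene,
#'   ordered by rank.
#' @export
gene_priority_table <- function(collection, alpha = 0.05,
                                denominator = "sqrtK", one_sided = FALSE) {
  z <- per_gene_z(collection)
  meta_z <- stouffer_combine(z, denominator)
  meta_p <- if (one_sided) pnorm(meta_z, lower.tail = FALSE)
            else 2 * pnorm(-abs(meta_z))
  adj_p <- bh_adjust(meta_p)
  ord <- order(-abs(meta_z), rownames(z))
  rk <- integer(length(meta_z)); rk[ord] <- seq_along(ord)
  tab <- data.frame(gene = rownames(z),
                    z,
                    meta_z = meta_z,
                    meta_p = meta_p,
                    adj_p = adj_p,
                    rank = rk,
                    selected = adj_p < alpha,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[1L + seq_len(ncol(z))] <- paste0("z_", colnames(z))
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- alpha
  attr(tab, "denominator") <- denominator
  attr(tab, "one_sided") <- one_sided
  class(tab) <- c("gene_priority_table", "data.frame")
  tab
}

#' Select the top genes from a priority table
#'
#' d is the number of genes whose BH-adjusted p falls below `alpha`; the
#' returned genes are the d largest by |meta-z| (under the two-sided
#' convention the two sets coincide). When nothing passes, an error points
#' at the `min_genes` fallback, which — when set above zero — returns the
#' top `min_genes` genes by |meta-z| regardless of significance.
#'
#' @param table `gene_priority_table`.
#' @param alpha significance threshold (defaults to the one used to build
#'   the table).
#' @param min_genes fallback floor when no gene is significant; 0 = off.
#' @return character vector of selected gene ids, in rank order.
#' @export
select_genes <- function(table, alpha = NULL, min_genes = 0L) {
  stopifnot(inherits(table, "gene_priority_table"))
  if (is.null(alpha)) alpha <- attr(table, "alpha")
  tab <- table[order(table$rank), , drop = FALSE]
  d <- sum(tab$adj_p < alpha)
  if (d == 0L) {
    if (min_genes > 0L) {
      warning("no gene passed BH at alpha = ", alpha, "; falling back to ",
              "the top ", min_genes, " by |meta-z|", call. = FALSE)
      d <- min(min_genes, nrow(tab))
    } else {
      stop("no gene passed BH at alpha = ", alpha,
           "; raise alpha or set min_genes > 0", call. = FALSE)
    }
  }
  tab$gene[seq_len(d)]
}

#' Write a gene priority table to TSV
#'
#' @param table `gene_priority_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_priority_table <- function(table, path) {
  stopifnot(inherits(table, "gene_priority_table"))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
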