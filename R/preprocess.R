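# Probeset collapsing, common-gene intersection and the intra-sample
# normalized percentile-rank transform.

#' Read a probeset-to-gene map
#'
#' Two-column delimited text (`probeset_id`, `gene_id`), many probesets per
#' gene allowed, but each probeset must map to exactly one gene.
#'
#' @param path path to a two-column TSV/CSV.
#' @return named character vector: `map[probeset_id] == gene_id`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("probe map needs two columns", call. = FALSE)
  probes <- as.character(df[[1L]])
  genes <- as.character(df[[2L]])
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("probeset(s) mapped to more than one gene: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  setNames(genes, probes)
}

#' Collapse probesets to genes by largest mean expression
#'
#' When several probesets interrogate the same gene, the probeset with the
#' largest mean expression across samples is retained to represent the gene
#' (the highest signal-to-noise candidate). Ties are broken toward the
#' lexicographically smallest probeset id. Probesets absent from the map are
#' dropped (a message reports the count).
#'
#' @param expression numeric probesets x samples matrix.
#' @param probe_map named character vector from [read_probe_map()].
#' @return numeric genes x samples matrix.
#' @export
collapse_probesets <- function(expression, probe_map) {
  validate_expression_matrix(expression)
  mapped <- intersect(rownames(expression), names(probe_map))
  if (!length(mapped))
    stop("no probeset maps to any gene", call. = FALSE)
  n_drop <- nrow(expression) - length(mapped)
  if (n_drop > 0)
    message("collapse_probesets: dropped ", n_drop, " unmapped probeset(s)")
  expr <- expression[mapped, , drop = FALSE]
  genes <- probe_map[mapped]
  means <- rowMeans(expr)
  # lexicographic probeset order first, then stable max-by-mean per gene
  ord <- order(genes, -means, mapped)
  keep <- ord[!duplicated(genes[ord])]
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Restrict cohorts to their common genes
#'
#' Keeps only the genes present in every cohort, sorted lexicographically,
#' and reorders each cohort's expression rows to that shared universe.
#'
#' @param cohorts list of `cohort` objects (or a `cohort_collection`).
#' @return `cohort_collection` over the common gene universe.
#' @export
intersect_genes <- function(cohorts) {
  if (inherits(cohorts, "cohort_collection")) cohorts <- cohorts$cohorts
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  if (!length(cohorts)) stop("no cohorts supplied", call. = FALSE)
  universe <- rownames(cohorts[[1L]]$expression)
  for (co in cohorts[-1L])
    universe <- intersect(universe, rownames(co$expression))
  if (!length(universe))
    stop("no genes are common to all cohorts", call. = FALSE)
  universe <- sort(universe)
  cohorts <- lapply(cohorts, function(co) {
    co$expression <- co$expression[universe, , drop = FALSE]
    co
  })
  cohort_collection(cohorts)
}

#' Normalized percentile-rank transform
#'
#' Within each sample, genes are ranked ascending by expression (midranks
#' for ties) and ranks are divided by the gene count p, giving features in
#' (0, 1]. Because only within-sample ranks enter, the output is invariant
#' to any strictly increasing per-sample distortion of the raw values —
#' this is what makes the features platform-agnostic.
#'
#' @param x genes x samples matrix, a `cohort`, or a `cohort_collection`.
#' @param ... unused.
#' @return object of the same shape with values replaced by rank / p.
#' @export
percentile_rank_transform <- function(x, ...) UseMethod("percentile_rank_transform")

#' @export
percentile_rank_transform.default <- function(x, ...) {
  validate_expression_matrix(x)
  p <- nrow(x)
  out <- apply(x, 2L, rank, ties.method = "average") / p
  if (p == 1L) out <- matrix(out, nrow = 1L, dimnames = dimnames(x))
  out
}

#' @export
percentile_rank_transform.cohort <- function(x, ...) {
  x$expression <- percentile_rank_transform(x$expression)
  x
}

#' @export
percentile_rank_transform.cohort_collection <- function(x, ...) {
  x$cohorts <- lapply(x$cohorts, percentile_rank_transform)
  x
}
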