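# Data model: expression matrices, clinical tables, cohorts, collections,
# trained signatures, and their on-disk formats.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix, features in rows and
#' samples in columns, with unique non-empty dimnames and no missing values.
#'
#' @param x numeric matrix to validate.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop(what, " is empty", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have feature rownames and sample colnames", call. = FALSE)
  dup_f <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_f))
    stop(what, ": duplicated feature id(s): ",
         paste(unique(dup_f), collapse = ", "), call. = FALSE)
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop(what, ": duplicated sample id(s): ",
         paste(unique(dup_s), collapse = ", "), call. = FALSE)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(what, ": missing value at feature '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (probesets or gene symbols). TSV/CSV is auto-detected from the file
#' extension. All cells must parse as numbers; missing or non-numeric cells
#' and duplicated ids are load-time errors naming the offender.
#'
#' @param path path to a `.tsv`/`.txt` or `.csv` file.
#' @param transpose if `TRUE`, the file is samples x features and is
#'   transposed after reading.
#' @return numeric matrix, features x samples.
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("empty expression matrix in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric cell at feature '", ids[bad[1L]], "', sample '",
             names(vals)[j], "' in ", path, call. = FALSE)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  validate_expression_matrix(m, paste0("expression matrix (", path, ")"))
  m
}

#' Write an expression matrix to delimited text
#'
#' @param x numeric features x samples matrix with dimnames.
#' @param path output path; `.csv` selects comma, anything else tab.
#' @param id_column header of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_column = "feature_id") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' The file must contain columns `sample_id`, `time` and `event`
#' (header required, extra columns ignored). `time` must be strictly
#' positive; `event` is 1 when the event was observed and 0 under right
#' censoring.
#'
#' @param path path to a `.tsv`/`.txt` or `.csv` file.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time),
                    event = as.numeric(df$event),
                    stringsAsFactors = FALSE)
  validate_clinical_table(out, paste0("clinical table (", path, ")"))
  out
}

#' Validate a clinical table
#'
#' @param df data.frame with `sample_id`, `time`, `event`.
#' @param what label for error messages.
#' @return `df`, invisibly.
#' @export
validate_clinical_table <- function(df, what = "clinical table") {
  if (!all(c("sample_id", "time", "event") %in% colnames(df)))
    stop(what, " must have columns sample_id, time, event", call. = FALSE)
  if (anyNA(df$time) || anyNA(df$event) || anyNA(df$sample_id))
    stop(what, " contains missing values", call. = FALSE)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop(what, ": duplicated sample id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(df$time <= 0))
    stop(what, ": time must be > 0 (offending sample: ",
         df$sample_id[which(df$time <= 0)[1L]], ")", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop(what, ": event must be 0 or 1 (offending sample: ",
         df$sample_id[which(!df$event %in% c(0, 1))[1L]], ")", call. = FALSE)
  invisible(df)
}

#' Write a clinical table
#'
#' @param df data.frame with `sample_id`, `time`, `event`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(df, path) {
  validate_clinical_table(df)
  write.table(df[, c("sample_id", "time", "event")], path,
              sep = .delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort from expression and clinical data
#'
#' Inner-joins the two inputs on sample id: expression columns are reordered
#' to the clinical order and samples present in only one input are dropped
#' (a message reports the count). A valid cohort has at least two samples
#' and at least one observed event.
#'
#' @param expression numeric features x samples matrix.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @param name cohort name.
#' @return object of class `cohort`: a list with `name`, `expression`,
#'   `clinical` (samples in identical order in both).
#' @export
assemble_cohort <- function(expression, clinical, name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  validate_expression_matrix(expression)
  validate_clinical_table(clinical)
  common <- intersect(clinical$sample_id, colnames(expression))
  if (!length(common))
    stop("cohort '", name,
         "': no samples shared between expression and clinical data",
         call. = FALSE)
  dropped <- (ncol(expression) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0)
    message("cohort '", name, "': dropped ", dropped,
            " sample record(s) absent from one input")
  clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  expr <- expression[, common, drop = FALSE]
  if (sum(clin$event) < 1)
    stop("cohort '", name, "': no observed events after joining",
         call. = FALSE)
  if (length(common) < 2L)
    stop("cohort '", name, "': fewer than 2 samples after joining",
         call. = FALSE)
  structure(list(name = name, expression = expr, clinical = clin),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d features x %d samples, %d events\n",
              x$name, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event)))
  invisible(x)
}

#' Bundle cohorts that share a gene universe
#'
#' All cohorts must carry exactly the same feature ids in the same order
#' (use [intersect_genes()] to get there) and unique names.
#'
#' @param cohorts list of `cohort` objects.
#' @return object of class `cohort_collection`: list with `cohorts` and
#'   `gene_universe`.
#' @export
cohort_collection <- function(cohorts) {
  if (!length(cohorts)) stop("empty cohort list", call. = FALSE)
  if (!all(vapply(cohorts, inherits, logical(1L), "cohort")))
    stop("all elements must be cohort objects", call. = FALSE)
  nm <- vapply(cohorts, `[[`, character(1L), "name")
  if (anyDuplicated(nm))
    stop("cohort names must be unique", call. = FALSE)
  genes <- rownames(cohorts[[1L]]$expression)
  for (co in cohorts[-1L])
    if (!identical(rownames(co$expression), genes))
      stop("cohort '", co$name,
           "' does not share the collection's gene universe ",
           "(run intersect_genes first)", call. = FALSE)
  names(cohorts) <- nm
  structure(list(cohorts = cohorts, gene_universe = genes),
            class = "cohort_collection")
}

#' @export
print.cohort_collection <- function(x, ...) {
  cat(sprintf("<cohort_collection> %d cohorts, %d common genes\n",
              length(x$cohorts), length(x$gene_universe)))
  for (co in x$cohorts)
    cat(sprintf("  %-12s %4d samples, %4d events\n", co$name,
                ncol(co$expression), sum(co$clinical$event)))
  invisible(x)
}

#' Construct a trained signature object
#'
#' @param gene_ids character vector of gene ids.
#' @param coefficients numeric vector `w` aligned to `gene_ids`; positive
#'   entries favour long survival in the internal linear score (the reported
#'   risk score is its negation, see [risk_score()]).
#' @param lambda nonnegative ridge penalty strength used in training.
#' @param provenance named list recording training settings (cohort names,
#'   alpha, optimizer settings, seed, ...).
#' @param feature_space feature convention tag; only `"percentile_rank"`
#'   is produced by this package.
#' @return object of class `trained_signature`.
#' @export
trained_signature <- function(gene_ids, coefficients, lambda,
                              provenance = list(),
                              feature_space = "percentile_rank") {
  gene_ids <- as.character(gene_ids)
  coefficients <- as.numeric(coefficients)
  if (length(gene_ids) != length(coefficients))
    stop("gene_ids and coefficients differ in length", call. = FALSE)
  if (!length(gene_ids))
    stop("signature must contain at least one gene", call. = FALSE)
  lambda <- as.numeric(lambda)
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be a single nonnegative number", call. = FALSE)
  structure(list(gene_ids = gene_ids,
                 coefficients = setNames(coefficients, gene_ids),
                 lambda = lambda,
                 feature_space = feature_space,
                 provenance = provenance),
            class = "trained_signature")
}

#' @export
print.trained_signature <- function(x, ...) {
  cat(sprintf("<trained_signature> %d genes, lambda = %g\n",
              length(x$gene_ids), x$lambda))
  k <- min(5L, length(x$gene_ids))
  ord <- order(-abs(x$coefficients))[seq_len(k)]
  for (i in ord)
    cat(sprintf("  %-12s % .4f\n", x$gene_ids[i], x$coefficients[i]))
  if (length(x$gene_ids) > k) cat("  ...\n")
  invisible(x)
}

.SIGNATURE_FORMAT <- "discordsig-signature"
.SIGNATURE_VERSION <- 1L

#' Write a trained signature to JSON
#'
#' The file is a small human-diffable JSON document holding the gene list,
#' coefficients at full precision, lambda, the feature-space tag and the
#' provenance record. [read_signature()] is its exact inverse.
#'
#' @param sig `trained_signature` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  if (!inherits(sig, "trained_signature"))
    stop("sig must be a trained_signature", call. = FALSE)
  if (length(sig$gene_ids) != length(sig$coefficients))
    stop("refusing to serialize: gene/coefficient length mismatch",
         call. = FALSE)
  doc <- list(format = .SIGNATURE_FORMAT,
              version = .SIGNATURE_VERSION,
              feature_space = sig$feature_space,
              genes = sig$gene_ids,
              coefficients = unname(sig$coefficients),
              lambda = sig$lambda,
              provenance = sig$provenance)
  # 17 significant digits: exact binary64 round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a trained signature from JSON
#'
#' @param path path written by [write_signature()].
#' @return `trained_signature` object.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, .SIGNATURE_FORMAT))
    stop("not a signature file: ", path, call. = FALSE)
  if (!identical(as.integer(doc$version), .SIGNATURE_VERSION))
    stop("unsupported signature version ", doc$version, " in ", path,
         call. = FALSE)
  for (f in c("genes", "coefficients", "lambda"))
    if (is.null(doc[[f]]))
      stop("signature file ", path, " missing field '", f, "'",
           call. = FALSE)
  prov <- doc$provenance
  if (is.null(prov)) prov <- list()
  trained_signature(doc$genes, doc$coefficients, doc$lambda,
                    provenance = prov,
                    feature_space = doc$feature_space)
}
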