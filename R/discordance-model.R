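# The core method: hinge-approximated survival-discordance loss per cohort,
# fast O(m + nd) subgradient, ridge-penalized joint minimization, and
# leave-one-dataset-out penalty selection.
#
# Sign convention: the hinge max(0, 1 + w'x_i - w'x_j) for a comparable
# pair (j, i) — j surviving strictly longer than the failing i — pushes
# w'x_j above w'x_i by a margin of 1, so w'x is a *survival* (protective)
# score. The reported risk score is its negation (see risk_score()).

#' Hinge discordance loss and subgradient for one cohort
#'
#' Computes the hinge-approximated discordance loss
#' L(w) = sum over comparable pairs (j, i) of max(0, 1 + w'x_i - w'x_j)
#' and its subgradient in O(m + nd): with b = X'w, every violating pair
#' (b_j - b_i < 1) contributes 1 + b_i - b_j to L and increments a
#' per-sample tally u (u_i + 1, u_j - 1); the subgradient is then X u.
#'
#' @param X numeric features x samples matrix (columns aligned with the
#'   samples indexed by `pairs`).
#' @param w coefficient vector, length `nrow(X)`.
#' @param pairs [comparable_pairs()] for this cohort's outcomes.
#' @return list with `loss`, `gradient` (length `nrow(X)`), `pair_count`,
#'   and `n_active` (violating pairs).
#' @export
hinge_loss_subgradient <- function(X, w, pairs) {
  if (!inherits(pairs, "comparable_pairs"))
    stop("pairs must come from comparable_pairs()", call. = FALSE)
  if (!is.matrix(X) || ncol(X) != pairs$n)
    stop("X must be a features x samples matrix with ", pairs$n,
         " columns", call. = FALSE)
  w <- as.numeric(w)
  if (length(w) != nrow(X))
    stop("w must have one coefficient per feature row", call. = FALSE)
  n <- ncol(X)
  if (pairs$m == 0L)
    return(list(loss = 0, gradient = numeric(nrow(X)), pair_count = 0L,
                n_active = 0L))
  b <- as.numeric(crossprod(X, w))
  delta <- b[pairs$j] - b[pairs$i]
  act <- delta < 1
  loss <- sum(1 - delta[act])
  u <- tabulate(pairs$i[act], nbins = n) - tabulate(pairs$j[act], nbins = n)
  list(loss = loss,
       gradient = as.numeric(X %*% u),
       pair_count = pairs$m,
       n_active = sum(act))
}

#' Assemble a training problem from a collection
#'
#' Precomputes, per cohort, the feature matrix restricted to the model
#' genes and the comparable-pair list, so repeated loss evaluations during
#' optimization touch no survival logic.
#'
#' @param collection `cohort_collection` in percentile-rank space.
#' @param genes character vector of model genes (subset of the universe).
#' @return object of class `discordance_problem`.
#' @export
discordance_problem <- function(collection, genes = NULL) {
  stopifnot(inherits(collection, "cohort_collection"))
  if (is.null(genes)) genes <- collection$gene_universe
  missing <- setdiff(genes, collection$gene_universe)
  if (length(missing))
    stop("gene(s) absent from the collection: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cohorts <- collection$cohorts
  X <- lapply(cohorts, function(co) co$expression[genes, , drop = FALSE])
  pairs <- lapply(cohorts, function(co)
    comparable_pairs(co$clinical$time, co$clinical$event))
  m_per <- vapply(pairs, `[[`, integer(1L), "m")
  if (any(m_per == 0L))
    warning("cohort(s) without comparable pairs contribute zero loss: ",
            paste(names(cohorts)[m_per == 0L], collapse = ", "),
            call. = FALSE)
  structure(list(genes = genes, X = X, pairs = pairs,
                 cohort_names = names(cohorts), m_per_cohort = m_per),
            class = "discordance_problem")
}

#' @export
print.discordance_problem <- function(x, ...) {
  cat(sprintf("<discordance_problem> %d genes, %d cohorts, m = %s\n",
              length(x$genes), length(x$X),
              paste(x$m_per_cohort, collapse = " + ")))
  invisible(x)
}

#' Ridge-penalized joint loss across cohorts
#'
#' loss(w) = sum_k L_k(w) + lambda ||w||^2, with L_k the hinge discordance
#' loss of cohort k computed only within that cohort — no pair ever crosses
#' cohorts, which is what makes the training decentralized and indifferent
#' to per-cohort survival-time scales.
#'
#' @param problem `discordance_problem`.
#' @param w coefficient vector.
#' @param lambda nonnegative ridge strength.
#' @return list with `loss`, `gradient`, `pair_count`, `loss_per_cohort`.
#' @export
joint_loss <- function(problem, w, lambda = 0) {
  stopifnot(inherits(problem, "discordance_problem"), lambda >= 0)
  w <- as.numeric(w)
  loss_k <- numeric(length(problem$X))
  g <- numeric(length(w))
  for (k in seq_along(problem$X)) {
    hk <- hinge_loss_subgradient(problem$X[[k]], w, problem$pairs[[k]])
    loss_k[k] <- hk$loss
    g <- g + hk$gradient
  }
  list(loss = sum(loss_k) + lambda * sum(w^2),
       gradient = g + 2 * lambda * w,
       pair_count = sum(problem$m_per_cohort),
       loss_per_cohort = setNames(loss_k, problem$cohort_names))
}

#' Optimizer settings for the discordance fit
#'
#' @param tol projected-gradient tolerance passed to the L-BFGS-B solver.
#' @param max_iter iteration cap.
#' @param init optional warm-start coefficients (default all zero — the
#'   deterministic reference start).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(tol = 1e-6, max_iter = 1000L, init = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), init = init),
            class = "fit_config")
}

#' Fit coefficients by minimizing the penalized joint loss
#'
#' Limited-memory quasi-Newton (L-BFGS-B) on the convex, piecewise-linear-
#' plus-quadratic objective, using the fast subgradient; at the (measure
#' zero) hinge kinks the subgradient is a valid supporting slope. Zero
#' initialization and a fixed solver make the fit deterministic.
#'
#' @param problem `discordance_problem`.
#' @param lambda nonnegative ridge strength.
#' @param config `fit_config`.
#' @return list of class `discordance_fit`: `w` (named), `lambda`, `loss`
#'   (penalized), `converged`, `iterations`, `message`.
#' @export
fit_discordance <- function(problem, lambda, config = fit_config()) {
  stopifnot(inherits(problem, "discordance_problem"),
            inherits(config, "fit_config"), lambda >= 0)
  d <- length(problem$genes)
  w0 <- if (is.null(config$init)) numeric(d) else as.numeric(config$init)
  if (length(w0) != d) stop("init has wrong length", call. = FALSE)
  fn <- function(w) joint_loss(problem, w, lambda)$loss
  gr <- function(w) joint_loss(problem, w, lambda)$gradient
  opt <- optim(w0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = config$max_iter,
                              pgtol = config$tol, factr = 1e3))
  structure(list(w = setNames(opt$par, problem$genes),
                 lambda = lambda,
                 loss = opt$value,
                 converged = opt$convergence == 0L,
                 iterations = opt$counts[["function"]],
                 message = if (is.null(opt$message)) "" else opt$message),
            class = "discordance_fit")
}

#' @export
print.discordance_fit <- function(x, ...) {
  cat(sprintf("<discordance_fit> %d coefficients, lambda = %g, loss = %.4f%s\n",
              length(x$w), x$lambda, x$loss,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Default penalty grid
#'
#' 13 logarithmically spaced values from 1e-4 to 1e2.
#'
#' @return numeric vector of penalty strengths.
#' @export
default_lambda_grid <- function() 10^seq(-4, 2, length.out = 13L)

#' Leave-one-dataset-out selection of the ridge penalty
#'
#' For every lambda and every cohort: fit on the other K - 1 cohorts and
#' evaluate the unpenalized hinge loss on the held-out cohort. Losses are
#' cumulated across folds and the lambda with the smallest cumulated loss
#' wins (ties go to the larger, more regularized lambda). Raw cumulation
#' over-weights large cohorts; `normalize = TRUE` divides each fold's loss
#' by its pair count instead.
#'
#' @param collection `cohort_collection` in percentile-rank space with at
#'   least two cohorts.
#' @param genes model genes.
#' @param lambda_grid positive penalty grid.
#' @param config `fit_config`.
#' @param normalize divide each held-out loss by the fold's pair count.
#' @return object of class `cv_report`: `lambda_grid`, `heldout_loss`
#'   (lambda x fold matrix), `cumulated_loss`, `best_lambda`.
#' @export
lodo_select_lambda <- function(collection, genes = NULL,
                               lambda_grid = default_lambda_grid(),
                               config = fit_config(), normalize = FALSE) {
  stopifnot(inherits(collection, "cohort_collection"))
  K <- length(collection$cohorts)
  if (K < 2L)
    stop("leave-one-dataset-out needs at least 2 cohorts; ",
         "with a single cohort pass lambda explicitly", call. = FALSE)
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive", call. = FALSE)
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  if (is.null(genes)) genes <- collection$gene_universe
  full <- discordance_problem(collection, genes)
  held <- matrix(NA_real_, length(lambda_grid), K,
                 dimnames = list(format(lambda_grid, digits = 6),
                                 full$cohort_names))
  for (k in seq_len(K)) {
    sub <- structure(list(genes = genes,
                          X = full$X[-k], pairs = full$pairs[-k],
                          cohort_names = full$cohort_names[-k],
                          m_per_cohort = full$m_per_cohort[-k]),
                     class = "discordance_problem")
    hold_X <- full$X[[k]]
    hold_pairs <- full$pairs[[k]]
    for (l in seq_along(lambda_grid)) {
      f <- fit_discordance(sub, lambda_grid[l], config)
      hl <- hinge_loss_subgradient(hold_X, f$w, hold_pairs)$loss
      held[l, k] <- if (normalize) hl / max(1L, hold_pairs$m) else hl
    }
  }
  cum <- rowSums(held)
  best_idx <- max(which(cum == min(cum)))    # tie -> larger lambda
  structure(list(lambda_grid = lambda_grid, heldout_loss = held,
                 cumulated_loss = cum, best_lambda = lambda_grid[best_idx],
                 normalized = normalize),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d lambdas x %d folds, best lambda = %g\n",
              length(x$lambda_grid), ncol(x$heldout_loss), x$best_lambda))
  invisible(x)
}

#' Write a cross-validation report to TSV
#'
#' @param report `cv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  df <- data.frame(lambda = report$lambda_grid,
                   report$heldout_loss,
                   cumulated_loss = report$cumulated_loss,
                   selected = report$lambda_grid == report$best_lambda,
                   check.names = FALSE)
  colnames(df)[1L + seq_len(ncol(report$heldout_loss))] <-
    paste0("heldout_", colnames(report$heldout_loss))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Train a signature end to end
#'
#' The full pipeline on gene-level cohorts: common-gene intersection,
#' percentile-rank transform, meta-z prioritization with a BH cut at
#' `alpha`, leave-one-dataset-out lambda selection (skipped when `lambda`
#' is given or only one cohort is supplied), and a final fit on all
#' cohorts. The returned signature carries the priority table and CV
#' report as attributes (`priority_table`, `cv_report`) plus a provenance
#' record.
#'
#' @param cohorts list of gene-level `cohort` objects (or a
#'   `cohort_collection`).
#' @param alpha BH threshold for gene selection.
#' @param lambda_grid penalty grid for leave-one-dataset-out selection.
#' @param lambda fixed penalty; bypasses cross-validation when non-`NULL`
#'   (required for a single cohort).
#' @param config `fit_config`.
#' @param denominator Stouffer denominator, see [stouffer_combine()].
#' @param min_genes selection floor, see [select_genes()].
#' @param normalize_cv normalize held-out losses by pair count.
#' @return `trained_signature`.
#' @export
train_signature <- function(cohorts, alpha = 0.05,
                            lambda_grid = default_lambda_grid(),
                            lambda = NULL, config = fit_config(),
                            denominator = "sqrtK", min_genes = 0L,
                            normalize_cv = FALSE) {
  collection <- intersect_genes(cohorts)
  if (is.null(lambda) && length(collection$cohorts) < 2L)
    stop("single-cohort training requires an explicit lambda ",
         "(leave-one-dataset-out needs K >= 2)", call. = FALSE)
  ranked <- percentile_rank_transform(collection)
  priority <- gene_priority_table(ranked, alpha = alpha,
                                  denominator = denominator)
  genes <- select_genes(priority, alpha = alpha, min_genes = min_genes)
  cv <- NULL
  if (is.null(lambda)) {
    cv <- lodo_select_lambda(ranked, genes, lambda_grid, config,
                             normalize = normalize_cv)
    lambda <- cv$best_lambda
  }
  problem <- discordance_problem(ranked, genes)
  f <- fit_discordance(problem, lambda, config)
  prov <- list(cohorts = names(ranked$cohorts),
               n_per_cohort = vapply(ranked$cohorts,
                                     function(co) ncol(co$expression),
                                     integer(1L)),
               genes_after_intersection = length(ranked$gene_universe),
               rank_denominator = length(ranked$gene_universe),
               alpha = alpha,
               stouffer_denominator = denominator,
               d_selected = length(genes),
               lambda_grid = if (is.null(cv)) NULL else cv$lambda_grid,
               optimizer = list(method = "L-BFGS-B", tol = config$tol,
                                max_iter = config$max_iter, init = "zero"),
               converged = f$converged,
               final_loss = f$loss,
               package_version = as.character(utils::packageVersion("discordsig")))
  sig <- trained_signature(genes, f$w, lambda, provenance = prov)
  attr(sig, "priority_table") <- priority
  attr(sig, "cv_report") <- cv
  sig
}

#' Risk scores for a cohort under a trained signature
#'
#' The cohort's expression is percentile-rank transformed over its own
#' gene set (same convention as training), restricted to the signature
#' genes, and scored as risk = -w'x per sample: the training objective
#' drives w'x upward for long survivors, so its negation is the risk.
#' Missing signature genes are an error — no imputation.
#'
#' @param sig `trained_signature`.
#' @param cohort gene-level `cohort` (raw expression; ranks are computed
#'   here).
#' @return named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(sig, cohort) {
  stopifnot(inherits(sig, "trained_signature"), inherits(cohort, "cohort"))
  missing <- setdiff(sig$gene_ids, rownames(cohort$expression))
  if (length(missing))
    stop("cohort '", cohort$name, "' lacks signature gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ranked <- percentile_rank_transform(cohort$expression)
  X <- ranked[sig$gene_ids, , drop = FALSE]
  setNames(-as.numeric(crossprod(X, unname(sig$coefficients))),
           colnames(X))
}

#' Evaluate a signature on cohorts
#'
#' Scores each cohort with [risk_score()] and reports Harrell's c-index
#' (with z-test) and a univariable Cox regression of survival on the
#' continuous risk score.
#'
#' @param sig `trained_signature`.
#' @param cohorts list of gene-level `cohort` objects (or one cohort, or a
#'   `cohort_collection`).
#' @return data.frame, one row per cohort: `cohort`, `n`, `events`,
#'   `cindex`, `se`, `z`, `p`, `cox_beta`, `cox_se`, `cox_z`, `cox_p`.
#' @export
evaluate_signature <- function(sig, cohorts) {
  if (inherits(cohorts, "cohort_collection")) cohorts <- cohorts$cohorts
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  rows <- lapply(cohorts, function(co) {
    r <- risk_score(sig, co)
    cc <- cindex_ztest(r, co$clinical$time, co$clinical$event)
    cx <- univariable_cox(r, co$clinical$time, co$clinical$event)
    data.frame(cohort = co$name, n = ncol(co$expression),
               events = sum(co$clinical$event),
               cindex = cc$c, se = cc$se, z = cc$z, p = cc$p,
               cox_beta = cx$beta, cox_se = cx$se, cox_z = cx$z,
               cox_p = cx$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge cohorts into one naive pooled cohort
#'
#' Concatenates all samples into a single cohort whose pairwise loss then
#' compares patients *across* studies — survival times measured on
#' incomparable per-study scales enter the same comparable-pair list. This
#' is the baseline the decentralized loss is designed to avoid; it exists
#' for contrast experiments only.
#'
#' @param collection `cohort_collection`.
#' @param name name for the merged cohort.
#' @return single `cohort` with all samples.
#' @export
merge_collection <- function(collection, name = "merged") {
  stopifnot(inherits(collection, "cohort_collection"))
  expr <- do.call(cbind, lapply(collection$cohorts, function(co) {
    m <- co$expression
    colnames(m) <- paste(co$name, colnames(m), sep = ".")
    m
  }))
  clin <- do.call(rbind, lapply(collection$cohorts, function(co) {
    cl <- co$clinical
    cl$sample_id <- paste(co$name, cl$sample_id, sep = ".")
    cl
  }))
  rownames(clin) <- NULL
  assemble_cohort(expr, clin, name)
}
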