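# Synthetic multi-cohort survival data with known ground truth, emulating
# the heterogeneity the method targets: cohort-specific baseline hazards on
# deliberately incomparable time scales, strictly monotone platform
# distortions of expression, and independent right censoring.

.DISTORTIONS <- list(
  identity = function(x) x,
  # log-flavoured compression, strictly increasing on all of R
  log = function(x) asinh(x),
  power = function(x) x^3,
  affine = function(x) 37.2 + 4.5 * x
)

#' Simulation configuration
#'
#' @param K cohort count.
#' @param n_per_cohort sample count per cohort (recycled to length K).
#' @param p gene count.
#' @param n_prognostic number of truly prognostic genes.
#' @param effect_size absolute value of each nonzero true coefficient; the
#'   default 0.35 puts the oracle within-cohort c-index near 0.8.
#' @param baseline_hazard per-cohort exponential baseline hazard (recycled);
#'   the default spans 10x, so survival times are on incomparable scales
#'   across cohorts.
#' @param censoring_target expected censored fraction in [0, 1).
#' @param distortion per-cohort platform distortion tag, one of
#'   `"identity"`, `"log"`, `"power"`, `"affine"` (recycled); all are
#'   strictly increasing, hence rank-preserving within each sample.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(K = 4L, n_per_cohort = 150L, p = 200L,
                       n_prognostic = 20L, effect_size = 0.35,
                       baseline_hazard = c(0.05, 0.1, 0.2, 0.5),
                       censoring_target = 0.3,
                       distortion = c("identity", "log", "power", "affine"),
                       seed = 20170077L) {
  K <- as.integer(K)
  stopifnot(K >= 1L, p >= 1L, n_prognostic >= 1L, n_prognostic <= p,
            effect_size > 0, censoring_target >= 0, censoring_target < 1,
            all(baseline_hazard > 0),
            all(distortion %in% names(.DISTORTIONS)))
  structure(list(K = K,
                 n_per_cohort = rep_len(as.integer(n_per_cohort), K),
                 p = as.integer(p),
                 n_prognostic = as.integer(n_prognostic),
                 effect_size = effect_size,
                 baseline_hazard = rep_len(baseline_hazard, K),
                 censoring_target = censoring_target,
                 distortion = rep_len(distortion, K),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' The reference simulation scenario
#'
#' Four cohorts of 150 samples over 200 common genes, 20 prognostic genes,
#' 30% censoring, baseline hazards spanning 10x and a distinct monotone
#' platform distortion per cohort.
#'
#' @return `sim_config`.
#' @export
default_sim_config <- function() sim_config()

# Censoring rate c solving mean_i c / (c + rate_i) = target for
# exponential event times with rates rate_i and independent Exp(c) censoring.
.censoring_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(lc) mean(exp(lc) / (exp(lc) + rates)) - target
  lo <- log(min(rates)) - 20; hi <- log(max(rates)) + 20
  exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Simulate a multi-cohort collection with known truth
#'
#' Latent expression is independent standard normal per gene and sample.
#' Survival follows a proportional-hazards exponential model with rate
#' h_k * exp(eta_i), eta_i = w_true' z_i; censoring is an independent
#' exponential clock whose rate is solved numerically for the target
#' censored fraction. Observed expression applies the cohort's strictly
#' monotone distortion to the latent values, so within-sample ranks — and
#' therefore the percentile-rank features — are untouched.
#'
#' @param config `sim_config`.
#' @param truth optional `ground_truth` from an earlier run: its true
#'   coefficient vector is reused instead of drawing a new one, so fresh
#'   held-out cohorts live in the same world as the training collection
#'   (`config$p` must match).
#' @param name_prefix cohort name prefix (change it when generating
#'   held-out cohorts alongside a training collection).
#' @return list with `collection` (a `cohort_collection`) and `truth`
#'   (class `ground_truth`: `true_coefficients` over all p genes,
#'   `prognostic_gene_ids`, per-cohort `linear_predictor` lists).
#' @export
simulate_collection <- function(config = default_sim_config(), truth = NULL,
                                name_prefix = "cohort") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$p))
  if (is.null(truth)) {
    prog <- sort(sample(config$p, config$n_prognostic))
    w_true <- setNames(numeric(config$p), genes)
    w_true[prog] <- config$effect_size *
      sample(c(-1, 1), config$n_prognostic, replace = TRUE)
  } else {
    stopifnot(inherits(truth, "ground_truth"),
              length(truth$true_coefficients) == config$p)
    w_true <- truth$true_coefficients
    names(w_true) <- genes
    prog <- which(w_true != 0)
  }
  cohorts <- vector("list", config$K)
  lps <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    n <- config$n_per_cohort[k]
    name <- sprintf("%s%02d", name_prefix, k)
    Z <- matrix(rnorm(config$p * n), config$p, n,
                dimnames = list(genes, sprintf("%s_s%03d", name, seq_len(n))))
    eta <- as.numeric(crossprod(Z, w_true))
    rate <- config$baseline_hazard[k] * exp(eta)
    t_event <- rexp(n, rate)
    crate <- .censoring_rate(rate, config$censoring_target)
    if (crate > 0) {
      t_cens <- rexp(n, crate)
      time <- pmin(t_event, t_cens)
      event <- as.numeric(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1, n)
    }
    obs <- .DISTORTIONS[[config$distortion[k]]](Z)
    dimnames(obs) <- dimnames(Z)
    clin <- data.frame(sample_id = colnames(Z), time = time, event = event,
                       stringsAsFactors = FALSE)
    cohorts[[k]] <- assemble_cohort(obs, clin, name)
    lps[[k]] <- setNames(eta, colnames(Z))
  }
  truth <- structure(list(true_coefficients = w_true,
                          prognostic_gene_ids = genes[prog],
                          linear_predictor = setNames(
                            lps, vapply(cohorts, `[[`, character(1L), "name")),
                          config = config),
                     class = "ground_truth")
  list(collection = cohort_collection(cohorts), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d prognostic of %d genes, |effect| = %g\n",
              length(x$prognostic_gene_ids),
              length(x$true_coefficients), x$config$effect_size))
  invisible(x)
}

#' Write a simulated collection to disk
#'
#' One expression TSV and one clinical TSV per cohort, plus a JSON ground
#' truth file, in the package's standard on-disk formats — so the CLI
#' pipeline can be exercised end to end from files.
#'
#' @param sim result of [simulate_collection()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (co in sim$collection$cohorts) {
    pe <- file.path(dir, paste0("expr_", co$name, ".tsv"))
    pc <- file.path(dir, paste0("clin_", co$name, ".tsv"))
    write_expression_matrix(co$expression, pe, id_column = "gene_id")
    write_clinical_table(co$clinical, pc)
    paths[[co$name]] <- c(expression = pe, clinical = pc)
  }
  tr <- sim$truth
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(prognostic_gene_ids = tr$prognostic_gene_ids,
         true_coefficients = as.list(
           tr$true_coefficients[tr$prognostic_gene_ids]),
         effect_size = tr$config$effect_size,
         seed = tr$config$seed),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$ground_truth <- truth_path
  invisible(paths)
}
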