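# Fixture builders and independent oracles, all generated in code.

# A tiny gene-level cohort with deterministic but non-trivial structure.
make_cohort <- function(name = "toy", n = 12L, p = 8L, seed = 1L,
                        effect = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(p))
  samples <- sprintf("%s_s%02d", name, seq_len(n))
  X <- matrix(rnorm(p * n), p, n, dimnames = list(genes, samples))
  eta <- effect * X[1L, ] - effect * X[2L, ]     # g01 risk, g02 protective
  tm <- rexp(n, 0.1 * exp(eta))
  cs <- rexp(n, 0.05)
  clin <- data.frame(sample_id = samples, time = pmin(tm, cs),
                     event = as.numeric(tm <= cs),
                     stringsAsFactors = FALSE)
  if (sum(clin$event) == 0) clin$event[1L] <- 1
  assemble_cohort(X, clin, name)
}

make_collection <- function(K = 3L, n = 20L, p = 8L, seed = 1L, ...) {
  cohorts <- lapply(seq_len(K), function(k)
    make_cohort(sprintf("c%02d", k), n = n, p = p, seed = seed + k, ...))
  intersect_genes(cohorts)
}

# A small simulated collection (cheap stand-in for the default scenario).
small_sim <- function(seed = 11L, K = 3L, n = 60L, p = 40L,
                      n_prognostic = 8L) {
  simulate_collection(sim_config(K = K, n_per_cohort = n, p = p,
                                 n_prognostic = n_prognostic,
                                 effect_size = 0.6,
                                 baseline_hazard = c(0.05, 0.2, 0.5),
                                 distortion = c("identity", "log", "power"),
                                 seed = seed))
}

# ---- independent oracles -------------------------------------------------

# Naive double-loop evaluation of the hinge discordance loss and its
# subgradient, straight from the defining sums (O(m d)).
oracle_hinge <- function(X, w, times, events) {
  n <- ncol(X)
  b <- as.numeric(crossprod(X, w))
  L <- 0
  g <- numeric(nrow(X))
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[j] <= times[i]) next
      delta <- b[j] - b[i]
      if (delta < 1) {
        L <- L + 1 + b[i] - b[j]
        g <- g + X[, i] - X[, j]
      }
    }
  }
  list(loss = L, gradient = g)
}

# Brute-force comparable-pair enumeration.
oracle_pairs <- function(times, events) {
  out <- NULL
  n <- length(times)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[j] > times[i]) out <- rbind(out, c(j, i))
    }
  }
  if (is.null(out)) matrix(integer(), 0L, 2L) else out
}

# Literal delete-one jackknife se of the concordance index.
oracle_jackknife_se <- function(scores, times, events) {
  n <- length(scores)
  cvec <- vapply(seq_len(n), function(u)
    concordance_index(scores[-u], times[-u], events[-u])$c, numeric(1L))
  sqrt((n - 1) / n * sum((cvec - mean(cvec))^2))
}

# Breslow partial log-likelihood for a single coefficient (grid oracle).
oracle_breslow_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    risk <- times >= t
    ev <- events == 1 & times == t
    ll <- ll + beta * sum(x[ev]) - sum(ev) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Manual BH step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
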