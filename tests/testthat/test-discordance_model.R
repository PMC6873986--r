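# Hinge loss/subgradient, joint loss, fitting, CV and scoring.

test_that("hinge loss reproduces the hand-traced base cases", {
  # zero coefficients: every pair violates with margin exactly 1
  co <- make_cohort(seed = 41)
  ranked <- percentile_rank_transform(co$expression)
  pairs <- comparable_pairs(co$clinical$time, co$clinical$event)
  res <- hinge_loss_subgradient(ranked, numeric(nrow(ranked)), pairs)
  expect_equal(res$loss, pairs$m)

  # n = 2 hand trace: x1 = (1,0), x2 = (0,1), E = {(2,1)}, w = 0
  X <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  pairs2 <- comparable_pairs(c(1, 5), c(1, 0))
  expect_identical(cbind(pairs2$j, pairs2$i), cbind(2L, 1L))
  res2 <- hinge_loss_subgradient(X, c(0, 0), pairs2)
  expect_equal(res2$loss, 1)
  expect_equal(res2$gradient, c(1, -1))   # X %*% (+1, -1)

  expect_error(hinge_loss_subgradient(X, c(0, 0, 0), pairs2), "coefficient")
})

test_that("fast subgradient equals the naive double-loop oracle", {
  set.seed(42)
  for (r in 1:40) {
    n <- sample(5:50, 1); d <- sample(2:10, 1)
    X <- matrix(rnorm(d * n), d, n)
    tm <- rexp(n, 0.2); ev <- rbinom(n, 1, 0.6)
    w <- rnorm(d)
    fast <- hinge_loss_subgradient(X, w, comparable_pairs(tm, ev))
    ora <- oracle_hinge(X, w, tm, ev)
    expect_equal(fast$loss, ora$loss, tolerance = 1e-11)
    expect_equal(fast$gradient, ora$gradient, tolerance = 1e-11)
  }
})

test_that("joint loss adds cohorts and the ridge term", {
  col <- percentile_rank_transform(make_collection(K = 2, seed = 43))
  prob <- discordance_problem(col)
  w <- rnorm(length(prob$genes))
  j0 <- joint_loss(prob, w, lambda = 0)
  singles <- lapply(seq_along(col$cohorts), function(k)
    hinge_loss_subgradient(prob$X[[k]], w, prob$pairs[[k]]))
  expect_equal(j0$loss, sum(vapply(singles, `[[`, numeric(1), "loss")))
  jl <- joint_loss(prob, w, lambda = 2.5)
  expect_equal(jl$loss, j0$loss + 2.5 * sum(w^2))
  expect_equal(jl$gradient, j0$gradient + 5 * w)

  # K = 1 equals the single-cohort result plus penalty
  p1 <- discordance_problem(cohort_collection(col$cohorts[1]))
  expect_equal(joint_loss(p1, w, 0)$loss, singles[[1]]$loss)
})

test_that("within-cohort time rescaling leaves loss and gradient alone", {
  col <- percentile_rank_transform(make_collection(K = 3, seed = 44))
  prob <- discordance_problem(col)
  w <- rnorm(length(prob$genes))
  base <- joint_loss(prob, w, 1)
  warped <- col
  warped$cohorts[[2]]$clinical$time <- 7 * warped$cohorts[[2]]$clinical$time
  warped$cohorts[[3]]$clinical$time <- warped$cohorts[[3]]$clinical$time^3
  prob2 <- discordance_problem(warped)
  after <- joint_loss(prob2, w, 1)
  expect_equal(after$loss, base$loss)
  expect_equal(after$gradient, base$gradient)
})

test_that("fit respects penalty dominance and descends from zero", {
  col <- percentile_rank_transform(make_collection(K = 2, seed = 45))
  prob <- discordance_problem(col)
  huge <- fit_discordance(prob, 1e8)
  expect_lt(sqrt(sum(huge$w^2)), 1e-3)

  fit <- fit_discordance(prob, 0.1)
  at_zero <- joint_loss(prob, numeric(length(prob$genes)), 0.1)$loss
  expect_lte(fit$loss, at_zero)
  expect_equal(at_zero, sum(prob$m_per_cohort) +  0)
})

test_that("a linearly separable instance is driven to c-index 1", {
  # Separability must hold in rank space: sample i's *within-sample* rank
  # of gene g1 is i, so the transformed g1 feature is i/p and survival
  # time i is ordered with margin 1/p by w* = (c, 0, ..., 0), c >= p.
  set.seed(46)
  mk <- function(name) {
    n <- 6L; p <- 6L
    genes <- sprintf("g%d", 1:p)
    X <- sapply(seq_len(n), function(i) {
      v <- numeric(p)
      v[1L] <- i
      v[-1L] <- sample(setdiff(seq_len(p), i))
      v
    })
    dimnames(X) <- list(genes, sprintf("%s%02d", name, 1:n))
    clin <- data.frame(sample_id = colnames(X), time = as.numeric(1:n),
                       event = rep(1, n), stringsAsFactors = FALSE)
    assemble_cohort(X, clin, name)
  }
  a <- mk("a"); b <- mk("b")
  col <- percentile_rank_transform(intersect_genes(list(a, b)))
  prob <- discordance_problem(col)
  wstar <- setNames(c(12, numeric(5)), prob$genes)
  expect_equal(joint_loss(prob, wstar, 0)$loss, 0)   # truly separable
  fit <- fit_discordance(prob, 1e-6)
  sig <- trained_signature(prob$genes, fit$w, 1e-6)
  for (co in list(a, b)) {
    r <- risk_score(sig, co)
    expect_equal(concordance_index(r, co$clinical$time,
                                   co$clinical$event)$c, 1.0)
  }
})

test_that("lodo_select_lambda shapes, ties and guards", {
  col <- percentile_rank_transform(small_sim(seed = 47)$collection)
  genes <- utils::head(col$gene_universe, 6)
  grid <- c(0.1, 10)
  cv <- lodo_select_lambda(col, genes, grid)
  expect_identical(dim(cv$heldout_loss), c(2L, 3L))    # K = 3 folds
  expect_equal(cv$cumulated_loss, rowSums(cv$heldout_loss))
  expect_equal(cv$best_lambda,
               cv$lambda_grid[max(which(cv$cumulated_loss ==
                                        min(cv$cumulated_loss)))])

  single <- lodo_select_lambda(col, genes, 3.3)
  expect_equal(single$best_lambda, 3.3)

  one <- cohort_collection(col$cohorts[1])
  expect_error(lodo_select_lambda(one, genes, grid), "at least 2")
  expect_error(lodo_select_lambda(col, genes, c(0, 1)), "positive")
})

test_that("coefficient norm is non-increasing along the lambda grid", {
  col <- percentile_rank_transform(small_sim(seed = 48)$collection)
  genes <- utils::head(col$gene_universe, 8)
  prob <- discordance_problem(col, genes)
  grid <- 10^seq(-2, 2, length.out = 5)
  norms <- vapply(grid, function(l)
    sqrt(sum(fit_discordance(prob, l)$w^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("train_signature is deterministic and records provenance", {
  sim <- small_sim(seed = 49)
  cohorts <- sim$collection$cohorts
  grid <- c(0.1, 1, 10)
  s1 <- suppressWarnings(train_signature(cohorts, lambda_grid = grid,
                                         min_genes = 5L))
  s2 <- suppressWarnings(train_signature(cohorts, lambda_grid = grid,
                                         min_genes = 5L))
  expect_identical(s1$gene_ids, s2$gene_ids)
  expect_identical(s1$coefficients, s2$coefficients)
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$provenance$cohorts, names(cohorts))
  expect_identical(s1$provenance$d_selected, length(s1$gene_ids))
  expect_s3_class(attr(s1, "priority_table"), "gene_priority_table")
  expect_s3_class(attr(s1, "cv_report"), "cv_report")
})

test_that("alpha = 1 selects every gene and the pipeline still runs", {
  sim <- small_sim(seed = 50, K = 2L, n = 30L, p = 12L, n_prognostic = 3L)
  sig <- suppressWarnings(train_signature(sim$collection$cohorts,
                                          alpha = 1.0, lambda = 1))
  expect_identical(length(sig$gene_ids), 12L)
})

test_that("single-cohort training demands an explicit lambda", {
  sim <- small_sim(seed = 51, K = 1L, n = 40L, p = 12L, n_prognostic = 3L)
  expect_error(suppressWarnings(
    train_signature(sim$collection$cohorts)), "explicit lambda")
  sig <- suppressWarnings(train_signature(sim$collection$cohorts,
                                          lambda = 0.5, min_genes = 4L))
  expect_equal(sig$lambda, 0.5)
})

test_that("risk_score conventions and guards", {
  co <- make_cohort(seed = 52, n = 10, p = 4)
  sig <- trained_signature(c("g01"), 1, 0)
  r <- risk_score(sig, co)
  ranks <- percentile_rank_transform(co$expression)["g01", ]
  expect_equal(order(r), order(-ranks))   # risk reverses the gene's ranks

  distorted <- co
  distorted$expression <- exp(co$expression)
  expect_equal(risk_score(sig, distorted), r)

  expect_error(risk_score(trained_signature("nope", 1, 0), co), "nope")
})

test_that("merge_collection concatenates samples for the naive baseline", {
  col <- make_collection(K = 2, n = 10, seed = 53)
  merged <- merge_collection(col)
  expect_identical(ncol(merged$expression), 20L)
  expect_identical(nrow(merged$clinical), 20L)
  m_merged <- comparable_pairs(merged$clinical$time,
                               merged$clinical$event)$m
  m_within <- sum(vapply(col$cohorts, function(co)
    comparable_pairs(co$clinical$time, co$clinical$event)$m, integer(1)))
  expect_gt(m_merged, m_within)          # cross-cohort pairs exist
})
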