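make_corr <- function(n, p, seed) {
  set.seed(seed)
  d <- matrix(rnorm(n * (p + 1)), n)
  list(data = d, corr = cor(d))
}

test_that("subset_r2 matches closed forms and an explicit regression fit", {
  R <- diag(3)
  R[1, 3] <- R[3, 1] <- 0.6
  expect_equal(subset_r2(R, integer(0)), 0)
  expect_equal(subset_r2(R, 1), 0.36)
  # two orthogonal predictors: additivity
  R2 <- diag(3)
  R2[1, 3] <- R2[3, 1] <- 0.5
  R2[2, 3] <- R2[3, 2] <- 0.5
  expect_equal(subset_r2(R2, 1:2), 0.5)
  # regression oracle on real data
  mc <- make_corr(60, 4, seed = 41)
  df <- as.data.frame(mc$data)
  names(df) <- c(paste0("x", 1:4), "y")
  for (sub in list(1, c(1, 3), 1:4)) {
    f <- as.formula(paste("y ~", paste(names(df)[sub], collapse = "+")))
    expect_equal(subset_r2(mc$corr, sub), summary(lm(f, df))$r.squared,
                 tolerance = 1e-10)
  }
  expect_error(subset_r2(matrix(1:9, 3), 1), "symmetric")
})

test_that("general dominance weights decompose R2 and match orthogonal closed forms", {
  R <- diag(3)
  R[1, 3] <- R[3, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.5
  w <- general_dominance_weights(R)
  expect_equal(as.numeric(w), c(0.25, 0.25))
  expect_equal(attr(w, "r2_full"), 0.5)
  # p = 1: weight is the full R2
  R1 <- diag(2); R1[1, 2] <- R1[2, 1] <- 0.6
  expect_equal(as.numeric(general_dominance_weights(R1)), 0.36)
  expect_error(general_dominance_weights(diag(23)), "20 predictors")
})

test_that("general dominance equals the exhaustive lm-based brute force", {
  for (s in 1:10) {
    p <- sample(2:5, 1)
    mc <- make_corr(40, p, seed = 50 + s)
    w <- general_dominance_weights(mc$corr)
    oracle <- brute_force_dominance(mc$data)
    expect_equal(as.numeric(w), oracle$weights, tolerance = 1e-10)
    expect_equal(attr(w, "r2_full"), oracle$r2_full, tolerance = 1e-10)
    expect_equal(sum(w), attr(w, "r2_full"), tolerance = 1e-10)
  }
})

test_that("complete dominance implies a larger general weight", {
  # x1's incremental R2 beats x2's for every subset by construction
  R <- diag(4)
  R[1, 4] <- R[4, 1] <- 0.6
  R[2, 4] <- R[4, 2] <- 0.3
  R[1, 2] <- R[2, 1] <- 0.2
  R[3, 4] <- R[4, 3] <- 0.1
  w <- general_dominance_weights(R)
  expect_gt(w[1], w[2])
  expect_gt(w[2], w[3])
})

test_that("Monte-Carlo dominance conserves R2 per run and is seed-deterministic", {
  d <- planted_design(100, c(0.4, 0.2, 0), seed = 61)
  cfg <- da_config(n_runs = 200, seed = 8)
  r1 <- run_mc_dominance(d$X, d$y, cfg)
  expect_lt(max(abs(rowSums(r1$weights) - r1$r2)), 1e-10)
  r2 <- run_mc_dominance(d$X, d$y, cfg)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$table, r2$table)
  # parametric resampling switch also conserves
  r3 <- run_mc_dominance(d$X, d$y,
                         da_config(n_runs = 100, seed = 8,
                                   resampling = "parametric"))
  expect_lt(max(abs(rowSums(r3$weights) - r3$r2)), 1e-10)
})

test_that("a noiseless single-predictor outcome dominates every run", {
  set.seed(62)
  X <- cbind(x1 = rnorm(60), x2 = rnorm(60))
  y <- 2 * X[, "x1"]
  res <- run_mc_dominance(X, y, da_config(n_runs = 200, seed = 3))
  expect_equal(res$table$rank_mean[1], 1.0)
  expect_equal(res$table$sig[1], 100)
})

test_that("significance proportions follow the spurious noise-floor rule", {
  set.seed(63)
  n_runs <- 1000
  spur <- abs(rnorm(n_runs)) * 0.01
  zero <- matrix(0, n_runs, 2)
  expect_equal(unname(significance_proportions(zero, spur)), c(0, 0))
  above <- matrix(max(spur) + 1, n_runs, 2)
  expect_equal(unname(significance_proportions(above, spur)), c(100, 100))
  # exchangeable with the spurious draws: Sig near (1 - ci_level) * 100
  same <- matrix(abs(rnorm(n_runs * 3)) * 0.01, n_runs, 3)
  sig <- significance_proportions(same, spur)
  se3 <- 3 * sqrt(0.05 * 0.95 / n_runs) * 100
  expect_true(all(abs(sig - 5) < se3))
})

test_that("pairwise-difference matrix is symmetric, zero-diagonal, and detects planted gaps", {
  set.seed(64)
  W <- matrix(abs(rnorm(300)) * 0.01, 100, 3)
  spur <- abs(rnorm(100)) * 0.01
  m <- pairwise_difference_matrix(W, spur)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  # identical predictor columns never differ
  X <- cbind(a = rnorm(60), b = rnorm(60))
  X <- cbind(X, c = X[, "a"])
  y <- X[, "a"] + rnorm(60)
  res <- run_mc_dominance(X, y, da_config(n_runs = 100, seed = 5))
  expect_equal(res$pairwise["a", "c"], 0)
  # strong vs null predictor separates in most runs
  d <- planted_design(252, c(0.6, 0), seed = 65)
  res2 <- run_mc_dominance(d$X, d$y, da_config(n_runs = 500, seed = 6))
  expect_gt(res2$pairwise[1, 2], 80)
})

test_that("the spurious noise floor is calibrated for truly null predictors", {
  # aggregate calibration: over independent all-null datasets the expected
  # Sig is near (1 - ci_level) * 100 = 5%; individual datasets can run
  # higher when a null predictor draws a large in-sample correlation
  sigs <- c()
  for (s in 1:10) {
    set.seed(660 + s)
    X <- matrix(rnorm(252 * 4), 252, 4)
    y <- rnorm(252)
    res <- run_mc_dominance(X, y, da_config(n_runs = 300, seed = 70 + s))
    sigs <- c(sigs, res$table$sig)
  }
  expect_gt(mean(sigs), 1)
  expect_lt(mean(sigs), 10)
  expect_gte(mean(sigs <= 15), 0.8)
})

test_that("mean-weight ordering recovers planted effect orderings across cohorts", {
  hits <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    betas <- sample(c(0.5, 0.3, 0.1))
    d <- planted_design(252, betas, seed = 800 + s)
    res <- run_mc_dominance(d$X, d$y, da_config(n_runs = 250, seed = s))
    hits <- hits + identical(order(-res$table$weight_mean), order(-betas))
  }
  expect_gte(hits, 18)
})

test_that("constant bootstrap columns are redrawn and logged", {
  set.seed(67)
  X <- cbind(x1 = rnorm(20), rare = c(1, rep(0, 19)))
  y <- rnorm(20)
  res <- run_mc_dominance(X, y, da_config(n_runs = 200, seed = 9))
  expect_gt(sum(res$redraws), 0)
  expect_lt(max(abs(rowSums(res$weights) - res$r2)), 1e-10)
})
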