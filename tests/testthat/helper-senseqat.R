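# Shared fixtures and independent oracles. Everything here deliberately
# avoids the package's own computational paths so that tests compare two
# independent routes to the same quantity.

# Data whose *sample* (divide-by-n) covariance equals Sigma exactly:
# whiten centered iid normals, then color with chol(Sigma).
exact_moments_data <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  S <- crossprod(Z) / n
  W <- Z %*% solve(chol(S))
  W %*% chol(Sigma)
}

# Mann-Whitney U by literal pairwise enumeration: wins plus half-ties,
# small side.
brute_force_U <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + (x > y) + 0.5 * (x == y)
  min(u1, length(a) * length(b) - u1)
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments
# (tiny samples, no ties assumed): P(U_min <= observed U_min), which for a
# symmetric null equals the doubled one-tail probability.
enumerate_mw_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  combs <- utils::combn(length(pooled), n1)
  obs <- brute_force_U(a, b)
  us <- apply(combs, 2, function(ix)
    brute_force_U(pooled[ix], pooled[-ix]))
  min(1, mean(us <= obs))
}

# General dominance weights by literally fitting every subset with lm()
# and averaging increments, from raw data (outcome = last column).
brute_force_dominance <- function(dat) {
  p <- ncol(dat) - 1
  dat <- as.data.frame(dat)
  names(dat) <- c(paste0("x", seq_len(p)), "y")
  r2 <- function(subset) {
    if (length(subset) == 0) return(0)
    f <- stats::as.formula(paste("y ~", paste(names(dat)[subset],
                                              collapse = " + ")))
    summary(stats::lm(f, data = dat))$r.squared
  }
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  r2s <- vapply(subsets, r2, numeric(1))
  w <- numeric(p)
  for (j in seq_len(p)) {
    by_size <- vapply(0:(p - 1), function(k) {
      idx <- which(vapply(subsets, function(s)
        length(s) == k && !(j %in% s), logical(1)))
      incs <- vapply(idx, function(i) {
        with_j <- which(vapply(subsets, function(s)
          setequal(s, c(subsets[[i]], j)), logical(1)))
        r2s[with_j] - r2s[i]
      }, numeric(1))
      mean(incs)
    }, numeric(1))
    w[j] <- mean(by_size)
  }
  list(weights = w, r2_full = r2s[length(r2s)])
}

# A small cohort config that keeps unit tests fast.
quick_sim <- function(seed = 1, n = 120, ...) {
  sim_config(n_respondents = n, seed = seed, ...)
}

# Fast sampler settings for structural (non-inferential) pipeline tests.
quick_ssvs <- function(seed = 1) {
  ssvs_config(burn_in = 500, total_iterations = 3000, seed = seed)
}

# Multivariate normal predictors with given standardized effects; returns
# list(X, y). Used where the questionnaire layer is irrelevant.
planted_design <- function(n, betas, seed = 1, rho = 0, noise_sd = NULL) {
  set.seed(seed)
  p <- length(betas)
  S <- matrix(rho, p, p); diag(S) <- 1
  X <- matrix(rnorm(n * p), n, p) %*% chol(S)
  colnames(X) <- paste0("x", seq_len(p))
  if (is.null(noise_sd)) noise_sd <- sqrt(max(1e-12, 1 - sum(betas^2)))
  y <- drop(X %*% betas) + rnorm(n, sd = noise_sd)
  list(X = X, y = y)
}
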