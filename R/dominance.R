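#' Settings for Monte-Carlo dominance analysis
#'
#' @param n_runs number of Monte-Carlo runs (default 1000).
#' @param ci_level level for percentile confidence intervals and for the
#'   spurious-predictor noise floor (default 0.95).
#' @param spurious append a freshly drawn standard-normal spurious predictor
#'   to every run as the empirical null for significance.
#' @param resampling `"bootstrap"` resamples respondents with replacement;
#'   `"parametric"` draws fresh multivariate-normal data matching the
#'   observed mean and covariance.
#' @param seed integer seed.
#' @return object of class `da_config`.
#' @export
da_config <- function(n_runs = 1000, ci_level = 0.95, spurious = TRUE,
                      resampling = c("bootstrap", "parametric"), seed = 1L) {
  if (n_runs < 2) stop("n_runs must be at least 2")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(list(n_runs = as.integer(n_runs), ci_level = ci_level,
                 spurious = isTRUE(spurious),
                 resampling = match.arg(resampling),
                 seed = as.integer(seed)),
            class = "da_config")
}

check_corr <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8 ||
      max(abs(diag(corr) - 1)) > 1e-8)
    stop("corr must be a symmetric correlation matrix with unit diagonal")
  corr
}

#' Squared multiple correlation of the outcome on a predictor subset
#'
#' Computed from the correlation matrix as `r_S' R_SS^{-1} r_S`, where the
#' outcome occupies the last row/column. The empty subset gives 0. A
#' singular predictor submatrix falls back to the Moore-Penrose
#' pseudoinverse with a warning (collinear Likert sums can be
#' near-singular).
#'
#' @param corr (p+1) x (p+1) correlation matrix, outcome last.
#' @param subset integer indices (into 1..p) of the predictors to use.
#' @return R-squared (scalar).
#' @export
subset_r2 <- function(corr, subset) {
  corr <- check_corr(corr)
  p <- nrow(corr) - 1
  if (length(subset) == 0) return(0)
  if (any(subset < 1 | subset > p)) stop("subset indices out of range")
  Rs <- corr[subset, subset, drop = FALSE]
  rs <- corr[subset, p + 1]
  sol <- tryCatch(solve(Rs, rs), error = function(e) {
    warning("singular predictor submatrix; using pseudoinverse")
    MASS::ginv(Rs) %*% rs
  })
  drop(crossprod(rs, sol))
}

#' General dominance weights
#'
#' For each predictor, the incremental R-squared of adding it is averaged
#' over all subsets of the other predictors of each size, then averaged
#' across subset sizes; the weights decompose the full-model R-squared
#' exactly. Enumeration over all `2^p` subsets limits `p` to 20.
#'
#' @param corr (p+1) x (p+1) correlation matrix, outcome last.
#' @return named weight vector with the full-model R-squared attached as
#'   attribute `r2_full`.
#' @export
general_dominance_weights <- function(corr) {
  corr <- check_corr(corr)
  p <- nrow(corr) - 1
  if (p < 1) stop("need at least one predictor")
  if (p > 20) stop("all-subsets enumeration is limited to 20 predictors")
  res <- dominance_weights_cpp(corr)
  w <- as.numeric(res$weights)
  nm <- rownames(corr)[seq_len(p)]
  if (!is.null(nm)) names(w) <- nm
  attr(w, "r2_full") <- res$r2_full
  w
}

#' Significance proportions against the spurious noise floor
#'
#' `Sig_j` is the percentage of runs in which predictor j's dominance
#' weight exceeds `q`, the `ci_level` quantile of the pooled spurious
#' weights across all runs. A predictor distributionally identical to the
#' spurious one therefore earns a Sig near `(1 - ci_level) * 100`.
#'
#' @param per_run_weights runs x p matrix of weights.
#' @param spurious_weights vector of spurious-predictor weights, one per
#'   run.
#' @param ci_level noise-floor quantile level.
#' @return named percentage vector in `[0, 100]`.
#' @export
significance_proportions <- function(per_run_weights, spurious_weights,
                                     ci_level = 0.95) {
  per_run_weights <- as.matrix(per_run_weights)
  if (nrow(per_run_weights) != length(spurious_weights))
    stop("run dimensions of weights and spurious weights disagree")
  q <- quantile(spurious_weights, ci_level, names = FALSE)
  100 * colMeans(per_run_weights > q)
}

#' Pairwise-difference percentage matrix
#'
#' Entry (A, B) is the percentage of runs in which the two predictors'
#' dominance weights differ by more than the spurious noise floor `q`
#' (the `ci_level` quantile of the pooled spurious weights). Symmetric
#' with a zero diagonal.
#'
#' @inheritParams significance_proportions
#' @return p x p percentage matrix.
#' @export
pairwise_difference_matrix <- function(per_run_weights, spurious_weights,
                                       ci_level = 0.95) {
  per_run_weights <- as.matrix(per_run_weights)
  p <- ncol(per_run_weights)
  if (p < 2) stop("need at least 2 predictors")
  if (nrow(per_run_weights) != length(spurious_weights))
    stop("run dimensions of weights and spurious weights disagree")
  q <- quantile(spurious_weights, ci_level, names = FALSE)
  m <- matrix(0, p, p,
              dimnames = list(colnames(per_run_weights),
                              colnames(per_run_weights)))
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      v <- 100 * mean(abs(per_run_weights[, a] - per_run_weights[, b]) > q)
      m[a, b] <- v
      m[b, a] <- v
    }
  }
  m
}

#' Monte-Carlo dominance analysis with a spurious-predictor null
#'
#' For each run, respondents are resampled (paired rows of `X` and `y`), a
#' freshly drawn standard-normal spurious predictor is appended (drawn on
#' the original rows and carried through the same resampling index, which
#' variance-matches its weights to those of a truly null real predictor),
#' and general dominance weights are computed from that run's correlation
#' matrix.
#' Aggregates are weight means with percentile CIs, per-run ranks
#' (1 = largest weight; the spurious predictor is excluded from ranking but
#' contributes to the weights), significance proportions against the
#' spurious noise floor, the pairwise-difference percentage matrix, and the
#' full-model R-squared. A run containing a constant column is redrawn
#' (at most 10 times per run index, counted in `redraws`).
#'
#' @param X numeric matrix (n x p) of selected predictors, with column
#'   names.
#' @param y numeric outcome.
#' @param config a [da_config()].
#' @return object of class `dominance_result`.
#' @export
run_mc_dominance <- function(X, y, config = da_config()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 1) stop("need at least one predictor")
  if (n <= p + 2) stop("need n > p + 2 respondents")
  if (length(y) != n) stop("X and y dimensions disagree")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  preds <- colnames(X)
  set.seed(config$seed)

  use_spur <- config$spurious
  k <- p + use_spur
  W <- matrix(NA_real_, config$n_runs, k)
  r2_full <- numeric(config$n_runs)
  redraws <- integer(config$n_runs)

  if (config$resampling == "parametric") {
    D <- cbind(X, y)
    mu <- colMeans(D)
    Lc <- chol(cov(D))
  }

  for (b in seq_len(config$n_runs)) {
    for (attempt in 0:10) {
      if (config$resampling == "bootstrap") {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        # the spurious column is drawn on the original rows and resampled
        # through the same bootstrap index, so its weights carry the same
        # two levels of sampling variation (dataset anchor + resampling
        # jitter) as a truly null real predictor
        spur <- if (use_spur) rnorm(n)[idx]
      } else {
        Db <- matrix(rnorm(n * (p + 1)), n) %*% Lc +
          matrix(mu, n, p + 1, byrow = TRUE)
        Xb <- Db[, seq_len(p), drop = FALSE]
        yb <- Db[, p + 1]
        spur <- if (use_spur) rnorm(n)
      }
      M <- if (use_spur) cbind(Xb, .spurious = spur, yb)
           else cbind(Xb, yb)
      sds <- apply(M, 2, sd)
      if (all(sds > 0)) break
      redraws[b] <- redraws[b] + 1L
      if (attempt == 10)
        stop("run ", b, ": constant column persisted after 10 redraws")
    }
    res <- dominance_weights_cpp(cor(M))
    W[b, ] <- res$weights
    r2_full[b] <- res$r2_full
  }
  colnames(W) <- c(preds, if (use_spur) ".spurious")

  Wp <- W[, seq_len(p), drop = FALSE]
  ranks <- t(apply(Wp, 1, function(w) rank(-w, ties.method = "average")))
  if (p == 1) ranks <- matrix(1, config$n_runs, 1)
  colnames(ranks) <- preds

  ci <- c((1 - config$ci_level) / 2, 1 - (1 - config$ci_level) / 2)
  qr2 <- quantile(r2_full, ci, names = FALSE)
  tab <- data.frame(
    predictor = preds,
    weight_mean = colMeans(Wp),
    weight_lo = apply(Wp, 2, quantile, ci[1]),
    weight_hi = apply(Wp, 2, quantile, ci[2]),
    rank_mean = colMeans(ranks),
    rank_lo = apply(ranks, 2, quantile, ci[1]),
    rank_hi = apply(ranks, 2, quantile, ci[2]),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  sig <- NULL
  pairwise <- NULL
  spur_w <- NULL
  if (use_spur) {
    spur_w <- W[, ".spurious"]
    sig <- significance_proportions(Wp, spur_w, config$ci_level)
    tab$sig <- as.numeric(sig)
    if (p >= 2) pairwise <- pairwise_difference_matrix(Wp, spur_w,
                                                       config$ci_level)
  }

  structure(list(table = tab, pairwise = pairwise, weights = W,
                 ranks = ranks, spurious_weights = spur_w,
                 r2 = r2_full, r2_mean = mean(r2_full),
                 r2_lo = qr2[1], r2_hi = qr2[2],
                 redraws = redraws, predictors = preds, config = config),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("Monte-Carlo dominance analysis:", length(x$predictors),
      "predictors,", x$config$n_runs, "runs\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab)
  cat(sprintf("Full-model R2 = %.3f [%.3f, %.3f]\n",
              x$r2_mean, x$r2_lo, x$r2_hi))
  invisible(x)
}

#' Heatmap of the pairwise-difference percentage matrix
#'
#' @param x a `dominance_result` with at least two predictors.
#' @param ... passed to [graphics::image()].
#' @export
plot.dominance_result <- function(x, ...) {
  if (is.null(x$pairwise)) stop("no pairwise matrix available")
  p <- nrow(x$pairwise)
  graphics::image(seq_len(p), seq_len(p), t(x$pairwise[p:1, ]),
                  axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, 100), ...)
  graphics::axis(1, seq_len(p), colnames(x$pairwise), las = 2)
  graphics::axis(2, seq_len(p), rev(rownames(x$pairwise)), las = 2)
  invisible(x)
}
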