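#' Sampler settings for stochastic search variable selection
#'
#' Defaults follow the standard operating settings for this analysis: prior
#' inclusion probability 0.5 (each predictor enters with even prior odds),
#' 5000 burn-in iterations out of 20,000 total, and a continuous
#' spike-and-slab prior on the standardized scale. With `spike_sd = 0.01`
#' and `slab_sd = 1`, "included" effectively means a standardized
#' coefficient no smaller than about 0.02.
#'
#' @param prior_inclusion prior probability that a predictor is included.
#' @param burn_in,total_iterations Gibbs iterations discarded / in total.
#' @param spike_sd,slab_sd prior SDs of the spike and slab components.
#' @param residual_prior length-2 vector: inverse-gamma shape and scale of
#'   the residual-variance prior.
#' @param mip_threshold marginal inclusion probability above which a
#'   predictor counts as selected.
#' @param seed integer seed; same seed means bit-identical chains.
#' @return object of class `ssvs_config`.
#' @export
ssvs_config <- function(prior_inclusion = 0.5, burn_in = 5000,
                        total_iterations = 20000, spike_sd = 0.01,
                        slab_sd = 1.0, residual_prior = c(0.01, 0.01),
                        mip_threshold = 0.5, seed = 1L) {
  if (prior_inclusion <= 0 || prior_inclusion >= 1)
    stop("prior_inclusion must lie in (0, 1)")
  if (burn_in >= total_iterations)
    stop("burn_in must be smaller than total_iterations")
  if (spike_sd <= 0 || slab_sd <= 0 || spike_sd > slab_sd)
    stop("need 0 < spike_sd <= slab_sd")
  if (mip_threshold <= 0 || mip_threshold >= 1)
    stop("mip_threshold must lie in (0, 1)")
  structure(list(prior_inclusion = prior_inclusion,
                 burn_in = as.integer(burn_in),
                 total_iterations = as.integer(total_iterations),
                 spike_sd = spike_sd, slab_sd = slab_sd,
                 residual_prior = residual_prior,
                 mip_threshold = mip_threshold, seed = as.integer(seed)),
            class = "ssvs_config")
}

#' Standardize a design matrix and outcome
#'
#' Centers each column and the outcome to mean zero and scales to unit
#' divide-by-(n-1) SD, so a single slab scale is comparable across Likert
#' sums, age and binary dummies, and no intercept needs to be sampled.
#' The transform parameters are returned for back-mapping coefficients.
#'
#' @param X numeric matrix (n x p) with column names.
#' @param y numeric outcome vector.
#' @return list with `X`, `y`, `centers`, `scales`, `y_center`, `y_scale`.
#' @export
standardize_design <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  if (any(scales == 0))
    stop("zero-variance column: ",
         paste(colnames(X)[scales == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale == 0) stop("zero-variance column: y")
  list(X = Xs, y = (y - y_center) / y_scale, centers = centers,
       scales = scales, y_center = y_center, y_scale = y_scale)
}

#' Run the spike-and-slab Gibbs sampler
#'
#' Samples coefficients, inclusion indicators and the residual variance of
#' a linear model under a continuous spike-and-slab prior, sweeping
#' predictors in fixed order each iteration. The marginal inclusion
#' probability (MIP) of a predictor is the mean of its indicator over the
#' retained (post burn-in) draws.
#'
#' @param X standardized design matrix (each column mean-zero; see
#'   [standardize_design()]).
#' @param y standardized outcome.
#' @param config an [ssvs_config()].
#' @return object of class `ssvs_fit` with elements `mip` (named vector),
#'   `gamma` (retained indicator draws), `beta` (retained coefficient
#'   draws), `sigma2`, `predictors`, `config`.
#' @export
run_ssvs <- function(X, y, config = ssvs_config()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (max(abs(colMeans(X))) > 1e-8 || abs(mean(y)) > 1e-8)
    stop("X and y must be standardized (see standardize_design)")
  set.seed(config$seed)
  res <- ssvs_gibbs_cpp(X, y, config$prior_inclusion, config$spike_sd,
                        config$slab_sd, config$residual_prior[1],
                        config$residual_prior[2], config$total_iterations,
                        config$burn_in)
  preds <- colnames(X)
  if (is.null(preds)) preds <- paste0("x", seq_len(ncol(X)))
  mip <- setNames(as.numeric(res$mip), preds)
  structure(list(mip = mip, gamma = res$gamma, beta = res$beta,
                 sigma2 = as.numeric(res$sigma2), predictors = preds,
                 config = config),
            class = "ssvs_fit")
}

#' Two-run stability diagnostic
#'
#' Pearson correlation between the marginal inclusion probabilities of two
#' independently seeded runs on the same data; values at or above 0.99 are
#' taken as evidence of a converged, stable selection.
#'
#' @param fit1,fit2 `ssvs_fit` objects over the same predictor set.
#' @return Pearson correlation (scalar).
#' @export
stability_check <- function(fit1, fit2) {
  if (!identical(fit1$predictors, fit2$predictors))
    stop("the two runs use different predictor sets")
  if (var(fit1$mip) == 0 || var(fit2$mip) == 0)
    stop("MIP vector is constant; correlation undefined")
  cor(fit1$mip, fit2$mip)
}

#' Select predictors above an inclusion threshold
#'
#' @param fit an `ssvs_fit`.
#' @param threshold MIP cutoff in (0, 1]; defaults to the fit's configured
#'   threshold (0.5). A threshold of 1 selects nothing.
#' @return character vector of selected predictors in descending MIP order.
#' @export
select_predictors <- function(fit, threshold = fit$config$mip_threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  sel <- fit$mip[fit$mip > threshold]
  names(sel)[order(-sel)]
}

#' Predictors selected in every cohort
#'
#' @param ... two or more character vectors of selected predictors.
#' @return predictors present in all selections, in the order of the first.
#' @export
intersect_selections <- function(...) {
  sels <- list(...)
  if (length(sels) == 1 && is.list(sels[[1]])) sels <- sels[[1]]
  Reduce(intersect, sels)
}

#' @export
print.ssvs_fit <- function(x, ...) {
  cat("Spike-and-slab SSVS fit:", length(x$predictors), "predictors,",
      x$config$total_iterations - x$config$burn_in, "retained draws\n")
  print(round(sort(x$mip, decreasing = TRUE), 3))
  invisible(x)
}

#' Bar plot of marginal inclusion probabilities
#'
#' @param x an `ssvs_fit`.
#' @param threshold horizontal reference line (the selection threshold).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ssvs_fit <- function(x, threshold = x$config$mip_threshold, ...) {
  graphics::barplot(sort(x$mip, decreasing = TRUE), las = 2,
                    ylab = "Marginal inclusion probability",
                    ylim = c(0, 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}
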