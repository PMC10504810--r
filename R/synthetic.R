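#' @title Names used throughout the pipeline
#' @description Canonical subscale and predictor names: seven sensory
#'   modalities, three trait subscales, and the seven covariates entering the
#'   14-predictor design (age, binary comorbidity flags for
#'   ADHD/DCD/anxiety/mood, and two gender dummies with woman as reference).
#' @rdname senseqat-names
#' @export
modality_names <- function() {
  c("visual", "auditory", "tactile", "olfactory", "gustatory",
    "proprioceptive", "vestibular")
}

#' @rdname senseqat-names
#' @export
trait_names <- function() c("aloof", "pragmatic", "rigid")

#' @rdname senseqat-names
#' @export
covariate_names <- function() {
  c("age", "adhd", "dcd", "anxiety", "mood", "gender_male", "gender_nonbinary")
}

#' @rdname senseqat-names
#' @export
predictor_names <- function() c(modality_names(), covariate_names())

#' Default correlation matrix of the modality latents
#'
#' Sensory modality scores are positively inter-correlated in questionnaire
#' data; an exchangeable structure with moderate correlation is used as the
#' default generating model.
#'
#' @param rho common inter-modality correlation.
#' @return 7x7 correlation matrix with modality dimnames.
#' @export
default_factor_corr <- function(rho = 0.3) {
  m <- matrix(rho, 7, 7, dimnames = list(modality_names(), modality_names()))
  diag(m) <- 1
  m
}

#' Default standardized generating coefficients
#'
#' One 3 x 14 matrix of standardized effects from the predictors to the three
#' trait latents. Defaults plant moderate, modality-specific effects (tactile
#' on the aloof trait, tactile and olfactory on the pragmatic trait, auditory
#' and proprioceptive on the rigid trait, plus a small anxiety effect on all
#' three), with every other predictor null.
#'
#' @return matrix with rows `trait_names()` and columns `predictor_names()`.
#' @export
default_trait_coefs <- function() {
  m <- matrix(0, 3, 14, dimnames = list(trait_names(), predictor_names()))
  m["aloof", "tactile"] <- 0.30
  m["pragmatic", "tactile"] <- 0.20
  m["pragmatic", "olfactory"] <- 0.15
  m["rigid", "auditory"] <- 0.30
  m["rigid", "proprioceptive"] <- 0.15
  m[, "anxiety"] <- m[, "anxiety"] + 0.10
  m
}

#' Default covariate-generating specification
#'
#' Age is normal (truncated below at 18), gender four-level categorical
#' (woman/man/non-binary/other), binary flags independent Bernoulli. The
#' `autism` flag is not a predictor; it provides the group variable for the
#' descriptive group-comparison stage.
#'
#' @export
default_covariate_spec <- function() {
  list(age_mean = 38, age_sd = 13,
       gender_probs = c(woman = 0.48, man = 0.42, nonbinary = 0.08,
                        other = 0.02),
       flag_prevalence = c(adhd = 0.08, dcd = 0.04, anxiety = 0.20,
                           mood = 0.20, autism = 0.25))
}

#' Configuration for a synthetic cohort
#'
#' Defines the generating model for one cohort: correlated modality latents,
#' linear planted effects onto three trait latents, graded-response
#' discretization of items, covariates, and attention-check failures.
#'
#' @param n_respondents cohort size.
#' @param factor_corr 7x7 symmetric positive-definite correlation matrix of
#'   the modality latents.
#' @param trait_coefs 3x14 matrix of standardized effects (rows
#'   `trait_names()`, columns `predictor_names()`).
#' @param noise_sd residual SD of each trait latent (length 1 or 3).
#' @param items_per_sensory,items_per_trait items per subscale.
#' @param likert_sensory,likert_trait number of response categories.
#' @param loading item-to-latent loading in `[0, 1]`; either a single value
#'   or a named vector with elements `sensory` and `trait`. Defaults give
#'   6-item sensory subscales a Cronbach's alpha around 0.7 and 12-item
#'   trait subscales around 0.85-0.9 after Likert coarsening.
#' @param attention_fail_rate expected proportion of respondents failing at
#'   least one attention check.
#' @param n_attention_checks number of attention-check items.
#' @param covariate_spec list as returned by [default_covariate_spec()].
#' @param seed integer RNG seed; regeneration with the same config is
#'   bit-identical.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_respondents = 252,
                       factor_corr = default_factor_corr(),
                       trait_coefs = default_trait_coefs(),
                       noise_sd = 0.9,
                       items_per_sensory = 6,
                       items_per_trait = 12,
                       likert_sensory = 5,
                       likert_trait = 6,
                       loading = c(sensory = 0.6, trait = 0.65),
                       attention_fail_rate = 0.03,
                       n_attention_checks = 3,
                       covariate_spec = default_covariate_spec(),
                       seed = 1L) {
  if (n_respondents < 1) stop("n_respondents must be a positive integer")
  if (!is.matrix(factor_corr) || nrow(factor_corr) != 7 ||
      ncol(factor_corr) != 7)
    stop("factor_corr must be a 7x7 matrix")
  if (max(abs(factor_corr - t(factor_corr))) > 1e-10)
    stop("factor_corr must be symmetric")
  if (max(abs(diag(factor_corr) - 1)) > 1e-10)
    stop("factor_corr must have unit diagonal")
  if (min(eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-10)
    stop("factor_corr must be positive definite")
  if (!is.matrix(trait_coefs) || nrow(trait_coefs) != 3 ||
      ncol(trait_coefs) != 14)
    stop("trait_coefs must be a 3x14 matrix (traits x predictors)")
  if (is.null(dimnames(trait_coefs)))
    dimnames(trait_coefs) <- list(trait_names(), predictor_names())
  if (length(loading) == 1) loading <- c(sensory = loading, trait = loading)
  loading <- loading[c("sensory", "trait")]
  if (any(loading < 0 | loading > 1)) stop("loading must lie in [0, 1]")
  if (attention_fail_rate < 0 || attention_fail_rate > 1)
    stop("attention_fail_rate must lie in [0, 1]")
  if (likert_sensory < 2 || likert_trait < 2)
    stop("Likert instruments need at least 2 categories")
  probs <- c(covariate_spec$gender_probs, covariate_spec$flag_prevalence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_respondents = as.integer(n_respondents),
                 factor_corr = factor_corr, trait_coefs = trait_coefs,
                 noise_sd = rep(noise_sd, length.out = 3),
                 items_per_sensory = as.integer(items_per_sensory),
                 items_per_trait = as.integer(items_per_trait),
                 likert_sensory = as.integer(likert_sensory),
                 likert_trait = as.integer(likert_trait),
                 loading = loading,
                 attention_fail_rate = attention_fail_rate,
                 n_attention_checks = as.integer(n_attention_checks),
                 covariate_spec = covariate_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Discretize a latent value onto an ordered Likert scale
#'
#' Graded-response style cut: category is `k + 1` where `k` is the number of
#' thresholds strictly below the latent value; categories are 1-based.
#'
#' @param latent numeric vector of latent values.
#' @param thresholds strictly increasing cutpoints (length = categories - 1).
#' @return integer categories in `[1, length(thresholds) + 1]`.
#' @export
latent_to_likert <- function(latent, thresholds) {
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  as.integer(rowSums(outer(latent, thresholds, ">")) + 1L)
}

# Equal-probability normal-quantile thresholds for an L-category item.
likert_thresholds <- function(levels) qnorm(seq_len(levels - 1) / levels)

# Standardize columns; an exactly constant column maps to zero rather than
# NaN (can happen for a rare flag in a tiny cohort).
standardize_cols <- function(m) {
  apply(m, 2, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws correlated modality latents, covariates, trait latents as a linear
#' function of the standardized predictors plus noise, and item responses via
#' a one-factor-per-subscale graded response model. Attention-check items are
#' included and a seeded fraction of respondents is planted to fail them.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements `responses`
#'   (respondents x items data frame with `pid` column), `covariates`,
#'   `key` (the [default_instrument_key()] used), and `truth` (a
#'   `synthetic_truth` holding latents, coefficients, thresholds and seed).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be built with sim_config()")
  set.seed(config$seed)
  n <- config$n_respondents
  cs <- config$covariate_spec

  # modality latents
  L <- chol(config$factor_corr)
  latents <- matrix(rnorm(n * 7), n, 7) %*% L
  colnames(latents) <- modality_names()

  # covariates
  age <- pmax(18, round(rnorm(n, cs$age_mean, cs$age_sd)))
  gender <- sample(names(cs$gender_probs), n, replace = TRUE,
                   prob = cs$gender_probs)
  flags <- vapply(cs$flag_prevalence, function(p) rbinom(n, 1L, p),
                  integer(n))
  covariates <- data.frame(pid = sprintf("P%04d", seq_len(n)),
                           age = age, gender = gender,
                           gender_male = as.integer(gender == "man"),
                           gender_nonbinary = as.integer(gender == "nonbinary"),
                           flags, stringsAsFactors = FALSE)

  # trait latents from standardized predictors
  P <- cbind(latents, as.matrix(covariates[, covariate_names()]))
  Ps <- standardize_cols(P)
  traits <- Ps %*% t(config$trait_coefs) +
    matrix(rnorm(n * 3), n, 3) %*% diag(config$noise_sd)
  colnames(traits) <- trait_names()
  traits_std <- standardize_cols(traits)

  key <- default_instrument_key(items_per_sensory = config$items_per_sensory,
                                items_per_trait = config$items_per_trait,
                                n_checks = config$n_attention_checks,
                                likert_sensory = config$likert_sensory,
                                likert_trait = config$likert_trait)

  th_s <- likert_thresholds(config$likert_sensory)
  th_t <- likert_thresholds(config$likert_trait)
  items <- list()
  for (s in modality_names()) {
    lam <- config$loading[["sensory"]]
    for (j in seq_len(config$items_per_sensory)) {
      v <- lam * latents[, s] + sqrt(1 - lam^2) * rnorm(n)
      items[[paste0(s, "_", j)]] <- latent_to_likert(v, th_s)
    }
  }
  for (s in trait_names()) {
    lam <- config$loading[["trait"]]
    for (j in seq_len(config$items_per_trait)) {
      v <- lam * traits_std[, s] + sqrt(1 - lam^2) * rnorm(n)
      items[[paste0(s, "_", j)]] <- latent_to_likert(v, th_t)
    }
  }
  checks <- key[key$attention_check, ]
  for (i in seq_len(nrow(checks)))
    items[[checks$item_id[i]]] <- rep(checks$correct_answer[i], n)

  responses <- data.frame(pid = covariates$pid, items,
                          stringsAsFactors = FALSE)
  responses <- plant_attention_failures(responses, key,
                                        rate = config$attention_fail_rate,
                                        seed = sample.int(2^31 - 2, 1))

  truth <- structure(list(config = config, latents = latents,
                          trait_latents = traits,
                          trait_latents_std = traits_std,
                          predictors_std = Ps,
                          trait_coefs = config$trait_coefs,
                          thresholds = list(sensory = th_s, trait = th_t),
                          attention_failers =
                            attr(responses, "attention_failers"),
                          seed = config$seed),
                     class = "synthetic_truth")
  structure(list(responses = responses, covariates = covariates, key = key,
                 truth = truth),
            class = "synthetic_cohort")
}

#' Plant attention-check failures
#'
#' A seeded random subset of respondents (expected fraction `rate`) answers
#' at least one attention-check item incorrectly; everyone else answers all
#' checks correctly.
#'
#' @param responses item-response data frame containing the check items.
#' @param key instrument key with `attention_check` and `correct_answer`.
#' @param rate failure probability per respondent, in `[0, 1]`.
#' @param seed integer seed.
#' @return `responses` with check columns rewritten; the pids of planted
#'   failers are recorded in the `attention_failers` attribute.
#' @export
plant_attention_failures <- function(responses, key, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  checks <- key[key$attention_check & !key$removed, ]
  if (nrow(checks) == 0)
    stop("key contains no attention-check items")
  if (!all(checks$item_id %in% names(responses)))
    stop("responses lack attention-check columns present in the key")
  set.seed(seed)
  n <- nrow(responses)
  for (i in seq_len(nrow(checks)))
    responses[[checks$item_id[i]]] <- rep(checks$correct_answer[i], n)
  fail <- runif(n) < rate
  for (r in which(fail)) {
    i <- sample.int(nrow(checks), 1)
    wrong <- setdiff(seq_len(checks$levels[i]), checks$correct_answer[i])
    responses[r, checks$item_id[i]] <- sample(wrong, 1)
  }
  attr(responses, "attention_failers") <- responses$pid[fail]
  responses
}
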