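#' Derive a stage seed from the master seed
#'
#' Deterministic splitting rule: the label is hashed with a 31-ary
#' polynomial rolling hash modulo 2^31 - 1 and combined with a multiplied
#' copy of the master seed, giving independent, reproducible streams per
#' stage/cohort/outcome.
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. `"ssvs/discovery/rigid/1"`).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483647)
}

#' Configuration of a full multi-cohort study
#'
#' @param cohorts named list; each element is either a [sim_config()] (the
#'   cohort is generated, with its seed re-derived from the master seed) or
#'   a list with `responses` and `covariates` CSV paths.
#' @param key instrument key; defaults to [default_instrument_key()]. The
#'   rigid-overlap items are always dropped before scoring.
#' @param rules an [exclusion_rules()] object.
#' @param ssvs an [ssvs_config()].
#' @param da a [da_config()].
#' @param outcomes trait subscales to analyze (each gets its own SSVS and
#'   dominance analysis).
#' @param covariates covariate columns entering the design alongside the
#'   seven modality scores (defaults to the full predictor list: age, the four comorbidity flags and the two gender dummies).
#' @param group_col optional covariate column giving the binary group flag
#'   for the descriptive comparison table (`NULL` to skip).
#' @param stability_min minimum two-run MIP correlation; an outcome whose
#'   diagnostic falls below this is aborted with a recorded diagnostic.
#' @param seed master seed; every stage seed is derived from it.
#' @return object of class `study_config`.
#' @export
study_config <- function(cohorts = list(discovery = sim_config(),
                                        replication = sim_config()),
                         key = NULL,
                         rules = exclusion_rules(),
                         ssvs = ssvs_config(),
                         da = da_config(),
                         outcomes = trait_names(),
                         covariates = covariate_names(),
                         group_col = "autism",
                         stability_min = 0.99,
                         seed = 1L) {
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be a named list")
  if (!all(outcomes %in% trait_names()))
    stop("outcomes must be trait subscales: ",
         paste(trait_names(), collapse = ", "))
  structure(list(cohorts = cohorts, key = key, rules = rules, ssvs = ssvs,
                 da = da, outcomes = outcomes, covariates = covariates,
                 group_col = group_col, stability_min = stability_min,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Assemble the study design matrix
#'
#' Binds the seven modality subscale sums to the requested covariate
#' columns. A warning is emitted for binary covariates with fewer than five
#' positive cells (sparse dummies are retained, not dropped).
#'
#' @param scores a `scale_scores` data frame.
#' @param covariates covariate table aligned with `scores`.
#' @param covariate_cols covariate column names to include.
#' @return numeric matrix with named columns.
#' @export
build_design <- function(scores, covariates,
                         covariate_cols = covariate_names()) {
  stopifnot(identical(scores$pid, covariates$pid))
  missing <- setdiff(covariate_cols, names(covariates))
  if (length(missing) > 0)
    stop("covariate table lacks columns: ", paste(missing, collapse = ", "))
  X <- cbind(as.matrix(scores[modality_names()]),
             as.matrix(covariates[covariate_cols]))
  for (cc in covariate_cols) {
    v <- covariates[[cc]]
    if (all(v %in% 0:1) && sum(v == 1) < 5)
      warning("covariate '", cc, "' has fewer than 5 positive cells")
  }
  X
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full study replica
#'
#' For every cohort: generate or load the data, screen respondents, score
#' the instruments (overlap items removed), and for each outcome run SSVS
#' twice with derived seeds, check two-run stability, and select predictors
#' above the MIP threshold. Selections are intersected across cohorts per
#' outcome, and Monte-Carlo dominance analysis is run per cohort on that
#' cohort's own selection. An outcome whose stability correlation falls
#' below `stability_min` is aborted with a recorded diagnostic; an empty
#' selection skips the dominance stage with an explicit record.
#'
#' @param config a [study_config()].
#' @return object of class `study_report` with elements `cohorts`, `ssvs`,
#'   `intersection`, `dominance` and `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  master <- config$seed
  key <- if (is.null(config$key)) default_instrument_key() else config$key
  key <- drop_overlap_items(key)
  seeds <- list()

  cohorts <- list()
  for (cn in names(config$cohorts)) {
    spec <- config$cohorts[[cn]]
    if (inherits(spec, "sim_config")) {
      spec$seed <- derive_seed(master, paste0("sim/", cn))
      seeds[[paste0("sim/", cn)]] <- spec$seed
      cohort <- with_stage(paste0("simulate/", cn), generate_dataset(spec))
      responses <- cohort$responses
      covariates <- cohort$covariates
      key_c <- drop_overlap_items(cohort$key)
      truth <- cohort$truth
    } else {
      responses <- with_stage(paste0("load/", cn),
                              read_responses_csv(spec$responses))
      covariates <- with_stage(paste0("load/", cn),
                               read_covariates_csv(spec$covariates))
      key_c <- key
      truth <- NULL
    }
    scr <- with_stage(paste0("screen/", cn),
                      apply_exclusions(responses, covariates, key_c,
                                       config$rules))
    scores <- with_stage(paste0("score/", cn),
                         score_subscales(scr$responses, key_c))
    comparison <- NULL
    gc <- config$group_col
    if (!is.null(gc) && gc %in% names(scr$covariates) &&
        length(unique(scr$covariates[[gc]])) == 2)
      comparison <- with_stage(paste0("compare/", cn),
                               comparison_table(scores,
                                                scr$covariates[[gc]]))
    cohorts[[cn]] <- list(responses = scr$responses,
                          covariates = scr$covariates,
                          exclusion_log = scr$log, scores = scores,
                          comparison = comparison, key = key_c,
                          truth = truth)
  }

  ssvs_res <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    X <- with_stage(paste0("design/", cn),
                    build_design(co$scores, co$covariates,
                                 config$covariates))
    ssvs_res[[cn]] <- list()
    for (o in config$outcomes) {
      y <- co$scores[[o]]
      std <- with_stage(paste0("standardize/", cn, "/", o),
                        standardize_design(X, y))
      cfg1 <- config$ssvs
      cfg2 <- config$ssvs
      cfg1$seed <- derive_seed(master, paste0("ssvs/", cn, "/", o, "/1"))
      cfg2$seed <- derive_seed(master, paste0("ssvs/", cn, "/", o, "/2"))
      seeds[[paste0("ssvs/", cn, "/", o, "/1")]] <- cfg1$seed
      seeds[[paste0("ssvs/", cn, "/", o, "/2")]] <- cfg2$seed
      fit1 <- with_stage(paste0("ssvs/", cn, "/", o),
                         run_ssvs(std$X, std$y, cfg1))
      fit2 <- with_stage(paste0("ssvs/", cn, "/", o),
                         run_ssvs(std$X, std$y, cfg2))
      stab <- stability_check(fit1, fit2)
      aborted <- stab < config$stability_min
      sel <- if (aborted) character(0) else select_predictors(fit1)
      ssvs_res[[cn]][[o]] <- list(
        fit1 = fit1, fit2 = fit2, stability = stab, selection = sel,
        aborted = aborted,
        diagnostic = if (aborted)
          sprintf("two-run MIP correlation %.4f below %.2f; outcome aborted",
                  stab, config$stability_min))
    }
  }

  intersection <- list()
  for (o in config$outcomes)
    intersection[[o]] <- intersect_selections(
      lapply(ssvs_res, function(cr) cr[[o]]$selection))

  dominance <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    X <- build_design(co$scores, co$covariates, config$covariates)
    dominance[[cn]] <- list()
    for (o in config$outcomes) {
      sr <- ssvs_res[[cn]][[o]]
      if (sr$aborted) {
        dominance[[cn]][[o]] <- list(skipped = TRUE,
                                     reason = "ssvs_unstable")
        next
      }
      if (length(sr$selection) == 0) {
        dominance[[cn]][[o]] <- list(skipped = TRUE,
                                     reason = "no predictors selected")
        next
      }
      dcfg <- config$da
      dcfg$seed <- derive_seed(master, paste0("da/", cn, "/", o))
      seeds[[paste0("da/", cn, "/", o)]] <- dcfg$seed
      dominance[[cn]][[o]] <- with_stage(
        paste0("dominance/", cn, "/", o),
        run_mc_dominance(X[, sr$selection, drop = FALSE],
                         co$scores[[o]], dcfg))
    }
  }

  manifest <- list(
    master_seed = master,
    seeds = seeds,
    package_version = as.character(utils::packageVersion("senseqat")),
    cohorts = lapply(cohorts, function(co)
      list(n_retained = nrow(co$scores),
           n_excluded = nrow(co$exclusion_log))),
    stability = lapply(ssvs_res, function(cr)
      lapply(cr, function(s) s$stability)),
    selections = lapply(ssvs_res, function(cr)
      lapply(cr, function(s) s$selection)),
    intersection = intersection)

  structure(list(cohorts = cohorts, ssvs = ssvs_res,
                 intersection = intersection, dominance = dominance,
                 manifest = manifest, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", length(x$cohorts), "cohort(s),",
      length(x$config$outcomes), "outcome(s)\n")
  for (o in names(x$intersection))
    cat(sprintf("  %-10s cross-cohort selection: %s\n", o,
                if (length(x$intersection[[o]]) == 0) "(none)"
                else paste(x$intersection[[o]], collapse = ", ")))
  invisible(x)
}
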