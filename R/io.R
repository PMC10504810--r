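#' Read an item-response table from CSV
#'
#' Expects a header row, a `pid` column and integer Likert codes in every
#' item column; a non-integer or missing code is an error naming the row
#' and column.
#'
#' @param path CSV path.
#' @return data frame with `pid` as character and integer item columns.
#' @export
read_responses_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"pid" %in% names(tab)) stop("responses CSV lacks a 'pid' column")
  tab$pid <- as.character(tab$pid)
  for (cc in setdiff(names(tab), "pid")) {
    v <- tab[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v))) {
      bad <- which(!grepl("^-?[0-9]+$", as.character(v)) | is.na(v))[1]
      stop(sprintf("non-integer item code in column '%s', data row %d",
                   cc, bad))
    }
    tab[[cc]] <- as.integer(v)
  }
  tab
}

#' Read a covariate table from CSV
#'
#' @param path CSV path (must contain a `pid` column).
#' @export
read_covariates_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"pid" %in% names(tab)) stop("covariates CSV lacks a 'pid' column")
  tab$pid <- as.character(tab$pid)
  tab
}

#' Write a synthetic cohort to a directory
#'
#' Emits `responses.csv`, `covariates.csv`, `key.csv` and `truth.json`
#' (generating coefficients, factor correlations, thresholds and seed).
#'
#' @param cohort a `synthetic_cohort` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$responses, file.path(dir, "responses.csv"),
            row.names = FALSE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write_instrument_key(cohort$key, file.path(dir, "key.csv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = truth$seed,
         trait_coefs = truth$trait_coefs,
         factor_corr = truth$config$factor_corr,
         thresholds = truth$thresholds,
         noise_sd = truth$config$noise_sd,
         loading = as.list(truth$config$loading),
         attention_failers = truth$attention_failers),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_da_csv <- function(da, path) {
  tab <- da$table
  tab$r2_mean <- da$r2_mean
  tab$r2_lo <- da$r2_lo
  tab$r2_hi <- da$r2_hi
  write.csv(tab, path, row.names = FALSE)
}

#' Write the report bundle of a study run
#'
#' Per cohort: exclusion log, score table and group-comparison table; per
#' cohort x outcome: MIP table (both runs), dominance table
#' and pairwise-difference matrix; plus a machine-readable `manifest.json`
#' recording seeds, stability diagnostics, selections and intersections.
#'
#' @param bundle a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in names(bundle$cohorts)) {
    co <- bundle$cohorts[[cn]]
    write.csv(co$exclusion_log,
              file.path(dir, paste0("exclusions_", cn, ".csv")),
              row.names = FALSE)
    write.csv(co$scores, file.path(dir, paste0("scores_", cn, ".csv")),
              row.names = FALSE)
    if (!is.null(co$comparison))
      write.csv(co$comparison,
                file.path(dir, paste0("comparison_", cn, ".csv")),
                row.names = FALSE)
    for (o in names(bundle$ssvs[[cn]])) {
      sr <- bundle$ssvs[[cn]][[o]]
      mip <- data.frame(predictor = sr$fit1$predictors,
                        mip_run1 = as.numeric(sr$fit1$mip),
                        mip_run2 = as.numeric(sr$fit2$mip),
                        stringsAsFactors = FALSE)
      write.csv(mip, file.path(dir, paste0("mip_", cn, "_", o, ".csv")),
                row.names = FALSE)
      da <- bundle$dominance[[cn]][[o]]
      if (inherits(da, "dominance_result")) {
        write_da_csv(da, file.path(dir, paste0("da_", cn, "_", o, ".csv")))
        if (!is.null(da$pairwise))
          write.csv(da$pairwise,
                    file.path(dir, paste0("pairwise_", cn, "_", o, ".csv")))
      }
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
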