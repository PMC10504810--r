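#' Build the default instrument key
#'
#' One row per item for the two instruments plus attention checks. Sensory
#' items carry alternating hyper/hypo-sensitivity tags; the two items known
#' to overlap with the rigid trait construct (a repeated-music auditory item
#' and a same-foods gustatory item) are flagged via `overlap_item` so that
#' [drop_overlap_items()] can mark them removed before the main analysis.
#' The flagged items are chosen with opposite tags so the post-removal
#' hyper/hypo split is 20/20.
#'
#' @param items_per_sensory,items_per_trait items per subscale.
#' @param n_checks number of attention-check items.
#' @param likert_sensory,likert_trait response categories per instrument.
#' @return data frame with columns `item_id`, `instrument`
#'   (`sensory`/`trait`/`check`), `subscale`, `tag` (`hyper`/`hypo`/`NA`),
#'   `attention_check`, `correct_answer`, `overlap_item`, `removed`,
#'   `reversed`, `levels`.
#' @export
default_instrument_key <- function(items_per_sensory = 6,
                                   items_per_trait = 12,
                                   n_checks = 3,
                                   likert_sensory = 5,
                                   likert_trait = 6) {
  rows <- list()
  for (s in modality_names()) {
    idx <- seq_len(items_per_sensory)
    rows[[s]] <- data.frame(
      item_id = paste0(s, "_", idx), instrument = "sensory", subscale = s,
      tag = ifelse(idx %% 2 == 1, "hyper", "hypo"),
      attention_check = FALSE, correct_answer = NA_integer_,
      overlap_item = FALSE, removed = FALSE, reversed = FALSE,
      levels = likert_sensory, stringsAsFactors = FALSE)
  }
  for (s in trait_names()) {
    idx <- seq_len(items_per_trait)
    rows[[s]] <- data.frame(
      item_id = paste0(s, "_", idx), instrument = "trait", subscale = s,
      tag = NA_character_, attention_check = FALSE,
      correct_answer = NA_integer_, overlap_item = FALSE, removed = FALSE,
      reversed = FALSE, levels = likert_trait, stringsAsFactors = FALSE)
  }
  if (n_checks > 0) {
    rows[["check"]] <- data.frame(
      item_id = paste0("check_", seq_len(n_checks)), instrument = "check",
      subscale = "check", tag = NA_character_, attention_check = TRUE,
      correct_answer = (likert_sensory + 1L) %/% 2L, overlap_item = FALSE,
      removed = FALSE, reversed = FALSE, levels = likert_sensory,
      stringsAsFactors = FALSE)
  }
  key <- do.call(rbind, rows)
  rownames(key) <- NULL
  # the two rigid-overlap items: one hypo (auditory) and one hyper (gustatory)
  if (items_per_sensory >= 6)
    key$overlap_item[key$item_id == "auditory_6"] <- TRUE
  if (items_per_sensory >= 5)
    key$overlap_item[key$item_id == "gustatory_5"] <- TRUE
  key
}

#' Mark the rigid-overlap sensory items as removed
#'
#' The auditory repeated-music item and the gustatory same-foods item
#' overlap conceptually with the rigid trait subscale and are excluded from
#' scoring; the auditory and gustatory subscales then contain five items
#' each. Idempotent.
#'
#' @param key an instrument key.
#' @return the key with `removed = TRUE` on exactly the overlap items.
#' @export
drop_overlap_items <- function(key) {
  ov <- key$overlap_item & key$instrument == "sensory"
  if (!any(ov & key$subscale == "auditory") ||
      !any(ov & key$subscale == "gustatory"))
    stop("key lacks the designated auditory/gustatory overlap items")
  key$removed[ov] <- TRUE
  key
}

# scored (non-check, non-removed) items of the key
scorable_items <- function(key) key[!key$removed & key$instrument != "check", ]

#' Score subscales, totals and hyper/hypo pools
#'
#' Summed scores per respondent: the three trait subscales and trait total,
#' the seven sensory subscales and sensory total, and the pooled hyper- and
#' hypo-sensitivity sums. Removed items never contribute. Out-of-range or
#' missing codes are hard errors naming the respondent and item.
#'
#' @param responses item-response data frame with a `pid` column.
#' @param key an instrument key (apply [drop_overlap_items()] first for the
#'   main analysis).
#' @return data frame of class `scale_scores`.
#' @export
score_subscales <- function(responses, key) {
  items <- scorable_items(key)
  missing <- setdiff(items$item_id, names(responses))
  if (length(missing) > 0)
    stop("responses lack scored items: ", paste(missing, collapse = ", "))
  vals <- as.matrix(responses[items$item_id])
  if (anyNA(vals) || any(vals != round(vals))) {
    bad <- which(is.na(vals) | vals != round(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer or missing response: respondent %s, item %s",
                 responses$pid[bad[1]], items$item_id[bad[2]]))
  }
  lo <- matrix(1, nrow(vals), ncol(vals), byrow = TRUE)
  hi <- matrix(items$levels, nrow(vals), ncol(vals), byrow = TRUE)
  if (any(vals < lo | vals > hi)) {
    bad <- which(vals < lo | vals > hi, arr.ind = TRUE)[1, ]
    stop(sprintf("response code out of range: respondent %s, item %s",
                 responses$pid[bad[1]], items$item_id[bad[2]]))
  }
  if (any(items$reversed)) {
    rev_idx <- which(items$reversed)
    vals[, rev_idx] <- rep(items$levels[rev_idx] + 1L, each = nrow(vals)) -
      vals[, rev_idx]
  }

  sum_over <- function(sel) {
    if (sum(sel) == 0) return(rep(0L, nrow(vals)))
    as.integer(rowSums(vals[, sel, drop = FALSE]))
  }
  out <- data.frame(pid = responses$pid, stringsAsFactors = FALSE)
  for (s in trait_names()) out[[s]] <- sum_over(items$subscale == s)
  out$trait_total <- as.integer(rowSums(out[trait_names()]))
  for (s in modality_names()) out[[s]] <- sum_over(items$subscale == s)
  out$sensory_total <- as.integer(rowSums(out[modality_names()]))
  sens <- items$instrument == "sensory"
  out$hyper <- sum_over(sens & !is.na(items$tag) & items$tag == "hyper")
  out$hypo <- sum_over(sens & !is.na(items$tag) & items$tag == "hypo")
  class(out) <- c("scale_scores", "data.frame")
  out
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the sum)`,
#' using population (divide-by-n) variances so the value is an exact
#' function of the data. Alpha is invariant to the shared variance
#' convention and to adding constants or positive rescaling of all items.
#'
#' @param item_matrix numeric matrix, respondents x k items.
#' @return alpha (scalar, at most 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(item_matrix) < 3) stop("Cronbach's alpha needs at least 3 rows")
  pvar <- function(x) mean((x - mean(x))^2)
  total_var <- pvar(rowSums(item_matrix))
  if (total_var == 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(item_matrix, 2, pvar)) / total_var)
}

#' Reliability report for both instruments
#'
#' Cronbach's alpha for each trait subscale and the trait total, each sensory
#' subscale and the sensory total, over scored (non-removed) items.
#'
#' @inheritParams score_subscales
#' @return data frame with columns `scale`, `n_items`, `alpha`.
#' @export
reliability_report <- function(responses, key) {
  items <- scorable_items(key)
  one <- function(scale, sel) {
    data.frame(scale = scale, n_items = sum(sel),
               alpha = cronbach_alpha(responses[items$item_id[sel]]),
               stringsAsFactors = FALSE)
  }
  rows <- list(one("trait_total", items$instrument == "trait"))
  for (s in trait_names()) rows[[s]] <- one(s, items$subscale == s)
  rows[["sensory_total"]] <- one("sensory_total",
                                 items$instrument == "sensory")
  for (s in modality_names()) rows[[s]] <- one(s, items$subscale == s)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Declare screening rules
#'
#' Rules are evaluated in declared order and the first matching rule gives
#' the recorded exclusion reason: optionally the attention-check rule
#' (respondent fails if any check item differs from its correct alternative),
#' then one rule per listed covariate flag column (excluded when the flag
#' is 1).
#'
#' @param attention apply the attention-check rule first?
#' @param flags character vector of covariate column names to exclude on.
#' @return object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(attention = TRUE, flags = character()) {
  rules <- list()
  if (attention)
    rules[[length(rules) + 1]] <- list(kind = "attention",
                                       reason = "failed_attention_check")
  for (f in flags)
    rules[[length(rules) + 1]] <- list(kind = "flag", column = f,
                                       reason = paste0("excluded_flag_", f))
  structure(rules, class = "exclusion_rules")
}

#' Apply screening rules to a cohort
#'
#' @param responses,covariates respondent-level tables sharing a `pid`
#'   column.
#' @param key instrument key (needed for the attention-check rule).
#' @param rules an [exclusion_rules()] object.
#' @return list with filtered `responses` and `covariates` plus a `log`
#'   data frame (`pid`, `reason`; one row per removed respondent, first
#'   matching rule wins).
#' @export
apply_exclusions <- function(responses, covariates, key,
                             rules = exclusion_rules()) {
  stopifnot(identical(responses$pid, covariates$pid))
  n <- nrow(responses)
  reason <- rep(NA_character_, n)
  for (rule in rules) {
    if (rule$kind == "attention") {
      checks <- key[key$attention_check & !key$removed, ]
      if (nrow(checks) == 0) next
      fails <- rep(FALSE, n)
      for (i in seq_len(nrow(checks)))
        fails <- fails |
          responses[[checks$item_id[i]]] != checks$correct_answer[i]
      hit <- fails
    } else {
      if (!rule$column %in% names(covariates))
        stop("unknown covariate column in exclusion rule: ", rule$column)
      hit <- covariates[[rule$column]] == 1
    }
    reason[is.na(reason) & hit] <- rule$reason
  }
  keep <- is.na(reason)
  list(responses = responses[keep, , drop = FALSE],
       covariates = covariates[keep, , drop = FALSE],
       log = data.frame(pid = responses$pid[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Read or write an instrument key as CSV
#'
#' @param key instrument key data frame.
#' @param path file path.
#' @rdname instrument_key_io
#' @export
write_instrument_key <- function(key, path) {
  write.csv(key, path, row.names = FALSE)
  invisible(path)
}

#' @rdname instrument_key_io
#' @export
read_instrument_key <- function(path) {
  key <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("item_id", "instrument", "subscale", "tag", "attention_check",
              "correct_answer", "overlap_item", "removed", "reversed",
              "levels")
  missing <- setdiff(needed, names(key))
  if (length(missing) > 0)
    stop("instrument key lacks columns: ", paste(missing, collapse = ", "))
  key$tag[key$tag %in% c("", "NA")] <- NA_character_
  key
}
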