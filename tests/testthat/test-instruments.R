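test_that("overlap removal leaves 40 scorable sensory items and is idempotent", {
  key <- default_instrument_key()
  expect_equal(sum(key$instrument == "sensory" & !key$removed), 42)
  key2 <- drop_overlap_items(key)
  sens <- key2[key2$instrument == "sensory" & !key2$removed, ]
  expect_equal(nrow(sens), 40)
  expect_equal(sum(sens$subscale == "auditory"), 5)
  expect_equal(sum(sens$subscale == "gustatory"), 5)
  expect_equal(table(sens$tag)[["hyper"]], 20)
  expect_equal(table(sens$tag)[["hypo"]], 20)
  expect_identical(drop_overlap_items(key2), key2)
  # precondition: designated items must exist
  broken <- key[key$item_id != "gustatory_5", ]
  expect_error(drop_overlap_items(broken), "overlap items")
})

test_that("subscale sums hit range endpoints and match brute-force re-summation", {
  key <- drop_overlap_items(default_instrument_key())
  items <- key[!key$removed & key$instrument != "check", ]
  make <- function(fill) {
    df <- data.frame(pid = c("a", "b", "c"), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(items)))
      df[[items$item_id[i]]] <- rep(fill(items$levels[i]), 3)
    df
  }
  lo <- score_subscales(make(function(l) 1L), key)
  expect_equal(lo$auditory, rep(5L, 3))     # 5 items x 1
  expect_equal(lo$aloof, rep(12L, 3))
  hi <- score_subscales(make(function(l) l), key)
  expect_equal(hi$auditory, rep(25L, 3))    # 5 items x 5
  expect_equal(hi$aloof, rep(72L, 3))       # 12 items x 6

  # randomized toy vs independent row-sum oracle
  set.seed(9)
  df <- data.frame(pid = c("a", "b", "c"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(items)))
    df[[items$item_id[i]]] <- sample.int(items$levels[i], 3, replace = TRUE)
  sc <- score_subscales(df, key)
  for (s in c(modality_names(), trait_names())) {
    ids <- items$item_id[items$subscale == s]
    oracle <- rowSums(df[ids])
    expect_equal(as.numeric(sc[[s]]), as.numeric(oracle))
  }
  expect_equal(sc$sensory_total, sc$hyper + sc$hypo)
  expect_equal(as.integer(rowSums(sc[modality_names()])), sc$sensory_total)
  expect_equal(as.integer(rowSums(sc[trait_names()])), sc$trait_total)
})

test_that("scoring rejects out-of-range codes and ignores removed items", {
  coh <- generate_dataset(quick_sim(n = 10))
  key <- drop_overlap_items(coh$key)
  bad <- coh$responses
  bad$visual_1[3] <- 9L
  expect_error(score_subscales(bad, key), "P0003.*visual_1")
  bad$visual_1[3] <- NA
  expect_error(score_subscales(bad, key), "P0003.*visual_1")
  # planting an extreme value in a removed item changes nothing
  base <- score_subscales(coh$responses, key)
  tweaked <- coh$responses
  tweaked$auditory_6 <- 999L
  expect_identical(score_subscales(tweaked, key), base)
})

test_that("cronbach_alpha matches closed forms and is scale-invariant", {
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # exact population moments: two unit-variance items, correlation 0.5
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  d <- exact_moments_data(40, S, seed = 2)
  expect_equal(cronbach_alpha(d), 2 / 3, tolerance = 1e-12)
  # two uncorrelated unit-variance items
  d0 <- exact_moments_data(40, diag(2), seed = 3)
  expect_equal(cronbach_alpha(d0), 0, tolerance = 1e-12)
  # invariances: shift by constants, multiply all items by a positive scalar
  set.seed(4)
  m <- matrix(rnorm(60), 20, 3)
  a0 <- cronbach_alpha(m)
  expect_equal(cronbach_alpha(m + 7), a0)
  expect_equal(cronbach_alpha(m * 3.3), a0)
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), "2 items")
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero variance")
})

test_that("synthetic 6-item sensory subscales land in the moderate reliability band", {
  in_band <- logical(0)
  for (s in 1:20) {
    coh <- generate_dataset(sim_config(n_respondents = 252, seed = s))
    rel <- reliability_report(coh$responses, drop_overlap_items(coh$key))
    a <- rel$alpha[rel$scale %in% modality_names()]
    in_band <- c(in_band, a >= 0.4 & a <= 0.8)
  }
  expect_gte(mean(in_band), 0.95)
})

test_that("exclusions follow declared rule order and match a replay oracle", {
  coh <- generate_dataset(sim_config(n_respondents = 100, seed = 21,
                                     attention_fail_rate = 0.1))
  key <- drop_overlap_items(coh$key)
  rules <- exclusion_rules(attention = TRUE, flags = "autism")
  res <- apply_exclusions(coh$responses, coh$covariates, key, rules)

  # independent per-respondent replay
  checks <- key[key$attention_check, ]
  for (i in seq_len(nrow(coh$responses))) {
    fails <- any(sapply(seq_len(nrow(checks)), function(k)
      coh$responses[i, checks$item_id[k]] != checks$correct_answer[k]))
    flagged <- coh$covariates$autism[i] == 1
    pid <- coh$responses$pid[i]
    if (fails) {
      expect_equal(res$log$reason[res$log$pid == pid],
                   "failed_attention_check")
    } else if (flagged) {
      expect_equal(res$log$reason[res$log$pid == pid],
                   "excluded_flag_autism")
    } else {
      expect_true(pid %in% res$responses$pid)
    }
  }
  expect_equal(nrow(res$responses) + nrow(res$log), 100)

  # no rules: identity
  ident <- apply_exclusions(coh$responses, coh$covariates, key,
                            exclusion_rules(attention = FALSE))
  expect_identical(ident$responses, coh$responses)
  expect_equal(nrow(ident$log), 0)

  # planted failers are removed
  planted <- plant_attention_failures(coh$responses, coh$key, rate = 0,
                                      seed = 1)
  planted[[checks$item_id[1]]][c(2, 5)] <- checks$correct_answer[1] + 1L
  out <- apply_exclusions(planted, coh$covariates, key,
                          exclusion_rules(attention = TRUE))
  expect_equal(nrow(out$responses), 98)
  expect_setequal(out$log$pid, planted$pid[c(2, 5)])
})

test_that("instrument keys round-trip through CSV", {
  key <- drop_overlap_items(default_instrument_key())
  path <- tempfile(fileext = ".csv")
  write_instrument_key(key, path)
  back <- read_instrument_key(path)
  expect_equal(back, key)
})
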