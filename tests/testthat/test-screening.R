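# A small deterministic cohort with a hand-set correctness structure:
# observers 101-105 are diligent references (correct on trials 1-90, accuracy
# 0.75 on both tasks), and test observers are layered on top.
screening_fixture <- function(extra = list()) {
  make_patterned_trials(c(reference_pattern(), extra))
}

test_that("trial difficulty is the proportion correct among above-chance participants", {
  # 3 above-chance observers; on trial 5 only two of them are correct
  pat <- list(
    `1` = list(length = 1:60, orientation = 1:60),
    `2` = list(length = 1:60, orientation = 1:60),
    `3` = list(length = setdiff(1:60, 5), orientation = 1:60),
    # below chance everywhere (10 correct out of 120)
    `4` = list(length = 1:10, orientation = 1:10)
  )
  tr <- make_patterned_trials(pat)
  diff_len <- dplyr::filter(trial_difficulty(tr), task == "length")
  expect_equal(nrow(diff_len), 120)
  expect_true(all(diff_len$difficulty >= 0 & diff_len$difficulty <= 1))
  expect_equal(diff_len$difficulty[diff_len$trial == 1], 1)
  expect_equal(diff_len$difficulty[diff_len$trial == 5], 2 / 3)
  expect_equal(unique(diff_len$n_above_chance), 3)

  # perturbing the below-chance observer's responses changes nothing
  tr2 <- make_patterned_trials(
    c(pat[1:3], list(`4` = list(length = 30:39, orientation = 50:59)))
  )
  expect_equal(trial_difficulty(tr2), trial_difficulty(tr))
})

test_that("trial difficulty fails loudly for a degenerate cohort", {
  pat <- list(`1` = list(length = 1:10, orientation = 1:10))
  expect_error(trial_difficulty(make_patterned_trials(pat)),
               "no above-chance participants")
})

test_that("person fit is the correlation of correctness with difficulty", {
  tr <- screening_fixture(list(
    `1` = list(length = 1:21, orientation = 1:36),        # succeeds on easy trials
    `2` = list(length = c(1:16, 91:95), orientation = 1:36)
  ))
  fits <- person_fit(tr)
  f1 <- fits$person_fit[fits$observer_id == 1 & fits$task == "length"]
  expect_gt(f1, 0.15)
  # the same accuracy spread across easy and hard trials carries little signal
  f2 <- fits$person_fit[fits$observer_id == 2 & fits$task == "length"]
  expect_lt(f2, 0.15)

  # succeeding exactly where the reference observers fail: negative fit
  tr_neg <- screening_fixture(list(`9` = list(length = 91:111,
                                              orientation = 1:36)))
  fneg <- person_fit(tr_neg)
  expect_lt(fneg$person_fit[fneg$observer_id == 9 & fneg$task == "length"], 0)

  # constant correctness has undefined fit
  tr_const <- screening_fixture(list(`8` = list(length = integer(0),
                                                orientation = 1:36)))
  fc <- person_fit(tr_const)
  expect_true(is.na(fc$person_fit[fc$observer_id == 8 & fc$task == "length"]))
})

test_that("the inclusion rule covers its three canonical cases", {
  tr <- screening_fixture(list(
    # accuracy 0.43 / 0.50: above chance on both
    `11` = list(length = 1:52, orientation = 1:60),
    # below chance on both with weak person fit: out
    `12` = list(length = c(1:16, 91:95), orientation = c(1:14, 91:94)),
    # below chance on length but sensitive to trial difficulty: rescued
    `13` = list(length = 1:21, orientation = 1:36)
  ))
  rep <- screen_participants(tr)
  row <- function(id) rep[rep$observer_id == id, ]

  expect_true(row(11)$included)
  expect_equal(row(11)$reason, "above-chance-both")
  expect_equal(row(11)$accuracy_length, 52 / 120)

  expect_false(row(12)$included)
  expect_equal(row(12)$reason, "below-fit-threshold")

  expect_true(row(13)$included)
  expect_equal(row(13)$reason, "rescued-by-person-fit")
  expect_false(row(13)$above_chance_length)

  # an undefined person fit fails the criterion
  tr_allwrong <- screening_fixture(list(`14` = list(length = integer(0),
                                                    orientation = 1:36)))
  expect_false(screen_participants(tr_allwrong)$included[
    screen_participants(tr_allwrong)$observer_id == 14])
})

test_that("manual exclusions override inclusion", {
  tr <- screening_fixture(list(`11` = list(length = 1:52, orientation = 1:60)))
  rep <- screen_participants(tr, manual_exclude = c(11, 103))
  expect_false(rep$included[rep$observer_id == 11])
  expect_equal(rep$reason[rep$observer_id == 11], "manual")
  expect_false(rep$included[rep$observer_id == 103])
})

test_that("re-screening the included subset with difficulty held fixed excludes no one", {
  trials <- simulate_study(cohort_params(n_observers = 40, p_inattentive = 0.2,
                                         seed = 31))
  difficulty <- trial_difficulty(trials)
  rep1 <- screen_participants(trials)
  kept <- rep1$observer_id[rep1$included]

  sub <- dplyr::filter(trials, observer_id %in% kept)
  fits <- person_fit(sub, difficulty = difficulty)
  acc <- dplyr::summarise(dplyr::group_by(sub, observer_id, task),
                          accuracy = mean(correct), .groups = "drop")
  joined <- dplyr::left_join(acc, fits, by = c("observer_id", "task"))
  still_ok <- dplyr::summarise(
    dplyr::group_by(joined, observer_id),
    ok = all(accuracy > 0.2) |
      all(accuracy > 0.2 | (!is.na(person_fit) & person_fit >= 0.15)),
    .groups = "drop"
  )
  expect_true(all(still_ok$ok))
})

test_that("screening separates inattentive from attentive observers at the rate the rule allows", {
  # An inattentive (uniform) responder still clears the strict >1/5 chance
  # criterion on one task with probability P(Bin(120, .2) > 24) ~ 0.446, so
  # the include-if-above-chance-on-both rule admits ~20% of them, and
  # the best attainable exclusion rate is ~0.78. Attentive observers with
  # calibrated noise are essentially always retained.
  res <- t(sapply(1:30, function(s) {
    p <- cohort_params(p_inattentive = 0.2, seed = s)
    obs <- draw_observers(p)
    tr <- simulate_study(obs, seed = s + 5000L)
    rep <- screen_participants(tr)
    j <- dplyr::left_join(rep, obs[, c("observer_id", "inattentive")],
                          by = "observer_id")
    c(excluded_inatt = sum(!j$included & j$inattentive),
      n_inatt = sum(j$inattentive),
      kept_att = sum(j$included & !j$inattentive),
      n_att = sum(!j$inattentive))
  }))
  excl_rate <- sum(res[, "excluded_inatt"]) / sum(res[, "n_inatt"])
  keep_rate <- sum(res[, "kept_att"]) / sum(res[, "n_att"])
  # the rule admits an inattentive observer with probability
  # p_above^2 (chance criterion on both tasks) plus a small person-fit rescue
  # term, so exclusion must sit below 1 - p_above^2 but stay substantial
  p_above <- pbinom(24, 120, 0.2, lower.tail = FALSE)
  expect_gt(excl_rate, 0.7)
  expect_lt(excl_rate, 1 - p_above^2 + 0.03)
  expect_gte(keep_rate, 0.95)
})

test_that("Cronbach's alpha matches its formula, an independent route, and known cases", {
  # perfectly parallel items
  set.seed(41)
  base <- rnorm(20)
  expect_equal(cronbach_alpha(cbind(base, base, base))$alpha, 1)

  # hand matrix: item variances 1 and 7/3, total variance 19/3
  m <- matrix(c(1, 2, 3, 2, 4, 5), nrow = 3)
  expect_equal(cronbach_alpha(m)$alpha, 18 / 19)
  # independent route through the covariance matrix:
  # alpha = k/(k-1) * (1 - tr(C) / sum(C))
  C <- cov(m)
  expect_equal(cronbach_alpha(m)$alpha,
               2 / 1 * (1 - sum(diag(C)) / sum(C)))

  # independent items: alpha near zero
  set.seed(42)
  noise <- matrix(rnorm(500 * 40), nrow = 500)
  expect_lt(abs(cronbach_alpha(noise)$alpha), 0.1)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_error(cronbach_alpha(matrix(1:4, 1)), "at least 2")
})

test_that("duplicating every item does not decrease alpha", {
  set.seed(43)
  x <- matrix(rnorm(30 * 10), nrow = 30) + rnorm(30)
  a1 <- cronbach_alpha(x)$alpha
  a2 <- cronbach_alpha(cbind(x, x))$alpha
  expect_gte(a2, a1)
})

test_that("task reliability uses trial-level absolute errors as items", {
  trials <- simulate_study(cohort_params(n_observers = 30, seed = 51))
  rel <- task_reliability(trials)
  expect_equal(rel$task, c("length", "orientation"))
  expect_equal(rel$n_items, c(120L, 120L))
  expect_equal(rel$n_cases, c(30L, 30L))
  expect_true(all(rel$alpha > 0.5 & rel$alpha <= 1))

  sub <- task_reliability(trials, include = 1:10)
  expect_equal(unique(sub$n_cases), 10L)
})
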