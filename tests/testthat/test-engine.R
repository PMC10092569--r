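dv <- c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0)

test_that("interim datasets expose exactly the completed cycles", {
  out_safe <- list(dlt_cycle = NA_integer_, cycles_on_study = 3L,
                   max_grade = c(0L, 1L, 0L), cat = c(1L, 1L, 1L),
                   nttp = c(0, 0.1, 0), grades = matrix(0L, 3, 3))
  out_dlt1 <- list(dlt_cycle = 1L, cycles_on_study = 1L,
                   max_grade = c(3L, NA, NA), cat = c(3L, NA, NA),
                   nttp = c(0.5, NA, NA), grades = matrix(0L, 3, 3))
  enrolled <- data.frame(id = 1:9,
                         dose = rep(1:3, each = 3),
                         dose_value = dv[rep(1:3, each = 3)],
                         enroll_week = rep(c(0, 6, 12), each = 3),
                         dlt_cycle = c(1L, rep(NA_integer_, 8)))
  outcomes <- c(list(out_dlt1), rep(list(out_safe), 8))

  d6 <- observable_dataset(enrolled, outcomes, 6, 3)
  expect_equal(d6$patients$u, c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))

  d18 <- observable_dataset(enrolled, outcomes, 18, 3)
  expect_equal(d18$patients$u[4:6], rep(2L, 3))   # second cohort: 2 cycles
  expect_equal(d18$patients$u[7:9], rep(1L, 3))   # third cohort: 1 cycle
  # cohort 1 complete except the cycle-1 DLT, who contributes 1 cycle ever
  expect_equal(d18$patients$u[1:3], c(1L, 3L, 3L))
  expect_equal(d18$patients$dlt[1], 1L)
  # no future leakage: every cycle row is within the patient's u
  merged <- merge(d18$cycles, d18$patients[, c("id", "u")], by = "id")
  expect_true(all(merged$cycle <= merged$u))

  d30 <- observable_dataset(enrolled, outcomes, 30, 3)
  expect_equal(d30$patients$u[1], 1L)  # still one cycle after going off study
})

test_that("an always-stay policy stops for sufficient information at 9 patients", {
  scn <- scenario(rep(0, 6))
  cfg <- trial_config(rules = rule_config(setting = 1))
  res <- run_trial(stub_design(function(state) 1L), scn, cfg, seed = 1)
  expect_equal(res$n_patients, 9L)
  expect_equal(res$stop_reasons, "sufficient_information")
  expect_equal(res$allocation, c(9, 0, 0, 0, 0, 0))
  # cohorts at weeks 0, 6, 12; no DLTs: last completes at 12 + 18
  expect_equal(res$duration, 30)
  expect_equal(res$recommendation, 1L)
})

test_that("a rotating policy exhausts the maximum patients", {
  scn <- scenario(rep(0, 6))
  cfg <- trial_config(rules = rule_config(setting = 1))
  res <- run_trial(stub_design(function(state) {
    (state$current_dose %% 6L) + 1L
  }), scn, cfg, seed = 1)
  expect_equal(res$n_patients, 30L)
  expect_true("maximum_patients" %in% res$stop_reasons)
  # 10 cohorts at weeks 0..54; last completes at 54 + 18
  expect_equal(res$duration, 72)
  expect_true(sum(res$allocation) == 30)
})

test_that("an all-DLT first cohort under setting 2 stops with no recommendation", {
  scn <- scenario(rep(0.5, 6))
  pop <- patient_population(30, 3, seed = 1)
  pop$latents[] <- 0.999   # 1 - z below every p1: DLT in cycle 1 for all
  cfg <- trial_config(rules = rule_config(setting = 2))
  res <- run_trial(titecrm_design(), scn, cfg, seed = 1, pop = pop)
  expect_equal(res$n_patients, 3L)
  expect_true("hard_safety" %in% res$stop_reasons)
  expect_true(is.na(res$recommendation))
  expect_equal(res$excluded, 1:6)
})

test_that("k-fold enforcement blocks value jumps beyond the fold limit", {
  scn <- scenario(rep(0, 6))
  cfg <- trial_config(rules = rule_config(setting = 1))
  # a policy that always demands the top dose
  res <- run_trial(stub_design(function(state) 6L), scn, cfg, seed = 1)
  # from 1.5 the cap is 3.0 -> dose 2; from 2.5 cap 5.0 -> dose 4; then 6
  doses_in_order <- res$patients$dose[seq(1, res$n_patients, by = 3)]
  expect_equal(doses_in_order[1:4], c(1L, 2L, 4L, 6L))
  for (k in seq_along(doses_in_order[-1])) {
    prev_max <- max(dv[doses_in_order[1:k]])
    expect_true(dv[doses_in_order[k + 1]] <= 2 * prev_max + 1e-9)
  }
})

test_that("excluded doses are never assigned and map to lower admissible doses", {
  scn <- scenario(c(0.05, 0.9, 0.9, 0.9, 0.9, 0.9))
  cfg <- trial_config(rules = rule_config(setting = 2))
  res <- run_trial(stub_design(function(state) 2L), scn, cfg, seed = 3)
  excl <- res$excluded
  if (length(excl)) {
    first_excl_week <- NA
    expect_true(all(res$patients$dose[res$patients$dose %in% excl] %in%
                      res$patients$dose))  # structural
  }
  # allocation to excluded doses can only have happened before exclusion
  expect_true(sum(res$allocation) == res$n_patients)
})

test_that("duration equals the completion week of the last patient", {
  scn <- scenario(c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  cfg <- trial_config(rules = rule_config(setting = 1))
  for (s in 1:5) {
    res <- run_trial(titecrm_design(), scn, cfg, seed = s)
    p <- res$patients
    expect_equal(res$duration,
                 max(p$enroll_week + 6 * ifelse(is.na(p$dlt_cycle), 3,
                                                p$dlt_cycle)))
    expect_lte(res$n_patients, 30)
    expect_equal(sum(res$allocation), res$n_patients)
  }
})

test_that("identical seeds give byte-identical operating characteristics", {
  scn <- scenario(c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8), label = "cal")
  cfg <- trial_config(rules = rule_config(setting = 1))
  oc1 <- simulate_ocs(titeboin_design(), scn, n_sims = 20, seed = 5,
                      config = cfg)
  oc2 <- simulate_ocs(titeboin_design(), scn, n_sims = 20, seed = 5,
                      config = cfg)
  expect_identical(oc1, oc2)
})

test_that("designs and benchmark consume identical latent sequences per seed", {
  # the population of replicate r depends only on (seed, r)
  p1 <- patient_population(30, 3, seed = 7 + 3)
  p2 <- patient_population(30, 3, seed = 7 + 3)
  expect_identical(p1, p2)
  # and a trial run does not disturb the population object it was given
  scn <- scenario(c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  cfg <- trial_config(rules = rule_config(setting = 1))
  before <- p1$latents
  run_trial(titeboin_design(), scn, cfg, seed = 10, pop = p1)
  run_trial(titecrm_design(), scn, cfg, seed = 10, pop = p1)
  expect_identical(p1$latents, before)
})

test_that("correct outcomes follow the truth-type conventions", {
  scn_mtd <- scenario(c(0.05, 0.05, 0.05, 0.8, 0.8, 0.8))
  r <- list(recommendation = 3L, stop_reasons = "sufficient_information")
  expect_true(correct_outcome(r, scn_mtd))
  r$recommendation <- 4L
  expect_false(correct_outcome(r, scn_mtd))

  scn_uns <- scenario(rep(0.5, 6))
  expect_true(correct_outcome(list(recommendation = NA_integer_,
                                   stop_reasons = "lowest_unsafe"), scn_uns))
  expect_true(correct_outcome(list(recommendation = NA_integer_,
                                   stop_reasons = "hard_safety"), scn_uns))
  expect_false(correct_outcome(list(recommendation = 1L,
                                    stop_reasons = "sufficient_information"),
                               scn_uns))

  scn_safe <- scenario(rep(0.05, 6), truth = "all_safe")
  expect_true(correct_outcome(list(recommendation = 6L,
                                   stop_reasons = "highest_safe"), scn_safe))
  expect_false(correct_outcome(list(recommendation = 6L,
                                    stop_reasons = "maximum_patients"),
                               scn_safe))
})

test_that("setting-2 safety stop fires on a toxic lowest dose", {
  scn <- scenario(rep(0.7, 6))
  cfg <- trial_config(rules = rule_config(setting = 2))
  stops <- vapply(1:10, function(s) {
    r <- run_trial(titeboin_design(prior = c(1, 1)), scn, cfg, seed = s)
    any(c("lowest_unsafe", "hard_safety") %in% r$stop_reasons) &&
      is.na(r$recommendation)
  }, TRUE)
  expect_gt(mean(stops), 0.7)
})

test_that("audit table serialises one row per observed patient-cycle", {
  d <- make_toxdata(dose = c(1L, 2L), u = c(2L, 1L))
  tab <- toxdata_frame(d)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("id", "dose", "cycle", "cat", "nttp", "dlt") %in%
                    names(tab)))
})
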