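test_that("BOIN boundaries match the printed calibrated values", {
  th <- boin_thresholds(0.391, 0.3128, 0.5083)
  expect_equal(round(unname(th["lambda_d"]), 4), 0.4492)
  # the printed lambda_e is the rounded value of the closed form; the
  # residual against the 4-dp print is below 5e-5
  expect_lt(abs(th["lambda_e"] - 0.3512), 5e-5)
  # frozen high-precision values computed symbolically before the build
  th2 <- boin_thresholds(0.3, 0.18, 0.42)
  expect_equal(unname(th2["lambda_e"]), 0.2364906852364680, tolerance = 1e-12)
  expect_equal(unname(th2["lambda_d"]), 0.3585194646409298, tolerance = 1e-12)
  # ordering property over random valid intervals
  set.seed(3)
  for (k in 1:50) {
    tau <- runif(1, 0.1, 0.5)
    t1 <- runif(1, 0.02, tau - 0.02)
    t2 <- runif(1, tau + 0.02, 0.95)
    th <- boin_thresholds(tau, t1, t2)
    expect_true(t1 < th["lambda_e"] && th["lambda_e"] < tau)
    expect_true(tau < th["lambda_d"] && th["lambda_d"] < t2)
  }
  expect_error(boin_thresholds(0.3, 0.4, 0.5))
})

th_ref <- boin_thresholds(0.391, 0.3128, 0.5083)

test_that("TITE-BOIN reduces to complete-data BOIN without pending patients", {
  sm <- function(n, m, pending = 0, stft = 0, consec = n)
    list(n = n, dlt = m, pending = pending, stft = stft,
         complete = n - m - pending, consec = consec)
  expect_equal(titeboin_decision(sm(3, 0), th_ref), "escalate")
  expect_equal(titeboin_decision(sm(3, 3), th_ref), "deescalate")
  # exhaustive zero-pending check against the plain boundary rule
  for (n in 1:12) for (m in 0:n) {
    rate <- m / n
    want <- if (rate >= th_ref["lambda_d"]) "deescalate"
            else if (rate <= th_ref["lambda_e"]) "escalate" else "stay"
    expect_equal(titeboin_decision(sm(n, m), th_ref), want)
  }
  expect_error(titeboin_decision(sm(0, 0), th_ref))
})

test_that("TITE-BOIN pending rules: DLT override, suspension, imputed rate", {
  sm <- function(n, m, pending, stft)
    list(n = n, dlt = m, pending = pending, stft = stft,
         complete = n - m - pending, consec = n)
  # observed DLTs alone can force de-escalation whatever is pending
  expect_equal(titeboin_decision(sm(6, 3, 3, 1), th_ref), "deescalate")
  # more than half pending suspends accrual (hand-traced fixture)
  expect_equal(titeboin_decision(sm(3, 0, 2, 2 / 3), th_ref), "suspend")
  # at half pending the imputed rate decides: 0 DLT in (1 + 1) effective
  expect_equal(titeboin_decision(sm(4, 0, 2, 1), th_ref), "escalate")
  # imputed rate 1/(1 + 1 + 1/3) = 0.43 sits between the boundaries
  expect_equal(titeboin_decision(sm(3, 1, 1, 1 / 3), th_ref), "stay")
})

test_that("effective counts weight pending patients by follow-up fraction", {
  sm <- list(n = 4, dlt = 1, pending = 1, stft = 1 / 3, complete = 2,
             consec = 4)
  eff <- keyboard_effective_counts(sm)
  expect_equal(eff$n_eff, 1 + 2 + 1 / 3)
  expect_equal(eff$events, 1)
  # all complete: effective equals observed
  smc <- list(n = 5, dlt = 2, pending = 0, stft = 0, complete = 3,
              consec = 5)
  expect_equal(keyboard_effective_counts(smc), list(n_eff = 5, events = 2))
})

test_that("keyboard decisions follow the strongest-key rule", {
  t1 <- 0.3519; t2 <- 0.5474
  expect_equal(keyboard_decision(3, 0, c(1, 1), t1, t2),
               oracle_keyboard(3, 0, c(1, 1), t1, t2))
  expect_equal(keyboard_decision(3, 0, c(1, 1), t1, t2), "escalate")
  expect_equal(keyboard_decision(3, 3, c(1, 1), t1, t2), "deescalate")
  # symmetric posterior centered in the target key stays
  mid <- (t1 + t2) / 2
  expect_equal(keyboard_decision(40, 40 * mid, c(1, 1), t1, t2), "stay")
  # agreement with the independent enumeration oracle over a grid
  for (n in c(1, 2.5, 3, 6, 9.5, 12)) for (ev in seq(0, floor(n))) {
    expect_equal(keyboard_decision(n, ev, c(1, 1), t1, t2),
                 oracle_keyboard(n, ev, c(1, 1), t1, t2))
  }
  expect_error(keyboard_decision(0, 0, c(1, 1), t1, t2))
})

test_that("keys tile the unit interval outward from the target key", {
  k <- keyboard_keys(0.3519, 0.5474)
  expect_equal(k[1], 0)
  expect_equal(k[length(k)], 1)
  expect_true(all(diff(k) > 0))
  tk <- attr(k, "target")
  expect_equal(k[tk], 0.3519)
  expect_equal(k[tk + 1], 0.5474)
  # interior keys all share the target width
  wid <- diff(k)
  if (length(wid) > 2)
    expect_true(all(abs(wid[2:(length(wid) - 1)] - (0.5474 - 0.3519)) < 1e-9))
})

test_that("rolling keyboard cascade: reduction, agreement, consecutive rule", {
  t1 <- 0.3519; t2 <- 0.5474
  sm <- function(n, m, pending, stft = 0, consec = n)
    list(n = n, dlt = m, pending = pending, stft = stft,
         complete = n - m - pending, consec = consec)
  # no pending: identical to the non-rolling keyboard decision
  for (n in 1:12) for (m in 0:n) {
    expect_equal(rmtpi2_decision(sm(n, m, 0), c(1, 1), t1, t2),
                 keyboard_decision(n, m, c(1, 1), t1, t2))
  }
  # best and worst case agree -> that move (0 DLT, 1 pending of 7)
  expect_equal(rmtpi2_decision(sm(7, 0, 1), c(1, 1), t1, t2), "escalate")
  # 0/3 complete + 3 pending: the worst-case imputation 3/6 (a Beta(4, 4)
  # posterior centered in the target key -> stay) disagrees with the
  # best case (escalate), so the consecutive-assignment rule decides
  expect_equal(keyboard_decision(6, 0, c(1, 1), t1, t2), "escalate")
  expect_equal(keyboard_decision(6, 3, c(1, 1), t1, t2), "stay")
  expect_equal(rmtpi2_decision(sm(6, 0, 3, consec = 3), c(1, 1), t1, t2),
               "stay")
  expect_equal(rmtpi2_decision(sm(6, 0, 3, consec = 6), c(1, 1), t1, t2),
               "suspend")
})

test_that("adding a DLT never relaxes an interval decision", {
  rank <- c(escalate = 1, stay = 2, deescalate = 3, suspend = 2)
  t1 <- 0.3519; t2 <- 0.5474
  for (n in 2:10) for (m in 0:(n - 1)) {
    expect_gte(rank[keyboard_decision(n, m + 1, c(1, 1), t1, t2)],
               rank[keyboard_decision(n, m, c(1, 1), t1, t2)])
    smA <- list(n = n, dlt = m, pending = 0, stft = 0,
                complete = n - m, consec = n)
    smB <- list(n = n, dlt = m + 1, pending = 0, stft = 0,
                complete = n - m - 1, consec = n)
    expect_gte(rank[titeboin_decision(smB, th_ref)],
               rank[titeboin_decision(smA, th_ref)])
  }
})

test_that("decision tables are pure functions of the configuration", {
  des <- titeboin_design()
  t1 <- assisted_decision_table(des, n_max = 6)
  t2 <- assisted_decision_table(des, n_max = 6)
  expect_identical(t1, t2)
  expect_true(all(t1$move %in% c("escalate", "stay", "deescalate",
                                 "suspend")))
  km <- assisted_decision_table(titemtpi2_design(), n_max = 5)
  expect_identical(km, assisted_decision_table(titemtpi2_design(),
                                               n_max = 5))
})

test_that("PAVA equals brute-force monotone least squares", {
  # exhaustive over 3-dose instances on a 0.1 grid, equal weights
  grid <- seq(0, 1, by = 0.1)
  for (a in grid) for (b in grid) for (cc in grid) {
    y <- c(a, b, cc)
    expect_equal(pava(y), brute_monotone_ls(y, rep(1, 3)), tolerance = 1e-9)
  }
  # random 5-dose instances with unequal weights
  set.seed(17)
  for (k in 1:200) {
    y <- round(runif(5), 1)
    w <- sample(1:9, 5, replace = TRUE)
    expect_equal(pava(y, w), brute_monotone_ls(y, w), tolerance = 1e-9)
  }
  # classic pooled pair
  expect_equal(pava(c(0.5, 0.2)), c(0.35, 0.35))
})

test_that("isotonic MTD selection respects monotone rates and treated doses", {
  # monotone raw rates pass through PAVA unchanged; nearest to tau selected
  n <- c(3, 6, 9, 6); dlt <- c(0, 1, 3, 5)
  pick <- isotonic_mtd(n, dlt, c(1, 1), tau = 0.391)
  pm <- (1 + dlt) / (2 + n)
  expect_equal(pava(pm, n), pm)  # already monotone
  expect_equal(pick, which.min(abs(pm - 0.391)))
  # single treated dose
  expect_equal(isotonic_mtd(c(0, 3, 0), c(0, 1, 0), c(1, 1), 0.391), 2L)
  # no treated dose
  expect_true(is.na(isotonic_mtd(c(0, 0), c(0, 0), c(1, 1), 0.391)))
  # pooled under-target block: the highest pooled dose is preferred
  pick2 <- isotonic_mtd(c(3, 3, 9, 9), c(0, 0, 0, 8), c(0.1, 0.9),
                        tau = 0.391)
  expect_equal(pick2, 3L)
  # admissibility restriction
  expect_equal(isotonic_mtd(c(3, 3, 9, 9), c(0, 0, 0, 8), c(0.1, 0.9),
                            0.391, admissible = 1:2), 2L)
})
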