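test_that("with no data the nTTP posterior equals the prior", {
  prior <- list(mu_b0 = 0.1, var_b0 = 100, mu_b1 = 0.5, var_b1 = 100,
                mu_b2 = 0, var_b2 = 10)
  fit <- nttp_fit(NULL, prior, seed = 2)
  expect_equal(unname(fit$mean), c(0.1, 0.5, 0), tolerance = 1e-10)
  pm <- colMeans(fit$draws[, 1:3])
  expect_equal(unname(pm), c(0.1, 0.5, 0), tolerance = 0.7)  # MC error only
})

test_that("nTTP fit recovers linear-mixed-model parameters", {
  set.seed(8)
  x <- c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0) / 7
  b0t <- 0.05; b1t <- 0.3; b2t <- 0.02; sg <- 0.05; se <- 0.08
  n <- 300
  dose <- sample(1:6, n, replace = TRUE)
  g <- rnorm(n, 0, sg)
  cyc <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = i, dose = dose[i], dose_value = x[dose[i]], cycle = 1:3,
               max_grade = 0L, cat = 1L,
               nttp = b0t + b1t * x[dose[i]] + b2t * (1:3) + g[i] +
                 rnorm(3, 0, se),
               dlt = 0L)
  }))
  td <- structure(list(patients = data.frame(), cycles = cyc,
                       n_cycles = 3L), class = "toxdata")
  prior <- list(mu_b0 = 0.1, var_b0 = 100, mu_b1 = 0.5, var_b1 = 100,
                mu_b2 = 0, var_b2 = 10)
  fit <- nttp_fit(td, prior, seed = 2)
  pm <- colMeans(fit$draws)
  psd <- apply(fit$draws, 2, sd)
  for (nm in c("b0", "b1", "b2")) {
    true <- c(b0 = b0t, b1 = b1t, b2 = b2t)[nm]
    expect_lt(abs(pm[nm] - true), 3 * max(psd[nm], 1e-6))
  }
  # variance components recovered to the grid resolution
  expect_equal(unname(pm["sig_g"]), sg^2, tolerance = 0.6)
  expect_equal(unname(pm["sig_e"]), se^2, tolerance = 0.4)
})

test_that("interval coverage of the dose slope is adequate over replicates", {
  set.seed(44)
  x <- c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0) / 7
  prior <- list(mu_b0 = 0.1, var_b0 = 100, mu_b1 = 0.5, var_b1 = 100,
                mu_b2 = 0, var_b2 = 10)
  hits <- 0L
  reps <- 25L
  for (r in seq_len(reps)) {
    n <- 120
    dose <- sample(1:6, n, replace = TRUE)
    g <- rnorm(n, 0, 0.05)
    cyc <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(id = i, dose = dose[i], dose_value = x[dose[i]],
                 cycle = 1:3, max_grade = 0L, cat = 1L,
                 nttp = 0.05 + 0.3 * x[dose[i]] + 0.02 * (1:3) + g[i] +
                   rnorm(3, 0, 0.08),
                 dlt = 0L)
    }))
    td <- structure(list(patients = data.frame(), cycles = cyc,
                         n_cycles = 3L), class = "toxdata")
    fit <- nttp_fit(td, prior, seed = r)
    ci <- quantile(fit$draws[, "b1"], c(0.025, 0.975))
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * reps)
})

test_that("posterior slope mass shifts positive with monotone data", {
  x <- c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0) / 7
  cyc <- do.call(rbind, lapply(1:30, function(i) {
    j <- (i - 1) %% 6 + 1
    data.frame(id = i, dose = j, dose_value = x[j], cycle = 1:3,
               max_grade = 0L, cat = 1L,
               nttp = 0.05 + 0.4 * x[j] + rnorm(3, 0, 0.05), dlt = 0L)
  }))
  set.seed(2)
  td <- structure(list(patients = data.frame(), cycles = cyc,
                       n_cycles = 3L), class = "toxdata")
  fit <- nttp_fit(td, list(mu_b0 = 0, var_b0 = 100, mu_b1 = 0,
                           var_b1 = 100, mu_b2 = 0, var_b2 = 10), seed = 3)
  expect_gt(mean(fit$draws[, "b1"] > 0), 0.95)
})

test_that("nTTP dose selection brackets the target expected toxicity", {
  fit <- list(mean = c(b0 = 0, b1 = 1, b2 = 0))
  xv <- c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30)
  # distances at 0.18: 0.03 (0.15) vs 0.02 (0.20) -> the dose with 0.20
  expect_equal(nttp_next_dose(fit, xv, 0.18), 4L)
  expect_equal(nttp_next_dose(fit, xv, 0.15), 3L)  # exact hit
  expect_equal(nttp_next_dose(fit, xv, 0.175), 3L) # tie -> lower dose
  expect_equal(nttp_next_dose(fit, xv, 0.18, admissible = 1:2), 2L)
  expect_equal(nttp_next_dose(fit, xv, 0.18, admissible = integer(0)),
               NA_integer_)
})

test_that("the default nTTP target is the expected value at the cycle-1 target", {
  tgt <- tau_nttp_default()
  expect_equal(tgt, expected_cycle1_nttp(0.3))
  expect_gt(tgt, 0); expect_lt(tgt, 1)
  # monotone in the underlying DLT probability
  expect_lt(expected_cycle1_nttp(0.1), expected_cycle1_nttp(0.5))
})
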