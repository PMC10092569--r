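test_that("cumulative DLT probability follows the decaying-hazard recursion", {
  expect_equal(round(cumulative_dlt_prob(0.3, 3), 3), 0.391)
  expect_equal(cumulative_dlt_prob(0, 3), 0)
  expect_equal(cumulative_dlt_prob(0.2, 2), 0.2 + 0.8 * 0.2 / 3)
  expect_equal(cumulative_dlt_prob(0.3, 1), 0.3)
  # closed form printed for three cycles
  p1 <- seq(0, 1, by = 0.05)
  expect_equal(cumulative_dlt_prob(p1, 3),
               p1 + (1 - p1) * p1 / 3 + (1 - p1) * (1 - p1 / 3) * p1 / 9)
  # non-decreasing in s, bounded by 1
  for (p in c(0.1, 0.5, 0.9)) {
    ps <- sapply(1:5, function(s) cumulative_dlt_prob(p, s))
    expect_true(all(diff(ps) >= 0))
    expect_true(all(ps <= 1))
  }
  expect_error(cumulative_dlt_prob(1.2, 2), "p1")
})

test_that("cycle-1 grade distribution matches the piecewise masses", {
  expect_equal(unname(grade_distribution(0.3)),
               c(0.25, 0.15, 0.30, 0.15, 0.15))
  expect_equal(unname(grade_distribution(0.6)), c(0, 0, 0.4, 0.3, 0.3))
  expect_equal(unname(grade_distribution(0.4)), c(0, 0.2, 0.4, 0.2, 0.2))
  expect_error(grade_distribution(-0.1))
  # conservation and DLT-consistency over a fine sweep of p1
  for (p in seq(0, 1, by = 0.01)) {
    g <- grade_distribution(p)
    expect_equal(sum(g), 1)
    expect_equal(unname(g["g3"] + g["g4"]), p)
    expect_true(all(g >= 0))
  }
})

test_that("later-cycle grade masses scale by the survivor fraction", {
  g1 <- grade_distribution(0.3)
  expect_equal(later_grade_masses(0.3, 2), 0.7 * g1)
  expect_equal(later_grade_masses(0, 2), grade_distribution(0))
  p2 <- cumulative_dlt_prob(0.3, 2)
  expect_equal(later_grade_masses(0.3, 3), (1 - p2) * g1)
  expect_equal(sum(later_grade_masses(0.3, 2)), 1 - 0.3)
  expect_error(later_grade_masses(0.3, 1))
})

test_that("grade/type combination space partitions the 125 triples", {
  cmb <- grade_combinations()
  expect_equal(vapply(cmb, nrow, 0L), c(1L, 7L, 19L, 37L, 61L))
  expect_equal(sum(vapply(cmb, nrow, 0L)), 125L)
  expect_equal(vapply(cmb, nrow, 0L),
               as.integer((1:5)^3 - (0:4)^3))
  for (g in 0:4) {
    expect_true(all(apply(cmb[[g + 1]], 1, max) == g))
  }
})

test_that("latent variable maps to a unique DLT cycle via half-open intervals", {
  ps <- c(0.3, 0.37, 0.391)
  expect_equal(dlt_cycle(0.9, ps), 1L)
  expect_true(is.na(dlt_cycle(0.5, ps)))
  expect_equal(dlt_cycle(0.65, ps), 2L)
  # boundary is deterministic: 1 - z exactly at p_s belongs to cycle s
  # (binary-exact boundaries)
  ps2 <- c(0.25, 0.5, 0.75)
  expect_equal(dlt_cycle(1 - 0.25, ps2), 1L)
  expect_equal(dlt_cycle(1 - 0.5, ps2), 2L)
  expect_equal(dlt_cycle(1 - 0.75, ps2), 3L)
  # monotone: smaller latent never yields a later DLT cycle, so the
  # cycle (with none coded high) is non-increasing in the latent
  zs <- seq(0.01, 0.99, by = 0.01)
  cyc <- vapply(zs, function(z) {
    s <- dlt_cycle(z, ps); if (is.na(s)) 99L else s
  }, 0L)
  expect_true(all(diff(cyc) <= 0))
})

test_that("DLT-cycle frequencies match the interval widths", {
  set.seed(401)
  ps <- sapply(1:3, function(s) cumulative_dlt_prob(0.3, s))
  n <- 2e5
  z <- runif(n)
  cyc <- vapply(z, dlt_cycle, 0L, ps = ps)
  probs <- c(ps[1], diff(ps))
  for (s in 1:3) {
    obs <- sum(cyc == s, na.rm = TRUE) / n
    se <- sqrt(probs[s] * (1 - probs[s]) / n)
    expect_lt(abs(obs - probs[s]), 3 * se)
  }
})

test_that("patient outcomes are internally consistent", {
  scn <- scenario(c(0.1, 0.3, 0.5, 0.6, 0.7, 0.8))
  pop <- patient_population(40, 3, seed = 11)
  for (i in seq_len(40)) {
    for (j in c(1L, 3L, 6L)) {
      out <- patient_outcome(pop, i, scn, j)
      S <- 3
      if (!is.na(out$dlt_cycle)) {
        expect_equal(out$cycles_on_study, out$dlt_cycle)
        expect_gte(out$max_grade[out$dlt_cycle], 3)
        if (out$dlt_cycle < S)
          expect_true(all(is.na(out$max_grade[(out$dlt_cycle + 1):S])))
      } else {
        expect_equal(out$cycles_on_study, S)
      }
      obs <- seq_len(out$cycles_on_study)
      # DLT in cycle s <=> max grade >= 3
      is_dlt <- !is.na(out$dlt_cycle) & obs == out$dlt_cycle
      expect_equal(out$max_grade[obs] >= 3, is_dlt)
      # triple max equals the drawn maximum grade; nTTP zero iff all-zero
      for (s in obs) {
        expect_equal(max(out$grades[s, ]), out$max_grade[s])
        expect_equal(out$nttp[s] == 0, all(out$grades[s, ] == 0))
      }
    }
  }
})

test_that("shared latents couple outcomes monotonically across doses", {
  scn <- scenario(c(0.1, 0.3, 0.5, 0.6, 0.7, 0.8))
  pop <- patient_population(60, 3, seed = 21)
  for (i in seq_len(60)) {
    cyc <- vapply(1:6, function(j) {
      s <- patient_outcome(pop, i, scn, j)$dlt_cycle
      if (is.na(s)) 99L else s
    }, 0L)
    # higher dose: DLT never later
    expect_true(all(diff(cyc) <= 0))
  }
})

test_that("nTTP values are normalized, monotone and reproduce a hand-computed case", {
  w <- nttp_weights_default()
  expect_equal(nttp_value(c(0, 0, 0), w), 0)
  expect_equal(nttp_value(c(4, 4, 4), w), 1)
  # hand evaluation: grades (3,2,0) -> sqrt(1^2 + 0.75^2) / (1.5 sqrt 3)
  expect_equal(nttp_value(c(3, 2, 0), w), 1.25 / (1.5 * sqrt(3)))
  # monotone in each coordinate
  set.seed(5)
  for (k in 1:50) {
    a <- sample(0:4, 3, replace = TRUE)
    b <- pmin(a + sample(0:2, 3, replace = TRUE), 4)
    expect_lte(nttp_value(a, w), nttp_value(b, w) + 1e-12)
  }
  expect_error(nttp_value(c(0, 0, 0), NULL), "weight")
})

test_that("scenario files round-trip through the key-value format", {
  scn <- scenario(c(0.05, 0.05, 0.05, 0.8, 0.8, 0.8), label = "D")
  f <- tempfile(fileext = ".txt")
  write_scenario(scn, f)
  back <- read_scenario(f)
  expect_equal(back$p1, scn$p1)
  expect_equal(back$dose_values, scn$dose_values)
  expect_equal(back$truth, scn$truth)
  expect_equal(back$ps, scn$ps)
  unlink(f)
})

test_that("scenario truth labelling follows the highest-dose-at-or-below-target rule", {
  scn <- scenario(c(0.05, 0.05, 0.05, 0.8, 0.8, 0.8))
  expect_equal(scn$truth, list(type = "mtd", mtd = 3L))
  expect_equal(scenario(rep(0.4, 6))$truth$type, "all_unsafe")
  expect_equal(scenario(rep(0.05, 6), truth = "all_safe")$truth$type,
               "all_safe")
  expect_error(scenario(rep(0.5, 3), dose_values = c(3, 2, 1)))
})
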