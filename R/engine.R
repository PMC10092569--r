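#' Trial configuration
#'
#' @param cohort_size patients per cohort.
#' @param max_patients maximum trial size (a multiple of `cohort_size`).
#' @param cycle_weeks length of one treatment cycle in weeks.
#' @param rules a [rule_config()].
#' @param duration_residual if `TRUE` (default) the trial duration counts
#'   the residual follow-up of already-enrolled patients after enrollment
#'   stops; if `FALSE` the clock stops at the stopping decision.
#' @param nttp_weights,nttp_normalizer nTTP weight configuration used when
#'   generating patient outcomes.
#' @return list of class `"trial_config"`.
#' @export
trial_config <- function(cohort_size = 3L, max_patients = 30L,
                         cycle_weeks = 6, rules = rule_config(),
                         duration_residual = TRUE,
                         nttp_weights = NULL, nttp_normalizer = NULL) {
  if (max_patients %% cohort_size != 0)
    stop("'max_patients' must be divisible by 'cohort_size'")
  structure(list(cohort_size = as.integer(cohort_size),
                 max_patients = as.integer(max_patients),
                 cycle_weeks = cycle_weeks, rules = rules,
                 duration_residual = duration_residual,
                 nttp_weights = nttp_weights,
                 nttp_normalizer = nttp_normalizer),
            class = "trial_config")
}

# admissible doses: not excluded, and within the k-fold rise limit of the
# highest dose value experimented so far
admissible_doses <- function(J, excluded, dose_values, highest_tried, kfold) {
  adm <- setdiff(seq_len(J), excluded)
  adm[k_fold_check(dose_values[adm], highest_tried, kfold)]
}

#' Simulate one dose-finding trial with rolling enrollment
#'
#' Cohorts enroll at successive cycle boundaries.  At each boundary the
#' design sees exactly the data observable at that calendar time, proposes
#' a dose (or suspends accrual for one cycle), the engine enforces the
#' exclusion and k-fold rules (an inadmissible proposal is mapped to the
#' nearest admissible lower dose), the active stopping rules are
#' evaluated, and — if the trial goes on — the next cohort enrolls at the
#' chosen dose.  A stopped trial no longer enrolls, but already-enrolled
#' patients complete their follow-up before the design's final-selection
#' rule is applied to the complete data.  The sufficient-information rule
#' stops the trial when the dose about to be assigned already carries
#' `sufficient_n` treated patients.
#'
#' @param design a `latetox_design` object.
#' @param scn a [scenario()].
#' @param config a [trial_config()]; its `rules` decide the setting.
#' @param seed integer seed (drives the patient population and any
#'   design-internal sampling).
#' @param pop optional pre-drawn [patient_population()] (shared across
#'   designs for benchmark comparability); defaults to
#'   `patient_population(config$max_patients, scn$n_cycles, seed)`.
#' @return object of class `"trial_result"`.
#' @export
run_trial <- function(design, scn, config = trial_config(), seed = 1L,
                      pop = NULL) {
  J <- length(scn$dose_values)
  S <- scn$n_cycles
  cw <- config$cycle_weeks
  rules <- config$rules
  setting2 <- rules$setting == 2
  if (is.null(pop)) pop <- patient_population(config$max_patients, S, seed)
  wts <- if (is.null(config$nttp_weights)) nttp_weights_default() else config$nttp_weights

  enrolled <- data.frame(id = integer(), dose = integer(),
                         dose_value = numeric(), enroll_week = numeric(),
                         dlt_cycle = integer())
  outcomes <- list()
  enroll <- function(dose, week) {
    n0 <- nrow(enrolled)
    ids <- seq.int(n0 + 1L, min(n0 + config$cohort_size, config$max_patients))
    for (i in ids) {
      out <- patient_outcome(pop, i, scn, dose, wts, config$nttp_normalizer)
      outcomes[[i]] <<- out
      enrolled[nrow(enrolled) + 1L, ] <<-
        list(i, dose, scn$dose_values[dose], week,
             if (is.na(out$dlt_cycle)) NA_integer_ else out$dlt_cycle)
    }
    length(ids)
  }

  excluded <- integer(0)
  stop_reasons <- character(0)
  no_recommendation <- FALSE
  suspensions <- 0L
  current_dose <- 1L
  consec <- 0L
  log <- list()
  log_row <- function(week, proposed, assigned, suspended, fired) {
    log[[length(log) + 1L]] <<-
      data.frame(week = week,
                 proposed = if (is.null(proposed)) NA_integer_ else proposed,
                 assigned = if (is.null(assigned)) NA_integer_ else assigned,
                 suspended = suspended,
                 rules_fired = paste(fired, collapse = ";"))
  }

  enroll(1L, 0)
  consec <- config$cohort_size
  stop_week <- NA_real_
  k <- 1L
  enrollment_open <- TRUE

  while (enrollment_open && k <= 200L) {
    week <- cw * k
    data <- observable_dataset(enrolled, outcomes, week, S, cw)
    interim_seed <- (seed + 7907L * k) %% 2147483000L

    if (setting2) {
      excluded <- union(excluded,
                        apply_hard_safety(cycle1_counts(data, J), rules))
      if (1L %in% excluded) {
        stop_reasons <- c(stop_reasons, "hard_safety")
        no_recommendation <- TRUE
        enrollment_open <- FALSE
        stop_week <- week
        break
      }
    }

    state <- list(current_dose = current_dose,
                  any_dlt = any(data$patients$dlt == 1L),
                  dose_values = scn$dose_values, n_cycles = S,
                  n_enrolled = nrow(enrolled), consec = consec)
    dec <- decide_dose(design, data, state, seed = interim_seed)
    if (isTRUE(dec$suspend)) {
      suspensions <- suspensions + 1L
      log_row(week, dec$dose, NA_integer_, TRUE, character(0))
      k <- k + 1L
      next
    }
    dose <- dec$dose

    highest_tried <- max(enrolled$dose_value)
    adm <- admissible_doses(J, excluded, scn$dose_values, highest_tried,
                            rules$kfold)
    if (length(adm) == 0L) {
      stop_reasons <- c(stop_reasons, "no_admissible_dose")
      no_recommendation <- TRUE
      enrollment_open <- FALSE
      stop_week <- week
      break
    }
    if (!(dose %in% adm)) {
      lower <- adm[adm <= dose]
      dose <- if (length(lower)) max(lower) else min(adm)
    }

    fired <- character(0)
    n_at <- sum(enrolled$dose == dose)
    if (sufficient_information_stop(n_at, rules))
      fired <- c(fired, "sufficient_information")

    if (setting2) {
      set.seed((interim_seed + 13L) %% 2147483000L)
      tail_prob <- function(dose_idx) {
        if (!is.null(dec$cycle1_tail))
          dec$cycle1_tail(dose_idx, rules$tau_cycle1)
        else cycle1_prob_for_rules(design, data, dose_idx, rules, scn,
                                   interim_seed)
      }
      if (sum(enrolled$dose == 1L) >= config$cohort_size) {
        p_unsafe <- tail_prob(1L)
        if (!is.na(p_unsafe) && p_unsafe > rules$unsafe_threshold) {
          fired <- c(fired, "lowest_unsafe")
          no_recommendation <- TRUE
        }
      }
      if (sum(enrolled$dose == J) >= config$cohort_size) {
        p_safe_tail <- tail_prob(J)
        if (!is.na(p_safe_tail) &&
            (1 - p_safe_tail) > rules$safe_threshold) {
          fired <- c(fired, "highest_safe")
        }
      }
      draws <- if (!is.null(dec$mtd_draws)) dec$mtd_draws
               else mtd_draws(design, data, scn$dose_values,
                              seed = (interim_seed + 29L) %% 2147483000L)
      ps <- precision_stop(draws, sum(data$patients$u >= 1L), rules)
      if (ps$stop) fired <- c(fired, "precision")
    }

    log_row(week, dec$dose, dose, FALSE, fired)
    if (length(fired)) {
      stop_reasons <- c(stop_reasons, fired)
      enrollment_open <- FALSE
      stop_week <- week
      break
    }

    enroll(dose, week)
    consec <- if (dose == current_dose) consec + config$cohort_size
              else config$cohort_size
    current_dose <- dose
    if (nrow(enrolled) >= config$max_patients) {
      stop_reasons <- c(stop_reasons, "maximum_patients")
      enrollment_open <- FALSE
      stop_week <- week + cw  # decision slot where further accrual would occur
    }
    k <- k + 1L
  }

  # complete follow-up for everyone already enrolled
  followup_end <- max(enrolled$enroll_week +
                        cw * ifelse(is.na(enrolled$dlt_cycle), S,
                                    enrolled$dlt_cycle))
  full <- observable_dataset(enrolled, outcomes, followup_end + cw, S, cw)

  if (setting2 && !no_recommendation) {
    excluded <- union(excluded, apply_hard_safety(cycle1_counts(full, J),
                                                  rules))
    if (1L %in% excluded) {
      stop_reasons <- c(stop_reasons, "hard_safety")
      no_recommendation <- TRUE
    }
  }

  recommendation <- NA_integer_
  if (!no_recommendation) {
    adm_final <- setdiff(seq_len(J), excluded)
    recommendation <- final_mtd(design, full, adm_final,
                                dose_values = scn$dose_values,
                                seed = (seed + 999983L) %% 2147483000L)
  }

  duration <- if (config$duration_residual) followup_end
              else min(followup_end, stop_week, na.rm = TRUE)
  alloc <- tabulate(enrolled$dose, nbins = J)
  structure(list(recommendation = recommendation,
                 n_patients = nrow(enrolled),
                 duration = duration,
                 allocation = alloc,
                 stop_reasons = unique(stop_reasons),
                 excluded = sort(excluded),
                 suspensions = suspensions,
                 n_dlt = sum(!is.na(enrolled$dlt_cycle)),
                 patients = enrolled,
                 decisions = do.call(rbind, c(log, list(
                   make.row.names = FALSE))),
                 seed = seed),
            class = "trial_result")
}

# posterior safety model for stopping rules 2 and 3: the design's own
# one-cycle model, or the Beta-binomial model when configured (always used
# for the model-assisted designs and the nTTP design, whose endpoints have
# no design-specific cycle-1 DLT model)
cycle1_prob_for_rules <- function(design, data, dose, rules, scn,
                                  interim_seed) {
  if (identical(rules$safety_model, "betabinom") ||
      inherits(design, "assisted_design") ||
      inherits(design, "nttp_design")) {
    cnt <- cycle1_counts(data, length(scn$dose_values))
    if (cnt$n[dose] == 0) return(NA_real_)
    return(beta_tail_prob(cnt$n[dose], cnt$dlt[dose], rules$tau_cycle1,
                          rules$safety_prior))
  }
  cycle1_prob(design, data, dose, rules$tau_cycle1,
              dose_values = scn$dose_values,
              seed = (interim_seed + 17L) %% 2147483000L)
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Trial result: ",
      if (is.na(x$recommendation)) "no dose recommended"
      else paste("recommended dose", x$recommendation), "\n", sep = "")
  cat("  patients:", x$n_patients, " duration:", x$duration, "weeks ",
      " DLTs:", x$n_dlt, "\n")
  cat("  allocation:", paste(x$allocation, collapse = "/"), "\n")
  if (length(x$stop_reasons))
    cat("  stopped for:", paste(x$stop_reasons, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.trial_result <- function(object, ...) {
  cat("Interim decisions (one row per decision boundary):\n")
  print(object$decisions)
  invisible(object$decisions)
}

#' Was the trial outcome correct for its scenario?
#'
#' A trial is correct when it recommends the scenario's true MTD; in an
#' all-unsafe scenario, when it stops for safety (posterior lowest-dose
#' rule or hard safety) without recommending a dose; in an all-safe
#' scenario, when it stops because the highest dose is deemed very safe.
#'
#' @param result a `"trial_result"`.
#' @param scn the [scenario()] that generated it (must carry a truth
#'   label).
#' @return logical.
#' @export
correct_outcome <- function(result, scn) {
  truth <- scn$truth
  if (is.null(truth)) stop("scenario has no truth label")
  switch(truth$type,
    mtd = !is.na(result$recommendation) &&
      result$recommendation == truth$mtd,
    all_unsafe = is.na(result$recommendation) &&
      any(c("lowest_unsafe", "hard_safety") %in% result$stop_reasons),
    all_safe = "highest_safe" %in% result$stop_reasons,
    stop("unknown truth type"))
}

#' Operating characteristics over simulated replicates
#'
#' Runs `n_sims` independent trials.  Replicate `r` draws its patient
#' population from seed `seed + r`, so different designs evaluated with
#' the same `seed` see identical sequences of patients with identical
#' latent toxicity variables (and the empirical benchmark can reuse them).
#'
#' @param design a `latetox_design`.
#' @param scn a [scenario()].
#' @param n_sims number of replicates.
#' @param seed base seed.
#' @param config a [trial_config()].
#' @return object of class `"trial_ocs"`: proportion of correct
#'   selections, trial-size and duration summaries, mean allocation,
#'   recommendation distribution and stopping-reason percentages.
#' @export
simulate_ocs <- function(design, scn, n_sims = 1000L, seed = 1L,
                         config = trial_config()) {
  J <- length(scn$dose_values)
  res <- vector("list", n_sims)
  for (r in seq_len(n_sims)) {
    pop <- patient_population(config$max_patients, scn$n_cycles, seed + r)
    res[[r]] <- run_trial(design, scn, config,
                          seed = (seed + 104729L * r) %% 2147483000L,
                          pop = pop)
  }
  summarize_ocs(res, scn, design$name, n_sims, seed)
}

summarize_ocs <- function(res, scn, design_name, n_sims, seed) {
  J <- length(scn$dose_values)
  rec <- vapply(res, function(x) {
    if (is.na(x$recommendation)) 0L else x$recommendation
  }, 0L)
  npat <- vapply(res, function(x) x$n_patients, 0L)
  dur <- vapply(res, function(x) x$duration, 0)
  alloc <- t(vapply(res, function(x) x$allocation, numeric(J)))
  correct <- vapply(res, correct_outcome, TRUE, scn = scn)
  reasons <- sort(unique(unlist(lapply(res, function(x) x$stop_reasons))))
  reason_pct <- vapply(reasons, function(rr) {
    100 * mean(vapply(res, function(x) rr %in% x$stop_reasons, TRUE))
  }, 0)
  rec_dist <- vapply(0:J, function(j) 100 * mean(rec == j), 0)
  names(rec_dist) <- c("none", paste0("d", seq_len(J)))
  structure(list(design = design_name, scenario = scn$label,
                 n_sims = n_sims, seed = seed,
                 pcs = 100 * mean(correct),
                 mean_patients = mean(npat), sd_patients = stats::sd(npat),
                 mean_duration = mean(dur), sd_duration = stats::sd(dur),
                 mean_allocation = colMeans(alloc),
                 recommendation_pct = rec_dist,
                 stop_reason_pct = reason_pct),
            class = "trial_ocs")
}

#' @export
print.trial_ocs <- function(x, ...) {
  cat("Operating characteristics —", x$design,
      if (!is.null(x$scenario)) paste0("(", x$scenario, ")"),
      "over", x$n_sims, "simulations\n")
  cat(sprintf("  PCS: %.1f%%\n", x$pcs))
  cat(sprintf("  patients: %.1f (SD %.1f)   duration: %.1f weeks (SD %.1f)\n",
              x$mean_patients, x$sd_patients, x$mean_duration,
              x$sd_duration))
  cat("  mean allocation:",
      paste(sprintf("%.1f", x$mean_allocation), collapse = "/"), "\n")
  cat("  recommendations (%):",
      paste(names(x$recommendation_pct),
            sprintf("%.0f", x$recommendation_pct), sep = "=",
            collapse = " "), "\n")
  if (length(x$stop_reason_pct))
    cat("  stopping reasons (%):",
        paste(names(x$stop_reason_pct),
              sprintf("%.0f", x$stop_reason_pct), sep = "=",
              collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.trial_ocs <- function(object, ...) {
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
  invisible(df)
}

#' Flatten operating characteristics to a one-row-per-metric table
#'
#' @param x a `"trial_ocs"` object.
#' @param ... unused.
#' @return data.frame with columns `design`, `scenario`, `metric`,
#'   `value`, mirroring a per-metric results table layout.
#' @export
as.data.frame.trial_ocs <- function(x, ...) {
  vals <- c(pcs = x$pcs, mean_patients = x$mean_patients,
            sd_patients = x$sd_patients, mean_duration = x$mean_duration,
            sd_duration = x$sd_duration,
            stats::setNames(x$mean_allocation,
                            paste0("alloc_d", seq_along(x$mean_allocation))),
            stats::setNames(x$recommendation_pct,
                            paste0("rec_", names(x$recommendation_pct))),
            stats::setNames(x$stop_reason_pct,
                            paste0("stop_", names(x$stop_reason_pct))))
  data.frame(design = x$design,
             scenario = if (is.null(x$scenario)) NA_character_ else x$scenario,
             metric = names(vals), value = unname(vals),
             row.names = NULL)
}
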