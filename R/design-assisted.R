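#' Time-to-event Bayesian optimal interval design (TITE-BOIN)
#'
#' @param tau target DLT probability over the full follow-up period.
#' @param tau1,tau2 calibrated target-interval bounds.
#' @param prior per-dose Beta prior `c(alpha, beta)` (calibrated
#'   setting-1 default Beta(0.1, 0.9)).
#' @param pending_frac accrual-suspension threshold on the fraction of
#'   pending patients at the current dose.
#' @return a design object usable by [run_trial()].
#' @export
titeboin_design <- function(tau = 0.391, tau1 = 0.3128, tau2 = 0.5083,
                            prior = c(0.1, 0.9), pending_frac = 0.5) {
  structure(list(name = "titeboin", tau = tau, tau1 = tau1, tau2 = tau2,
                 prior = prior, pending_frac = pending_frac,
                 thresholds = boin_thresholds(tau, tau1, tau2)),
            class = c("titeboin_design", "assisted_design", "latetox_design"))
}

#' Time-to-event keyboard design (TITE-mTPI2)
#'
#' @inheritParams titeboin_design
#' @param prior per-dose Beta prior (Beta(1, 1) in the reference setting).
#' @return a design object usable by [run_trial()].
#' @export
titemtpi2_design <- function(tau = 0.391, tau1 = 0.3519, tau2 = 0.5474,
                             prior = c(1, 1), pending_frac = 0.5) {
  structure(list(name = "titemtpi2", tau = tau, tau1 = tau1, tau2 = tau2,
                 prior = prior, pending_frac = pending_frac),
            class = c("titemtpi2_design", "assisted_design", "latetox_design"))
}

#' Rolling mTPI2 design (R-mTPI2)
#'
#' @inheritParams titemtpi2_design
#' @param consec_limit consecutive-assignment cap of the rolling rule.
#' @return a design object usable by [run_trial()].
#' @export
rmtpi2_design <- function(tau = 0.391, tau1 = 0.3519, tau2 = 0.5474,
                          prior = c(1, 1), consec_limit = 6) {
  structure(list(name = "rmtpi2", tau = tau, tau1 = tau1, tau2 = tau2,
                 prior = prior, consec_limit = consec_limit),
            class = c("rmtpi2_design", "assisted_design", "latetox_design"))
}

# map a relative move to a dose index; de-escalation below dose 1 stays
move_to_dose <- function(move, current, J) {
  switch(move,
         escalate = min(current + 1L, J),
         stay = current,
         deescalate = max(current - 1L, 1L),
         suspend = NA_integer_)
}

#' @export
decide_dose.titeboin_design <- function(design, data, state, ...) {
  sm <- interim_summary(data, state$current_dose, state$consec)
  move <- titeboin_decision(sm, design$thresholds, design$pending_frac)
  list(dose = move_to_dose(move, state$current_dose, length(state$dose_values)),
       suspend = identical(move, "suspend"), move = move)
}

#' @export
decide_dose.titemtpi2_design <- function(design, data, state, ...) {
  sm <- interim_summary(data, state$current_dose, state$consec)
  if (sm$n > 0 && sm$pending / sm$n > design$pending_frac) {
    return(list(dose = NA_integer_, suspend = TRUE, move = "suspend"))
  }
  eff <- keyboard_effective_counts(sm)
  if (eff$n_eff <= 0) {
    return(list(dose = NA_integer_, suspend = TRUE, move = "suspend"))
  }
  move <- keyboard_decision(eff$n_eff, eff$events, design$prior,
                            design$tau1, design$tau2)
  list(dose = move_to_dose(move, state$current_dose, length(state$dose_values)),
       suspend = FALSE, move = move)
}

#' @export
decide_dose.rmtpi2_design <- function(design, data, state, ...) {
  sm <- interim_summary(data, state$current_dose, state$consec)
  move <- rmtpi2_decision(sm, design$prior, design$tau1, design$tau2,
                          design$consec_limit)
  list(dose = move_to_dose(move, state$current_dose, length(state$dose_values)),
       suspend = identical(move, "suspend"), move = move)
}

#' @export
final_mtd.assisted_design <- function(design, data, admissible, dose_values, ...) {
  J <- length(dose_values)
  n <- dlt <- integer(J)
  p <- data$patients
  for (j in seq_len(J)) {
    n[j] <- sum(p$dose == j)
    dlt[j] <- sum(p$dose == j & p$dlt == 1L)
  }
  isotonic_mtd(n, dlt, design$prior, design$tau, admissible)
}

#' Precompute a model-assisted decision table
#'
#' Enumerates the design's interim decision over a grid of interim
#' summaries — patients treated, observed DLTs, pending patients and
#' discretised standardized total follow-up time — as done before a trial
#' starts.  The table is a pure function of the design configuration:
#' recomputing it always yields identical output.
#'
#' @param design a TITE-BOIN, TITE-mTPI2 or R-mTPI2 design object.
#' @param n_max largest treated count to tabulate.
#' @param S follow-up cycles (STFT is discretised in steps of 1/S).
#' @return data.frame with columns `n`, `dlt`, `pending`, `stft`,
#'   `consec`, `move`.
#' @export
assisted_decision_table <- function(design, n_max = 12L, S = 3L) {
  rows <- list()
  for (n in 1:n_max) for (m in 0:n) for (pen in 0:(n - m)) {
    stft_vals <- unique(seq(0, pen * (S - 1) / S, by = 1 / S))
    for (stft in stft_vals) {
      sm <- list(n = n, dlt = m, pending = pen, stft = stft,
                 complete = n - m - pen, consec = n)
      move <- switch(design$name,
        titeboin = titeboin_decision(sm, design$thresholds,
                                     design$pending_frac),
        titemtpi2 = {
          if (pen / n > design$pending_frac) "suspend"
          else {
            eff <- keyboard_effective_counts(sm)
            if (eff$n_eff <= 0) "suspend"
            else keyboard_decision(eff$n_eff, eff$events, design$prior,
                                   design$tau1, design$tau2)
          }
        },
        rmtpi2 = rmtpi2_decision(sm, design$prior, design$tau1,
                                 design$tau2, design$consec_limit),
        stop("not a model-assisted design"))
      rows[[length(rows) + 1L]] <-
        data.frame(n = n, dlt = m, pending = pen, stft = stft,
                   consec = n, move = move)
    }
  }
  do.call(rbind, rows)
}
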