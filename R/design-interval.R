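#' BOIN escalation and de-escalation boundaries
#'
#' Closed-form optimal interval boundaries: with target `tau` and interval
#' bounds `tau1 < tau < tau2`,
#' \deqn{\lambda_e = \frac{\log\{(1-\tau_1)/(1-\tau)\}}
#'   {\log\{\tau(1-\tau_1)/(\tau_1(1-\tau))\}}, \qquad
#'   \lambda_d = \frac{\log\{(1-\tau)/(1-\tau_2)\}}
#'   {\log\{\tau_2(1-\tau)/(\tau(1-\tau_2))\}}.}
#' Escalate when the observed DLT rate is at or below \eqn{\lambda_e},
#' de-escalate at or above \eqn{\lambda_d}.
#'
#' @param tau target DLT probability over the full follow-up period.
#' @param tau1,tau2 lower and upper bounds of the target interval.
#' @return named vector `c(lambda_e =, lambda_d =)` with
#'   `tau1 < lambda_e < tau < lambda_d < tau2`.
#' @examples
#' boin_thresholds(0.391, 0.3128, 0.5083)  # (0.3512, 0.4492)
#' @export
boin_thresholds <- function(tau, tau1, tau2) {
  if (!(tau1 > 0 && tau1 < tau && tau < tau2 && tau2 < 1))
    stop("need 0 < tau1 < tau < tau2 < 1")
  lambda_e <- log((1 - tau1) / (1 - tau)) /
    log(tau * (1 - tau1) / (tau1 * (1 - tau)))
  lambda_d <- log((1 - tau) / (1 - tau2)) /
    log(tau2 * (1 - tau) / (tau * (1 - tau2)))
  c(lambda_e = lambda_e, lambda_d = lambda_d)
}

#' Interim summary of the current dose for model-assisted decisions
#'
#' @param data a `"toxdata"` object.
#' @param dose current dose index.
#' @param consec number of patients consecutively assigned to `dose`
#'   without interruption (tracked by the trial engine; defaults to the
#'   number treated at `dose`).
#' @return list with `n` treated, `dlt` observed DLTs, `pending` patients
#'   with incomplete follow-up and no DLT, `stft` standardized total
#'   follow-up time of the pending patients (sum of u/S), `complete`
#'   non-DLT patients with full follow-up, and `consec`.
#' @export
interim_summary <- function(data, dose, consec = NULL) {
  p <- data$patients[data$patients$dose == dose, , drop = FALSE]
  S <- data$n_cycles
  dlt <- sum(p$dlt)
  nondlt <- p[p$dlt == 0L, , drop = FALSE]
  complete <- sum(nondlt$u >= S)
  pending_rows <- nondlt[nondlt$u < S, , drop = FALSE]
  pending <- nrow(pending_rows)
  stft <- sum(pending_rows$u) / S
  list(n = nrow(p), dlt = dlt, pending = pending, stft = stft,
       complete = complete,
       consec = if (is.null(consec)) nrow(p) else consec)
}

#' TITE-BOIN interim decision
#'
#' With every patient fully observed this is exactly the complete-data BOIN
#' rule (observed rate against \eqn{\lambda_e}/\eqn{\lambda_d}).  With
#' pending patients: a DLT rate already at or above \eqn{\lambda_d} on the
#' *observed* DLT count alone forces de-escalation (pending data can only
#' raise the rate); otherwise, if more than `pending_frac` of the patients
#' at the dose are pending, accrual is suspended; otherwise the rate is
#' estimated by the time-to-event imputation
#' \eqn{\hat p = m / (m + c + \mathrm{STFT})} (DLTs count fully, completed
#' non-DLT patients count fully, pending patients contribute their observed
#' follow-up fraction) and compared with the boundaries.
#'
#' @param summary an [interim_summary()].
#' @param thresholds output of [boin_thresholds()].
#' @param pending_frac suspension threshold on the pending fraction.
#' @return one of `"escalate"`, `"stay"`, `"deescalate"`, `"suspend"`.
#' @export
titeboin_decision <- function(summary, thresholds, pending_frac = 0.5) {
  n <- summary$n
  if (n < 1) stop("no patients treated at the current dose")
  m <- summary$dlt
  if (m / n >= thresholds[["lambda_d"]]) return("deescalate")
  if (summary$pending / n > pending_frac) return("suspend")
  phat <- m / (m + summary$complete + summary$stft)
  if (is.nan(phat)) phat <- 0   # n>0 but all mass pending is excluded above
  if (phat <= thresholds[["lambda_e"]]) return("escalate")
  if (phat >= thresholds[["lambda_d"]]) return("deescalate")
  "stay"
}

#' Effective binomial counts under time-to-event follow-up
#'
#' Completed patients count fully; a pending patient without a DLT
#' contributes their observed follow-up fraction u/S to the effective
#' sample size and nothing to the event count; a patient with a DLT counts
#' as one full event (DLT is terminal, their follow-up is complete).
#'
#' @param summary an [interim_summary()].
#' @return list with `n_eff` and `events`.
#' @export
keyboard_effective_counts <- function(summary) {
  list(n_eff = summary$dlt + summary$complete + summary$stft,
       events = summary$dlt)
}

#' Key layout for the keyboard (mTPI2-type) designs
#'
#' The target key is the calibrated interval `(tau1, tau2)`; keys of the
#' same width tile outward from it in both directions, with the two end
#' keys absorbing the remainders at 0 and 1.
#'
#' @inheritParams boin_thresholds
#' @return numeric vector of key boundaries (starting at 0, ending at 1),
#'   with attribute `target` giving the index of the target key.
#' @export
keyboard_keys <- function(tau1, tau2) {
  w <- tau2 - tau1
  lower <- tau1 - w * seq_len(floor(tau1 / w + 1e-12))
  lower <- lower[lower > 1e-12]
  upper <- tau2 + w * seq_len(floor((1 - tau2) / w + 1e-12))
  upper <- upper[upper < 1 - 1e-12]
  b <- c(0, rev(lower), tau1, tau2, upper, 1)
  structure(b, target = which(abs(b - tau1) < 1e-12))
}

#' Keyboard interim decision from effective binomial data
#'
#' The DLT probability posterior is `Beta(alpha + events, beta + n_eff -
#' events)`; the key holding the largest posterior mass is the "strongest".
#' A strongest key below the target key escalates, the target key stays,
#' and a key above de-escalates.  Mass ties resolve toward the more
#' cautious move (de-escalate over stay over escalate).
#'
#' @param n_eff effective sample size (> 0).
#' @param events effective DLT count.
#' @param prior length-2 Beta prior `c(alpha, beta)`.
#' @inheritParams boin_thresholds
#' @return `"escalate"`, `"stay"`, or `"deescalate"`.
#' @export
keyboard_decision <- function(n_eff, events, prior = c(1, 1), tau1, tau2) {
  if (n_eff <= 0) stop("effective sample size must be positive")
  keys <- keyboard_keys(tau1, tau2)
  target <- attr(keys, "target")
  a <- prior[1] + events
  b <- prior[2] + n_eff - events
  mass <- diff(stats::pbeta(keys, a, b))
  # ties toward the higher key (more cautious move)
  strongest <- max(which(mass >= max(mass) - 1e-12))
  if (strongest < target) "escalate" else if (strongest == target) "stay" else "deescalate"
}

#' Rolling mTPI2 interim decision
#'
#' Rule cascade for the rolling (enroll-while-pending) keyboard variant:
#' \enumerate{
#' \item with no pending patients, the plain keyboard decision on the
#'   complete data;
#' \item otherwise impute the pending patients both ways — best case (all
#'   complete without DLT) and worst case (all DLT) — and if the two
#'   imputed keyboard decisions agree, take that move;
#' \item otherwise fall back on the consecutive-assignment rule: if fewer
#'   than `consec_limit` patients have been consecutively assigned to the
#'   current dose the trial keeps enrolling there (`"stay"`), else accrual
#'   is suspended until more follow-up accumulates.
#' }
#'
#' @inheritParams titeboin_decision
#' @param prior length-2 Beta prior.
#' @inheritParams boin_thresholds
#' @param consec_limit consecutive-assignment cap in rule 3.
#' @return `"escalate"`, `"stay"`, `"deescalate"`, or `"suspend"`.
#' @export
rmtpi2_decision <- function(summary, prior = c(1, 1), tau1, tau2,
                            consec_limit = 6) {
  m <- summary$dlt; cpl <- summary$complete; pen <- summary$pending
  if (pen == 0L) {
    return(keyboard_decision(m + cpl, m, prior, tau1, tau2))
  }
  best <- keyboard_decision(m + cpl + pen, m, prior, tau1, tau2)
  worst <- keyboard_decision(m + cpl + pen, m + pen, prior, tau1, tau2)
  if (identical(best, worst)) return(best)
  if (summary$consec < consec_limit) "stay" else "suspend"
}

#' Pool-adjacent-violators algorithm (weighted, non-decreasing)
#'
#' Weighted least-squares projection of `y` onto the cone of non-decreasing
#' sequences: adjacent violating blocks are pooled to their weighted mean
#' until the fit is monotone.
#'
#' @param y numeric values.
#' @param w positive weights (default equal).
#' @return monotone non-decreasing fit, same length as `y`.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n <= 1L) return(y)
  val <- y[1]; wt <- w[1]; len <- 1L
  for (i in 2:n) {
    val <- c(val, y[i]); wt <- c(wt, w[i]); len <- c(len, 1L)
    k <- length(val)
    while (k > 1L && val[k - 1] > val[k] + 1e-15) {
      val[k - 1] <- (val[k - 1] * wt[k - 1] + val[k] * wt[k]) / (wt[k - 1] + wt[k])
      wt[k - 1] <- wt[k - 1] + wt[k]
      len[k - 1] <- len[k - 1] + len[k]
      val <- val[-k]; wt <- wt[-k]; len <- len[-k]
      k <- k - 1L
    }
  }
  rep(val, len)
}

#' Final MTD selection by isotonic regression
#'
#' Applies [pava()] with n-weighted pooling to the per-dose posterior mean
#' DLT probabilities `(alpha + dlt) / (alpha + beta + n)` of the doses with
#' at least one treated patient, then recommends the admissible dose whose
#' isotonic estimate is closest to the target.  Doses pooled by the
#' isotonic regression carry identical estimates; among equally close
#' doses the highest one is chosen when its estimate sits below the
#' target (the pooled doses are then all under-target and the highest is
#' the best MTD candidate) and the lowest when above (safety).
#'
#' @param n per-dose number of treated (fully followed) patients.
#' @param dlt per-dose DLT counts.
#' @param prior length-2 Beta prior.
#' @param tau target DLT probability.
#' @param admissible logical or index vector of admissible doses (default
#'   all).
#' @return recommended dose index, or `NA` if no dose was ever treated.
#' @export
isotonic_mtd <- function(n, dlt, prior = c(1, 1), tau,
                         admissible = seq_along(n)) {
  adm <- logical(length(n))
  adm[admissible] <- TRUE
  treated <- which(n > 0)
  if (length(treated) == 0L) return(NA_integer_)
  pm <- (prior[1] + dlt[treated]) / (prior[1] + prior[2] + n[treated])
  iso <- pava(pm, w = n[treated])
  cand <- treated[adm[treated]]
  if (length(cand) == 0L) return(NA_integer_)
  est <- iso[match(cand, treated)]
  d <- abs(est - tau)
  tied <- which(d <= min(d) + 1e-12)
  below <- tied[est[tied] <= tau]
  pick <- if (length(below)) max(below) else min(tied)
  cand[pick]
}
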