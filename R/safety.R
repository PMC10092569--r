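#' Enforcement and stopping rule configuration
#'
#' Setting 1 activates only the k-fold escalation limit and the
#' sufficient-information and maximum-patients stops; setting 2 adds the
#' hard-safety exclusion rule, the posterior safety stops at the lowest and
#' highest dose, and the precision stop (model-based designs only).
#'
#' @param setting 1 (minimal rules) or 2 (full rules).
#' @param tau_cycle1 cycle-1 DLT probability defining "too toxic" in the
#'   safety rules (0.3 in the reference setting).
#' @param hard_threshold posterior probability beyond which a dose is
#'   excluded by the hard-safety rule.
#' @param unsafe_threshold posterior probability for "lowest dose unsafe".
#' @param safe_threshold posterior probability for "highest dose very safe".
#' @param kfold maximum fold-rise in dose value over the highest tried.
#' @param sufficient_n treated-patient count at a recommended dose that
#'   stops the trial for sufficient information.
#' @param cv_bound coefficient-of-variation bound of the precision stop.
#' @param precision_n number of patients with at least one observed cycle
#'   required before the precision stop activates.
#' @param max_patients maximum trial size.
#' @param hard_prior,safety_prior Beta priors of the hard-safety and
#'   posterior-safety Beta-binomial models.
#' @param safety_model `"design"` to evaluate the posterior safety stops
#'   with each design's own one-cycle model where it has one, or
#'   `"betabinom"` to force the Beta-binomial model for every design.
#' @return a list of class `"rule_config"`.
#' @export
rule_config <- function(setting = 1, tau_cycle1 = 0.3,
                        hard_threshold = 0.95, unsafe_threshold = 0.80,
                        safe_threshold = 0.80, kfold = 2,
                        sufficient_n = 9, cv_bound = 0.30, precision_n = 9,
                        max_patients = 30, hard_prior = c(1, 1),
                        safety_prior = c(1, 1),
                        safety_model = c("design", "betabinom")) {
  stopifnot(setting %in% c(1, 2))
  structure(list(setting = setting, tau_cycle1 = tau_cycle1,
                 hard_threshold = hard_threshold,
                 unsafe_threshold = unsafe_threshold,
                 safe_threshold = safe_threshold, kfold = kfold,
                 sufficient_n = sufficient_n, cv_bound = cv_bound,
                 precision_n = precision_n, max_patients = max_patients,
                 hard_prior = hard_prior, safety_prior = safety_prior,
                 safety_model = match.arg(safety_model)),
            class = "rule_config")
}

#' Beta posterior tail probability of excessive toxicity
#'
#' `P(p > tau | r DLTs in n cycle-1 patients)` under a `Beta(prior)` prior.
#'
#' @param n cycle-1 completions, `r` cycle-1 DLTs among them.
#' @param r DLT count.
#' @param tau toxicity threshold on the cycle-1 DLT probability.
#' @param prior length-2 Beta prior.
#' @return posterior tail probability.
#' @export
beta_tail_prob <- function(n, r, tau, prior = c(1, 1)) {
  stats::pbeta(tau, prior[1] + r, prior[2] + n - r, lower.tail = FALSE)
}

#' Minimal DLT count triggering the hard-safety exclusion
#'
#' The smallest `r` such that `P(p1 > tau | Beta(1 + r, 1 + n - r)) >
#' threshold`.  At the reference configuration (tau 0.3, threshold 0.95,
#' uniform prior) this reproduces the dividing triples 3/3, 4/6 and 5/9.
#'
#' @param n number of patients with cycle 1 fully observed at the dose.
#' @inheritParams beta_tail_prob
#' @param threshold exclusion threshold (strict inequality).
#' @return minimal excluding DLT count, or `NA` if no `r <= n` qualifies.
#' @export
hard_safety_boundary <- function(n, tau = 0.3, threshold = 0.95,
                                 prior = c(1, 1)) {
  if (n < 0) stop("'n' must be >= 0")
  for (r in 0:n) {
    if (beta_tail_prob(n, r, tau, prior) > threshold) return(as.integer(r))
  }
  NA_integer_
}

#' Doses excluded by the hard-safety rule
#'
#' A dose whose observed cycle-1 DLTs exceed the [hard_safety_boundary()]
#' is excluded together with every higher dose; exclusions are permanent
#' and therefore upward-closed and non-shrinking over the trial.
#'
#' @param counts output of [cycle1_counts()]: per-dose cycle-1 completions
#'   and DLTs.
#' @param config a [rule_config()].
#' @return integer vector of excluded dose indices (possibly empty).
#' @export
apply_hard_safety <- function(counts, config) {
  J <- length(counts$n)
  excl <- J + 1L
  for (j in seq_len(J)) {
    if (counts$n[j] == 0) next
    if (beta_tail_prob(counts$n[j], counts$dlt[j], config$tau_cycle1,
                       config$hard_prior) > config$hard_threshold) {
      excl <- min(excl, j)
    }
  }
  if (excl > J) integer(0) else seq.int(excl, J)
}

#' k-fold escalation limit
#'
#' A proposed dose is allowed only if its value does not exceed `k` times
#' the highest dose value experimented so far.
#'
#' @param proposed_value,highest_value dose quantities (MBq).
#' @param k fold limit.
#' @return logical.
#' @export
k_fold_check <- function(proposed_value, highest_value, k = 2) {
  proposed_value <= k * highest_value + 1e-12
}

#' Sufficient-information stopping check
#'
#' The trial stops when the dose it is about to recommend already carries
#' at least `sufficient_n` treated patients.
#'
#' @param n_at_recommended patients treated at the recommended dose.
#' @param config a [rule_config()].
#' @return logical.
#' @export
sufficient_information_stop <- function(n_at_recommended, config) {
  n_at_recommended >= config$sufficient_n
}

#' Robust coefficient of variation of MTD posterior draws
#'
#' The adjusted median absolute deviation (MAD scaled by the normal
#' consistency constant 1.4826) divided by the median of the draws.
#'
#' @param draws MTD posterior draws on the dose scale.
#' @return list with `cv` (NA when the median is not positive) and the
#'   `median` and `mad` components.
#' @export
precision_cv <- function(draws) {
  med <- stats::median(draws)
  m <- stats::mad(draws)        # already scaled by 1.4826
  cv <- if (is.na(med) || med <= 0) NA_real_ else m / med
  list(cv = cv, median = med, mad = m)
}

#' Precision stopping decision
#'
#' Stops when the MTD is precisely estimated: CV below `cv_bound`, active
#' only once at least `precision_n` patients have at least one observed
#' cycle, and only for designs with a dose-response model (the
#' model-assisted designs cannot estimate an MTD on the dose scale).
#'
#' @param draws MTD posterior draws on the dose scale (may be `NULL` for
#'   designs without a model).
#' @param n_with_cycle number of patients with >= 1 observed cycle.
#' @param config a [rule_config()].
#' @return list with logical `stop` and the computed `cv`.
#' @export
precision_stop <- function(draws, n_with_cycle, config) {
  if (is.null(draws) || n_with_cycle < config$precision_n)
    return(list(stop = FALSE, cv = NA_real_))
  cv <- precision_cv(draws)$cv
  list(stop = !is.na(cv) && cv < config$cv_bound, cv = cv)
}
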