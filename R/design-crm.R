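#' Follow-up weight of the time-to-event CRM
#'
#' The simple linear weight `u/S` of observed cycles over total follow-up
#' cycles; a patient with an observed DLT is weighted 1 regardless of
#' follow-up.
#'
#' @param u cycles observed (0..S).
#' @param S total follow-up cycles.
#' @param dlt logical/0-1 observed-DLT flag.
#' @return weight in \[0, 1\].  Vectorised.
#' @export
titecrm_weight <- function(u, S, dlt = FALSE) {
  if (any(u < 0 | u > S)) stop("'u' must be in 0..S")
  ifelse(as.logical(dlt), 1, u / S)
}

# weighted log-likelihood of the 1-parameter power model at each beta node
titecrm_loglik <- function(beta, skel_d, w, y) {
  if (length(y) == 0L) return(rep(0, length(beta)))
  e <- exp(beta)
  ll <- numeric(length(beta))
  for (i in seq_along(y)) {
    G <- w[i] * skel_d[i]^e
    ll <- ll + if (y[i] == 1L) log(G) else log1p(-G)
  }
  ll
}

#' Posterior of the 1-parameter TITE-CRM power model
#'
#' The dose-response model is \eqn{F(d, \beta) = d^{\exp(\beta)}} on the
#' skeleton scale with weighted bernoulli likelihood
#' \eqn{\prod_i (w_i F)^{y_i} (1 - w_i F)^{1-y_i}} and a `N(0, sigma2)`
#' prior on \eqn{\beta}.  The posterior mean is computed by dense
#' trapezoidal quadrature on a fixed interval; with no data it is the prior
#' mean, 0.  Patients with weight 0 contribute a unit factor.
#'
#' @param data a `"toxdata"` object (or `NULL` for no data).
#' @param skeleton strictly increasing per-dose prior toxicity guesses.
#' @param sigma2 prior variance of beta.
#' @param grid number of quadrature nodes.
#' @param range support of the quadrature, `c(lower, upper)`.
#' @return list with `beta_hat` (posterior mean), `nodes`, and normalised
#'   posterior `weights` over the nodes (for resampling-based summaries).
#' @export
titecrm_fit <- function(data, skeleton, sigma2 = 1, grid = 2001,
                        range = c(-10, 10)) {
  nodes <- seq(range[1], range[2], length.out = grid)
  if (is.null(data) || nrow(data$patients) == 0L) {
    ll <- rep(0, grid)
  } else {
    p <- data$patients
    keep <- p$u > 0L | p$dlt == 1L
    p <- p[keep, , drop = FALSE]
    w <- titecrm_weight(p$u, data$n_cycles, p$dlt)
    ll <- titecrm_loglik(nodes, skeleton[p$dose], w, p$dlt)
  }
  lp <- ll + stats::dnorm(nodes, 0, sqrt(sigma2), log = TRUE)
  lp <- lp - max(lp)
  wts <- exp(lp)
  wts <- wts / sum(wts)
  if (!all(is.finite(wts))) stop("degenerate TITE-CRM posterior")
  list(beta_hat = sum(nodes * wts), nodes = nodes, weights = wts)
}

#' Next dose under the 1-parameter TITE-CRM
#'
#' During the initial phase — before any DLT has been observed anywhere in
#' the trial — the dose escalates exactly one level per decision.  After
#' the first DLT the model takes over: the dose minimising
#' \eqn{|F(d_j, \hat\beta) - \tau|}, ties toward the lower dose.  Skipping
#' and exclusion restrictions are enforced by the trial engine.
#'
#' @param beta_hat posterior mean of beta.
#' @param skeleton per-dose skeleton.
#' @param tau target DLT probability over the full follow-up.
#' @param any_dlt has any DLT been observed in the trial so far?
#' @param current_dose current dose index (for the initial phase).
#' @return recommended dose index.
#' @export
titecrm_next_dose <- function(beta_hat, skeleton, tau, any_dlt,
                              current_dose) {
  J <- length(skeleton)
  if (!any_dlt) return(min(current_dose + 1L, J))
  fitted <- skeleton^exp(beta_hat)
  which.min(abs(fitted - tau))
}

#' One-parameter TITE-CRM design
#'
#' @param skeleton per-dose prior guesses of the full-follow-up DLT
#'   probability (defaults to the calibrated values).
#' @param sigma2 prior variance of the model parameter.
#' @param tau target DLT probability over the full follow-up period.
#' @return a design object usable by [run_trial()].
#' @export
titecrm_design <- function(skeleton = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                           sigma2 = 1, tau = 0.391) {
  structure(list(name = "titecrm", skeleton = skeleton, sigma2 = sigma2,
                 tau = tau),
            class = c("titecrm_design", "latetox_design"))
}

#' @export
decide_dose.titecrm_design <- function(design, data, state, ...) {
  if (!state$any_dlt) {
    dose <- min(state$current_dose + 1L, length(design$skeleton))
    return(list(dose = dose, suspend = FALSE))
  }
  fit <- titecrm_fit(data, design$skeleton, design$sigma2)
  dose <- titecrm_next_dose(fit$beta_hat, design$skeleton, design$tau,
                            TRUE, state$current_dose)
  list(dose = dose, suspend = FALSE, fit = fit)
}

#' @export
final_mtd.titecrm_design <- function(design, data, admissible, ...) {
  fit <- titecrm_fit(data, design$skeleton, design$sigma2)
  fitted <- design$skeleton^exp(fit$beta_hat)
  cand <- admissible
  if (length(cand) == 0L) return(NA_integer_)
  cand[which.min(abs(fitted[cand] - design$tau))]
}

# draws of beta from the quadrature posterior
titecrm_beta_draws <- function(fit, n = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(fit$nodes, n, replace = TRUE, prob = fit$weights)
}

# continuous MTD (dose scale) for one beta: linear interpolation of the
# fitted curve over dose values, extrapolating with the end segments so
# that posterior spread is preserved beyond the grid (clamping would
# collapse the draws onto an end dose and overstate precision)
crm_continuous_mtd <- function(beta, skeleton, dose_values, tau) {
  p <- skeleton^exp(beta)
  J <- length(p)
  if (tau <= p[1]) {
    return(dose_values[1] -
             (p[1] - tau) * (dose_values[2] - dose_values[1]) /
             (p[2] - p[1]))
  }
  if (tau >= p[J]) {
    return(dose_values[J] +
             (tau - p[J]) * (dose_values[J] - dose_values[J - 1]) /
             (p[J] - p[J - 1]))
  }
  stats::approx(p, dose_values, xout = tau, ties = "ordered")$y
}

#' @export
mtd_draws.titecrm_design <- function(design, data, dose_values, seed = NULL, ...) {
  fit <- titecrm_fit(data, design$skeleton, design$sigma2)
  betas <- titecrm_beta_draws(fit, seed = seed)
  vapply(betas, crm_continuous_mtd, 0, skeleton = design$skeleton,
         dose_values = dose_values, tau = design$tau)
}

#' @export
cycle1_prob.titecrm_design <- function(design, data, dose, tau_cycle1, ...) {
  # one-cycle restricted model: S = 1, only cycle-1 outcomes
  d1 <- restrict_first_cycle(data)
  fit <- titecrm_fit(d1, design$skeleton, design$sigma2)
  p_draws <- design$skeleton[dose]^exp(fit$nodes)
  sum(fit$weights[p_draws > tau_cycle1])
}

# collapse a toxdata object to a one-cycle trial: u = min(u, 1), DLT only
# if it occurred in cycle 1
restrict_first_cycle <- function(data) {
  p <- data$patients
  p$u <- pmin(p$u, 1L)
  c1 <- !is.na(p$dlt_cycle) & p$dlt_cycle == 1L
  p$dlt <- as.integer(c1)
  p$dlt_cycle <- ifelse(c1, 1L, NA_integer_)
  structure(list(patients = p, cycles = data$cycles[data$cycles$cycle == 1L, ,
                                                    drop = FALSE],
                 n_cycles = 1L), class = "toxdata")
}
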