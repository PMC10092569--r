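#' Posterior of the 2-parameter TITE-CRM logistic model
#'
#' Uses the real dose quantities through the 2-parameter logistic model
#' \eqn{F(d, a_0, a_1) = \mathrm{logit}^{-1}(a_0 + a_1 d)} with the same
#' weighted likelihood as the 1-parameter model.  Priors are
#' \eqn{a_0 \sim N(\mu_{a_0}, \sigma^2_{a_0})} and \eqn{\log a_1 \sim
#' N(\mu_{a_1}, \sigma^2_{a_1})}, so the fitted curve is always increasing
#' in dose.  The posterior is integrated on a dense 2-D grid over
#' \eqn{(a_0, \log a_1)} (mean +/- 7 prior SDs per axis), which makes every
#' decision deterministic given the data.
#'
#' @param data a `"toxdata"` object (or `NULL`).
#' @param dose_values real dose quantities (MBq).
#' @param prior list with `mu_a0`, `var_a0`, `mu_la1`, `var_la1` (mean and
#'   variance of the intercept and of log slope).
#' @param grid nodes per axis.
#' @return list with posterior means `a0_hat`, `a1_hat`, the grid
#'   marginals (`a0_nodes`, `la1_nodes`, `weights` matrix) for
#'   resampling-based summaries.
#' @export
titecrm2_fit <- function(data, dose_values, prior, grid = 121) {
  s0 <- sqrt(prior$var_a0); s1 <- sqrt(prior$var_la1)
  a0n <- seq(prior$mu_a0 - 7 * s0, prior$mu_a0 + 7 * s0, length.out = grid)
  la1n <- seq(prior$mu_la1 - 7 * s1, prior$mu_la1 + 7 * s1, length.out = grid)
  lp <- outer(stats::dnorm(a0n, prior$mu_a0, s0, log = TRUE),
              stats::dnorm(la1n, prior$mu_la1, s1, log = TRUE), "+")
  if (!is.null(data) && nrow(data$patients) > 0L) {
    p <- data$patients
    keep <- p$u > 0L | p$dlt == 1L
    p <- p[keep, , drop = FALSE]
    if (nrow(p) > 0L) {
      w <- titecrm_weight(p$u, data$n_cycles, p$dlt)
      d <- p$dose_value
      a1 <- exp(la1n)
      for (i in seq_len(nrow(p))) {
        eta <- outer(a0n, a1 * d[i], "+")
        G <- w[i] * stats::plogis(eta)
        lp <- lp + if (p$dlt[i] == 1L) log(G) else log1p(-G)
      }
    }
  }
  lp <- lp - max(lp)
  wts <- exp(lp); wts <- wts / sum(wts)
  a1mat <- matrix(exp(la1n), grid, grid, byrow = TRUE)
  a0mat <- matrix(a0n, grid, grid)
  list(a0_hat = sum(a0mat * wts), a1_hat = sum(a1mat * wts),
       a0_nodes = a0n, la1_nodes = la1n, weights = wts)
}

#' Two-parameter TITE-CRM design
#'
#' @param prior normal prior for the intercept and the log slope;
#'   defaults to the calibrated values (means -1 and log 0.2, precision
#'   0.3 on both, i.e. variance 10/3).
#' @param tau target DLT probability over the full follow-up period.
#' @return a design object usable by [run_trial()].
#' @export
titecrm2_design <- function(prior = list(mu_a0 = -1, var_a0 = 1 / 0.3,
                                         mu_la1 = log(0.2), var_la1 = 1 / 0.3),
                            tau = 0.391) {
  structure(list(name = "titecrm2", prior = prior, tau = tau),
            class = c("titecrm2_design", "latetox_design"))
}

crm2_fitted <- function(fit, dose_values) {
  stats::plogis(fit$a0_hat + fit$a1_hat * dose_values)
}

#' @export
decide_dose.titecrm2_design <- function(design, data, state, ...) {
  J <- length(state$dose_values)
  if (!state$any_dlt) {
    return(list(dose = min(state$current_dose + 1L, J), suspend = FALSE))
  }
  fit <- titecrm2_fit(data, state$dose_values, design$prior)
  fitted <- crm2_fitted(fit, state$dose_values)
  list(dose = which.min(abs(fitted - design$tau)), suspend = FALSE, fit = fit)
}

#' @export
final_mtd.titecrm2_design <- function(design, data, admissible, dose_values, ...) {
  if (length(admissible) == 0L) return(NA_integer_)
  fit <- titecrm2_fit(data, dose_values, design$prior)
  fitted <- crm2_fitted(fit, dose_values)
  admissible[which.min(abs(fitted[admissible] - design$tau))]
}

# sample (a0, a1) cells from the grid posterior
crm2_draws <- function(fit, n = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(fit$weights), n, replace = TRUE,
                    prob = as.vector(fit$weights))
  g <- length(fit$a0_nodes)
  a0 <- fit$a0_nodes[(idx - 1L) %% g + 1L]
  a1 <- exp(fit$la1_nodes[(idx - 1L) %/% g + 1L])
  cbind(a0 = a0, a1 = a1)
}

#' @export
mtd_draws.titecrm2_design <- function(design, data, dose_values, seed = NULL, ...) {
  fit <- titecrm2_fit(data, dose_values, design$prior)
  dr <- crm2_draws(fit, seed = seed)
  (stats::qlogis(design$tau) - dr[, "a0"]) / dr[, "a1"]
}

#' @export
cycle1_prob.titecrm2_design <- function(design, data, dose, tau_cycle1,
                                        dose_values, ...) {
  d1 <- restrict_first_cycle(data)
  fit <- titecrm2_fit(d1, dose_values, design$prior)
  a1 <- exp(fit$la1_nodes)
  p <- stats::plogis(outer(fit$a0_nodes, a1 * dose_values[dose], "+"))
  sum(fit$weights[p > tau_cycle1])
}
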