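#' Pseudo-data prior of the interval-censored survival design
#'
#' The prior is expressed as fractional pseudo-patients at the lowest and
#' highest dose: `n0` pseudo-patients enter cycle 1 at each anchor dose
#' and experience DLTs at the anchor rate, the survivors roll into the
#' next cycle where the anchor rate decays geometrically (factor `decay`),
#' and so on over the S cycles.  Non-integer counts are allowed.
#'
#' @param prior list with `pi1` (cycle-1 DLT anchor at the lowest dose),
#'   `piJ` (anchor at the highest dose), `n0` (pseudo-patients per anchor
#'   dose) and optionally `decay` (per-cycle anchor decay, default 1/3).
#' @param S follow-up cycles.
#' @param n_dose number of doses J.
#' @return data.frame with columns `dose`, `cycle`, `r` (pseudo events),
#'   `q` (pseudo survivors).
#' @examples
#' icsdp_pseudo_data(list(pi1 = 0.2, piJ = 0.4, n0 = 6), S = 3, n_dose = 6)
#' @export
icsdp_pseudo_data <- function(prior, S, n_dose) {
  if (is.null(prior$n0) || prior$n0 <= 0)
    stop("ICSDP needs n0 > 0 pseudo-patients")
  decay <- if (is.null(prior$decay)) 1/3 else prior$decay
  anchor <- function(dose, pi1) {
    enter <- prior$n0
    out <- vector("list", S)
    for (s in seq_len(S)) {
      pis <- pi1 * decay^(s - 1)
      r <- pis * enter
      q <- enter - r
      out[[s]] <- data.frame(dose = dose, cycle = s, r = r, q = q)
      enter <- q
    }
    do.call(rbind, out)
  }
  rbind(anchor(1L, prior$pi1), anchor(n_dose, prior$piJ))
}

# negative log-likelihood of the cloglog interval-censored model
# par = (gamma_1..gamma_S, theta); counts: dose, cycle, r, q; log-dose ld
icsdp_negll <- function(par, counts, ld, S) {
  gam <- par[seq_len(S)]
  theta <- par[S + 1L]
  eta <- gam[counts$cycle] + theta * ld[counts$dose]
  # pi = 1 - exp(-exp(eta)); use stable logs
  log_pi <- log(-expm1(-exp(eta)))
  log_1mpi <- -exp(eta)
  -sum(counts$r * log_pi + counts$q * log_1mpi)
}

#' Fit the interval-censored survival model
#'
#' Maximises the pseudo-data-augmented likelihood
#' \eqn{\prod_{j,s} \pi_{j,s}^{r_{j,s}} (1-\pi_{j,s})^{q_{j,s}}} under the
#' complementary log-log link \eqn{\log(-\log(1 - \pi_{j,s})) = \gamma_s +
#' \theta \log d_j}.  `r` counts first DLTs in cycle `s` at dose `j`, `q`
#' counts completions of cycle `s` without DLT; partially observed cycles
#' contribute nothing (interval censoring).
#'
#' @param data a `"toxdata"` object, or `NULL` for a pseudo-data-only fit.
#' @param dose_values real dose quantities.
#' @param prior see [icsdp_pseudo_data()].
#' @param S follow-up cycles.
#' @return list with `gamma` (length S), `theta`, `vcov` (asymptotic
#'   covariance from the numeric Hessian, `NULL` if singular),
#'   `converged`, and fitted per-cycle probabilities `pi` (J x S).
#' @export
icsdp_fit <- function(data, dose_values, prior, S = 3L) {
  J <- length(dose_values)
  counts <- icsdp_pseudo_data(prior, S, J)
  if (!is.null(data)) {
    cc <- cycle_counts(data, J)
    idx <- which(cc$r + cc$q > 0, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      counts <- rbind(counts,
                      data.frame(dose = idx[, 1], cycle = idx[, 2],
                                 r = cc$r[idx], q = cc$q[idx]))
    }
  }
  ld <- log(dose_values)
  # start gammas at the cloglog of the decayed lowest-dose anchor, theta at 0.5
  start <- c(log(-log(1 - pmin(0.95, prior$pi1 * (1/3)^(seq_len(S) - 1)))) -
               0.5 * ld[1], 0.5)
  opt <- stats::optim(start, icsdp_negll, counts = counts, ld = ld, S = S,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  gam <- opt$par[seq_len(S)]
  theta <- opt$par[S + 1L]
  eta <- outer(theta * ld, gam, "+")
  structure(list(gamma = gam, theta = theta, vcov = vc,
                 converged = opt$convergence == 0,
                 pi = 1 - exp(-exp(eta))), class = "icsdp_fit")
}

#' Total DLT probability over all cycles under the fitted ICSDP model
#'
#' \eqn{\rho_j = 1 - \prod_s (1 - \pi_{j,s})}.
#'
#' @param pi per-cycle conditional DLT probabilities for one dose (vector)
#'   or all doses (J x S matrix).
#' @return total probability (scalar or per-dose vector).
#' @export
icsdp_total_prob <- function(pi) {
  if (is.matrix(pi)) apply(pi, 1, function(x) 1 - prod(1 - x))
  else 1 - prod(1 - pi)
}

#' Next dose under the ICSDP gain criterion
#'
#' Maximises the gain \eqn{1 / (\tau - \hat\rho_j)^2} over admissible
#' doses — equivalently minimises \eqn{|\hat\rho_j - \tau|}; a dose with
#' \eqn{\hat\rho_j = \tau} has infinite gain and is selected; ties break
#' toward the lower dose.
#'
#' @param rho per-dose total DLT probability estimates.
#' @param tau target probability.
#' @param admissible candidate dose indices.
#' @return dose index (`NA` if no candidates).
#' @export
icsdp_next_dose <- function(rho, tau, admissible = seq_along(rho)) {
  if (length(admissible) == 0L) return(NA_integer_)
  admissible[which.min(abs(rho[admissible] - tau))]
}

#' Interval-censored survival design (ICSDP)
#'
#' @param prior pseudo-data prior, see [icsdp_pseudo_data()]; defaults to
#'   the calibrated setting-1 values.
#' @param tau target DLT probability over the full follow-up period.
#' @return a design object usable by [run_trial()].
#' @export
icsdp_design <- function(prior = list(pi1 = 0.2, piJ = 0.4, n0 = 6,
                                      decay = 1/3),
                         tau = 0.391) {
  structure(list(name = "icsdp", prior = prior, tau = tau),
            class = c("icsdp_design", "latetox_design"))
}

#' @export
decide_dose.icsdp_design <- function(design, data, state, ...) {
  fit <- icsdp_fit(data, state$dose_values, design$prior, state$n_cycles)
  if (!fit$converged) {
    return(list(dose = state$current_dose, suspend = FALSE, fit = fit))
  }
  rho <- icsdp_total_prob(fit$pi)
  list(dose = icsdp_next_dose(rho, design$tau), suspend = FALSE, fit = fit)
}

#' @export
final_mtd.icsdp_design <- function(design, data, admissible, dose_values, ...) {
  fit <- icsdp_fit(data, dose_values, design$prior, data$n_cycles)
  rho <- icsdp_total_prob(fit$pi)
  icsdp_next_dose(rho, design$tau, admissible)
}

# draws of (gamma, theta) from the asymptotic normal at the mode
icsdp_param_draws <- function(fit, n = 2000L, seed = NULL) {
  if (is.null(fit$vcov)) return(NULL)
  if (!is.null(seed)) set.seed(seed)
  ch <- tryCatch(chol(fit$vcov), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  k <- length(fit$gamma) + 1L
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% ch, 2, c(fit$gamma, fit$theta), "+")
}

#' @export
mtd_draws.icsdp_design <- function(design, data, dose_values, seed = NULL, ...) {
  fit <- icsdp_fit(data, dose_values, design$prior, data$n_cycles)
  dr <- icsdp_param_draws(fit, seed = seed)
  if (is.null(dr)) return(NULL)
  S <- length(fit$gamma)
  # solve 1 - exp(-sum_s exp(gamma_s) d^theta) = tau for d
  A <- rowSums(exp(dr[, seq_len(S), drop = FALSE]))
  theta <- dr[, S + 1L]
  d <- (-log(1 - design$tau) / A)^(1 / theta)
  d[!is.finite(d)] <- NA_real_
  d[!is.na(d)]
}

#' @export
cycle1_prob.icsdp_design <- function(design, data, dose, tau_cycle1,
                                     dose_values, ...) {
  fit <- icsdp_fit(data, dose_values, design$prior, data$n_cycles)
  dr <- icsdp_param_draws(fit, seed = NULL)
  if (is.null(dr)) {
    pi1 <- fit$pi[dose, 1]
    return(as.numeric(pi1 > tau_cycle1))
  }
  eta <- dr[, 1] + dr[, ncol(dr)] * log(dose_values[dose])
  pi1 <- 1 - exp(-exp(eta))
  mean(pi1 > tau_cycle1)
}
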