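#' Pseudo-data prior of the proportional-odds (POMM) design
#'
#' The prior is a set of fractional ordinal pseudo-observations on every
#' dose and cycle.  Each (dose, cycle) cell carries total weight
#' `n0 / (J * S)`, split across the three ordinal categories by the anchor
#' probabilities: category 3 (DLT) with the cycle-1 anchor `p1star[j]`,
#' category 2 (grade 2) with `ratio[j] * p1star[j]`, and category 1 with
#' the remainder.
#'
#' @param prior list with `p1star` (per-dose cycle-1 DLT anchors), `ratio`
#'   (per-dose grade-2-to-DLT anchor ratios; recycled to J values) and
#'   `n0` (total pseudo-weight).
#' @param dose_values dose quantities.
#' @param S follow-up cycles.
#' @return data.frame with `dose`, `dose_value`, `cycle`, `cat`, `weight`.
#' @export
pomm_pseudo_data <- function(prior, dose_values, S) {
  J <- length(dose_values)
  p3 <- prior$p1star
  ratio <- rep(prior$ratio, length.out = J)
  p2 <- ratio * p3
  p1 <- 1 - p3 - p2
  if (any(p1 < 0)) stop("POMM anchors imply negative category-1 mass")
  cell <- prior$n0 / (J * S)
  out <- expand.grid(dose = seq_len(J), cycle = seq_len(S), cat = 1:3,
                     KEEP.OUT.ATTRS = FALSE)
  out$dose_value <- dose_values[out$dose]
  prob <- cbind(p1, p2, p3)
  out$weight <- cell * prob[cbind(out$dose, out$cat)]
  out[out$weight > 0, c("dose", "dose_value", "cycle", "cat", "weight")]
}

#' Initial-phase POMM fit (first 15 subjects)
#'
#' Weighted maximum-likelihood logistic regression of the binary DLT
#' indicator (category 3 vs below) on the dose value, using only cycle-1
#' responses, augmented by the cycle-1 layer of the pseudo-data.  The next
#' dose minimises the distance of the fitted cycle-1 DLT probability to
#' the cycle-1 target.
#'
#' @param data a `"toxdata"` object (or `NULL`).
#' @param prior see [pomm_pseudo_data()].
#' @param dose_values dose quantities.
#' @param S follow-up cycles (for the pseudo-data layout).
#' @return list with `b0`, `b1`, `vcov`, `ok` (fit usable), and fitted
#'   per-dose cycle-1 DLT probabilities `p1_hat`.
#' @export
pomm_initial_fit <- function(data, prior, dose_values, S = 3L) {
  ps <- pomm_pseudo_data(prior, dose_values, S)
  ps <- ps[ps$cycle == 1L, , drop = FALSE]
  d <- ps$dose_value
  y <- as.integer(ps$cat == 3L)
  w <- ps$weight
  if (!is.null(data) && nrow(data$cycles) > 0L) {
    cy <- data$cycles[data$cycles$cycle == 1L, , drop = FALSE]
    d <- c(d, cy$dose_value)
    y <- c(y, as.integer(cy$cat == 3L))
    w <- c(w, rep(1, nrow(cy)))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ d, weights = w,
                                family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || abs(stats::coef(fit)[2]) > 50) {
    return(list(ok = FALSE))
  }
  b <- unname(stats::coef(fit))
  list(b0 = b[1], b1 = b[2], vcov = stats::vcov(fit), ok = TRUE,
       p1_hat = stats::plogis(b[1] + b[2] * dose_values))
}

pomm_mixed_model_string <- function(has_obs) {
  paste0("model {\n",
    if (has_obs) paste0(
      "  for (i in 1:Nobs) {\n",
      "    logit(c1[i]) <- a1 - b1*d[i] - b2*s[i] - u[pid[i]]\n",
      "    logit(c2[i]) <- a2 - b1*d[i] - b2*s[i] - u[pid[i]]\n",
      "    p[i,1] <- max(c1[i], 1.0E-9)\n",
      "    p[i,2] <- max(c2[i] - c1[i], 1.0E-9)\n",
      "    p[i,3] <- max(1 - c2[i], 1.0E-9)\n",
      "    y[i] ~ dcat(p[i,1:3])\n",
      "  }\n",
      "  for (j in 1:Npat) { u[j] ~ dnorm(0, tau_u) }\n"),
    "  for (k in 1:Nps) {\n",
    "    logit(pc1[k]) <- a1 - b1*dp[k] - b2*sp[k]\n",
    "    logit(pc2[k]) <- a2 - b1*dp[k] - b2*sp[k]\n",
    "    pp[k,1] <- max(pc1[k], 1.0E-9)\n",
    "    pp[k,2] <- max(pc2[k] - pc1[k], 1.0E-9)\n",
    "    pp[k,3] <- max(1 - pc2[k], 1.0E-9)\n",
    "    phi[k] <- -wp[k] * log(pp[k, yp[k]]) + 100\n",
    "    zeros[k] ~ dpois(phi[k])\n",
    "  }\n",
    "  a1 ~ dnorm(0, 0.01)\n",
    "  del ~ dnorm(0, 0.01) T(0,)\n",
    "  a2 <- a1 + del\n",
    "  b1 ~ dnorm(0, 0.01)\n",
    "  b2 ~ dnorm(0, 0.01)\n",
    "  tau_u ~ dgamma(0.001, 0.001)\n",
    "  sig0sq <- 1/tau_u\n",
    "}\n")
}

#' Bayesian proportional-odds mixed-effect fit (POMM, subject 16 onward)
#'
#' Fits \eqn{\mathrm{logit}\, P(Y_{i,s} \le k \mid d_j) = \alpha_k -
#' \beta_1 d_j - \beta_2 s - u_i} for \eqn{k = 1, 2} with patient random
#' effects \eqn{u_i \sim N(0, \sigma_0^2)}, ordering \eqn{\alpha_1 <
#' \alpha_2} enforced by construction, weakly informative normal priors on
#' the coefficients and an inverse-gamma(0.001, 0.001) prior on
#' \eqn{\sigma_0^2}.  The fractional pseudo-data enter through a weighted
#' (power) likelihood.  Cycles after a DLT contribute nothing; the DLT
#' cycle contributes its category-3 response.
#'
#' @param data a `"toxdata"` object.
#' @param prior see [pomm_pseudo_data()].
#' @param dose_values dose quantities.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed for the sampler.
#' @return list with `draws` (matrix with columns a1, a2, b1, b2, sig0sq),
#'   `converged`.
#' @export
pomm_mixed_fit <- function(data, prior, dose_values, mcmc = mcmc_config(),
                           seed = 1L) {
  S <- data$n_cycles
  ps <- pomm_pseudo_data(prior, dose_values, S)
  cy <- data$cycles
  has_obs <- nrow(cy) > 0L
  jd <- list(Nps = nrow(ps), dp = ps$dose_value, sp = ps$cycle,
             yp = ps$cat, wp = ps$weight, zeros = rep(0, nrow(ps)))
  if (has_obs) {
    pid <- match(cy$id, unique(cy$id))
    jd <- c(jd, list(Nobs = nrow(cy), d = cy$dose_value, s = cy$cycle,
                     y = cy$cat, pid = pid, Npat = max(pid)))
  }
  run_jags(pomm_mixed_model_string(has_obs), jd,
           c("a1", "a2", "b1", "b2", "sig0sq"), mcmc, seed,
           conv_pars = c("a1", "a2", "b1", "b2"))
}

# P(DLT in whole follow-up | dose, u = 0) per posterior draw: 1 - prod_s
# P(Y <= 2 | dose, s, u = 0)
pomm_prob_all_cycles <- function(draws, dose_value, S) {
  keep <- rep(1, nrow(draws))
  for (s in seq_len(S)) {
    keep <- keep * stats::plogis(draws[, "a2"] - draws[, "b1"] * dose_value -
                                   draws[, "b2"] * s)
  }
  1 - keep
}

#' Proportional-odds mixed-model design (POMM)
#'
#' Uses grade information as a three-level ordinal response.  The first 15
#' subjects are assigned by a cycle-1-only weighted logistic model against
#' the cycle-1 target; from subject 16 a Bayesian proportional-odds mixed
#' model over all observed cycles targets the whole-follow-up DLT
#' probability of a median (random-effect 0) patient.
#'
#' @param prior pseudo-data prior (calibrated defaults).
#' @param tau target DLT probability over the full follow-up period.
#' @param tau_cycle1 cycle-1 target used in the initial phase.
#' @param switch_at subject count at which the mixed model takes over.
#' @param mcmc an [mcmc_config()].
#' @return a design object usable by [run_trial()].
#' @export
pomm_design <- function(prior = list(p1star = c(0.15, 0.20, 0.25, 0.3, 0.35, 0.40),
                                     ratio = c(0.20, 0.30, 0.40, 0.50, 0.60),
                                     n0 = 2),
                        tau = 0.391, tau_cycle1 = 0.3, switch_at = 16L,
                        mcmc = mcmc_config()) {
  structure(list(name = "pomm", prior = prior, tau = tau,
                 tau_cycle1 = tau_cycle1, switch_at = as.integer(switch_at),
                 mcmc = mcmc),
            class = c("pomm_design", "latetox_design"))
}

pomm_uses_initial <- function(design, state) {
  state$n_enrolled < design$switch_at
}

#' @export
decide_dose.pomm_design <- function(design, data, state, seed = 1L, ...) {
  dv <- state$dose_values
  if (pomm_uses_initial(design, state)) {
    fit <- pomm_initial_fit(data, design$prior, dv, state$n_cycles)
    if (!fit$ok) return(list(dose = state$current_dose, suspend = FALSE))
    tail_fun <- function(dose_idx, tau1) {
      ch <- tryCatch(chol(fit$vcov), error = function(e) NULL)
      if (is.null(ch)) return(as.numeric(fit$p1_hat[dose_idx] > tau1))
      z <- matrix(stats::rnorm(2 * 2000L), 2000L, 2)
      b <- sweep(z %*% ch, 2, c(fit$b0, fit$b1), "+")
      mean(stats::plogis(b[, 1] + b[, 2] * dv[dose_idx]) > tau1)
    }
    return(list(dose = which.min(abs(fit$p1_hat - design$tau_cycle1)),
                suspend = FALSE, fit = fit, cycle1_tail = tail_fun))
  }
  fit <- pomm_mixed_fit(data, design$prior, dv, design$mcmc, seed)
  if (!fit$converged) {
    return(list(dose = state$current_dose, suspend = FALSE))
  }
  S <- state$n_cycles
  pmat <- vapply(dv, function(d) pomm_prob_all_cycles(fit$draws, d, S),
                 numeric(nrow(fit$draws)))
  p_all <- colMeans(pmat)
  draws_mtd <- dv[apply(abs(pmat - design$tau), 1, which.min)]
  tail_fun <- function(dose_idx, tau1) {
    p1 <- 1 - stats::plogis(fit$draws[, "a2"] -
                              fit$draws[, "b1"] * dv[dose_idx] -
                              fit$draws[, "b2"] * 1)
    mean(p1 > tau1)
  }
  list(dose = which.min(abs(p_all - design$tau)), suspend = FALSE,
       fit = fit, mtd_draws = draws_mtd, cycle1_tail = tail_fun)
}

#' @export
final_mtd.pomm_design <- function(design, data, admissible, dose_values,
                                  seed = 1L, ...) {
  if (length(admissible) == 0L) return(NA_integer_)
  n_pat <- nrow(data$patients)
  if (n_pat < design$switch_at) {
    fit <- pomm_initial_fit(data, design$prior, dose_values, data$n_cycles)
    if (!fit$ok) return(NA_integer_)
    crit <- abs(fit$p1_hat - design$tau_cycle1)
  } else {
    fit <- pomm_mixed_fit(data, design$prior, dose_values, design$mcmc, seed)
    p_all <- vapply(dose_values, function(d) {
      mean(pomm_prob_all_cycles(fit$draws, d, data$n_cycles))
    }, 0)
    crit <- abs(p_all - design$tau)
  }
  admissible[which.min(crit[admissible])]
}

#' @export
mtd_draws.pomm_design <- function(design, data, dose_values, seed = 1L, ...) {
  if (nrow(data$patients) < design$switch_at) return(NULL)
  fit <- pomm_mixed_fit(data, design$prior, dose_values, design$mcmc, seed)
  if (!fit$converged) return(NULL)
  S <- data$n_cycles
  pmat <- vapply(dose_values, function(d) {
    pomm_prob_all_cycles(fit$draws, d, S)
  }, numeric(nrow(fit$draws)))
  idx <- apply(abs(pmat - design$tau), 1, which.min)
  dose_values[idx]
}

#' @export
cycle1_prob.pomm_design <- function(design, data, dose, tau_cycle1,
                                    dose_values, seed = 1L, ...) {
  n_pat <- nrow(data$patients)
  if (n_pat < design$switch_at) {
    fit <- pomm_initial_fit(data, design$prior, dose_values, data$n_cycles)
    if (!fit$ok) return(NA_real_)
    ch <- tryCatch(chol(fit$vcov), error = function(e) NULL)
    if (is.null(ch)) return(as.numeric(fit$p1_hat[dose] > tau_cycle1))
    z <- matrix(stats::rnorm(2 * 2000L), 2000L, 2)
    b <- sweep(z %*% ch, 2, c(fit$b0, fit$b1), "+")
    p <- stats::plogis(b[, 1] + b[, 2] * dose_values[dose])
    return(mean(p > tau_cycle1))
  }
  fit <- pomm_mixed_fit(data, design$prior, dose_values, design$mcmc, seed)
  p1 <- 1 - stats::plogis(fit$draws[, "a2"] -
                            fit$draws[, "b1"] * dose_values[dose] -
                            fit$draws[, "b2"] * 1)
  mean(p1 > tau_cycle1)
}
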