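#' Bayesian linear mixed-effect fit of nTTP values
#'
#' Fits \eqn{y_{i,s} = \beta_0 + \beta_1 x_i + \beta_2 s + \gamma_i +
#' \epsilon_{i,s}} to the observed per-cycle nTTP values, where \eqn{x_i}
#' is the model dose covariate, \eqn{\gamma_i \sim N(0, \sigma_\gamma^2)}
#' a patient effect and \eqn{\epsilon_{i,s} \sim N(0, \sigma_\epsilon^2)}
#' measurement error; the coefficients carry normal priors and both
#' variances inverse-gamma(0.001, 0.001) priors.  Cycles after a DLT are
#' not observed and contribute nothing; the DLT cycle contributes its
#' observed nTTP.
#'
#' Conditional on the two variance components the model is conjugate, so
#' the posterior is computed exactly: a log-spaced grid over
#' \eqn{(\sigma_\gamma^2, \sigma_\epsilon^2)} carries closed-form normal
#' updates of the coefficients, and the marginal posterior is the
#' weighted mixture.  This removes Monte-Carlo error (and convergence
#' failures) from dose decisions; `draws` are exact samples from the
#' mixture for summaries that need them.  With no data the prior is
#' returned.
#'
#' @param data a `"toxdata"` object (or `NULL`).
#' @param prior list with `mu_b0`, `var_b0`, `mu_b1`, `var_b1`, `mu_b2`,
#'   `var_b2`.
#' @param grid nodes per variance axis.
#' @param sigma_range range of each variance component (the upper end is
#'   ample for a \[0, 1\] endpoint).
#' @param n_draws posterior draws returned.
#' @param seed seed for the returned draws.
#' @return list with `draws` (columns b0, b1, b2, sig_g, sig_e),
#'   `mean` (exact posterior coefficient means), and `converged`
#'   (always `TRUE`; kept for interface compatibility).
#' @export
nttp_fit <- function(data, prior, grid = 25, sigma_range = c(1e-4, 1),
                     n_draws = 2000L, seed = NULL) {
  m0 <- c(prior$mu_b0, prior$mu_b1, prior$mu_b2)
  S0 <- diag(c(prior$var_b0, prior$var_b1, prior$var_b2))
  S0inv <- diag(1 / c(prior$var_b0, prior$var_b1, prior$var_b2))
  cy <- if (is.null(data)) NULL else data$cycles
  has_obs <- !is.null(cy) && nrow(cy) > 0L

  sig <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                 length.out = grid))
  # IG(0.001, 0.001) prior mass on the log-spaced grid (jacobian included)
  lw_prior <- function(s) -0.001 * log(s) - 0.001 / s
  cells <- expand.grid(sg = sig, se = sig, KEEP.OUT.ATTRS = FALSE)
  lw <- lw_prior(cells$sg) + lw_prior(cells$se)
  post_m <- rep(list(m0), nrow(cells))
  post_S <- rep(list(S0), nrow(cells))

  if (has_obs) {
    pid <- match(cy$id, unique(cy$id))
    X <- cbind(1, cy$dose_value, cy$cycle)
    y <- cy$nttp
    r0 <- drop(y - X %*% m0)
    blocks <- split(seq_along(y), pid)
    for (k in seq_len(nrow(cells))) {
      sg <- cells$sg[k]; se <- cells$se[k]
      XtAX <- matrix(0, 3, 3); XtAy <- numeric(3); XtAr <- numeric(3)
      qf <- 0; logdetV <- 0
      for (b in blocks) {
        ni <- length(b)
        Xi <- X[b, , drop = FALSE]; yi <- y[b]; ri <- r0[b]
        c1 <- sg / (se + ni * sg)
        Ax <- (Xi - matrix(colSums(Xi) * c1, ni, 3, byrow = TRUE)) / se
        XtAX <- XtAX + crossprod(Xi, Ax)
        XtAy <- XtAy + crossprod(Ax, yi)
        XtAr <- XtAr + crossprod(Ax, ri)
        Ar <- (ri - c1 * sum(ri)) / se
        qf <- qf + sum(ri * Ar)
        logdetV <- logdetV + (ni - 1) * log(se) + log(se + ni * sg)
      }
      B <- S0inv + XtAX
      Bs <- solve(B)
      # marginal likelihood of the cell: N(y; X m0, V + X S0 X')
      logdetM <- logdetV +
        as.numeric(determinant(diag(3) + S0 %*% XtAX, TRUE)$modulus)
      qfM <- qf - drop(t(XtAr) %*% Bs %*% XtAr)
      lw[k] <- lw[k] - 0.5 * (logdetM + qfM)
      post_S[[k]] <- Bs
      post_m[[k]] <- drop(Bs %*% (S0inv %*% m0 + XtAy))
    }
  }
  lw <- lw - max(lw)
  w <- exp(lw); w <- w / sum(w)
  bmean <- Reduce(`+`, Map(`*`, post_m, w))

  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(cells), n_draws, replace = TRUE, prob = w)
  z <- matrix(stats::rnorm(3 * n_draws), n_draws, 3)
  draws <- matrix(NA_real_, n_draws, 5,
                  dimnames = list(NULL, c("b0", "b1", "b2", "sig_g",
                                          "sig_e")))
  for (k in unique(idx)) {
    sel <- which(idx == k)
    ch <- chol(post_S[[k]])
    draws[sel, 1:3] <- z[sel, , drop = FALSE] %*% ch +
      matrix(post_m[[k]], length(sel), 3, byrow = TRUE)
    draws[sel, 4] <- cells$sg[k]
    draws[sel, 5] <- cells$se[k]
  }
  list(draws = draws, mean = stats::setNames(bmean, c("b0", "b1", "b2")),
       converged = TRUE)
}

#' Next dose under the nTTP criterion
#'
#' The admissible dose minimising the absolute distance of the posterior
#' expected cycle-1 nTTP, \eqn{E[\beta_0 + \beta_1 x_j + \beta_2]}, from
#' the nTTP target; ties break toward the lower dose.
#'
#' @param fit an [nttp_fit()] result.
#' @param xvals model dose covariate values.
#' @param tau_nttp target cycle-1 nTTP.
#' @param admissible candidate dose indices.
#' @return dose index.
#' @export
nttp_next_dose <- function(fit, xvals, tau_nttp,
                           admissible = seq_along(xvals)) {
  if (length(admissible) == 0L) return(NA_integer_)
  e1 <- fit$mean["b0"] + fit$mean["b1"] * xvals + fit$mean["b2"]
  admissible[which.min(abs(e1[admissible] - tau_nttp))]
}

#' Normalized total toxicity profile (nTTP) design
#'
#' Treats toxicity as a quasi-continuous endpoint: each observed cycle
#' contributes an nTTP value and a Bayesian linear mixed model guides
#' escalation toward a target cycle-1 nTTP.
#'
#' @param prior coefficient priors; defaults to the calibrated setting-1
#'   values.
#' @param tau_nttp target cycle-1 nTTP; defaults to [tau_nttp_default()].
#' @param standardize_dose if `TRUE` (default) the model covariate is the
#'   dose value divided by the largest dose on the grid — the scale on
#'   which the calibrated slope prior is meaningful for a \[0, 1\]
#'   endpoint.
#' @return a design object usable by [run_trial()].
#' @export
nttp_design <- function(prior = list(mu_b0 = 0.1, var_b0 = 100,
                                     mu_b1 = 0.5, var_b1 = 100,
                                     mu_b2 = 0, var_b2 = 10),
                        tau_nttp = NULL, standardize_dose = TRUE) {
  if (is.null(tau_nttp)) tau_nttp <- tau_nttp_default()
  structure(list(name = "nttp", prior = prior, tau_nttp = tau_nttp,
                 standardize_dose = standardize_dose),
            class = c("nttp_design", "latetox_design"))
}

nttp_xvals <- function(design, dose_values) {
  if (isTRUE(design$standardize_dose)) dose_values / max(dose_values)
  else dose_values
}

# rescale the cycles table so the model sees the design's dose covariate
nttp_scale_data <- function(design, data, dose_values) {
  if (!isTRUE(design$standardize_dose)) return(data)
  data$cycles$dose_value <- data$cycles$dose_value / max(dose_values)
  data
}

#' @export
decide_dose.nttp_design <- function(design, data, state, seed = 1L, ...) {
  dv <- state$dose_values
  fit <- nttp_fit(nttp_scale_data(design, data, dv), design$prior,
                  seed = seed)
  d <- (design$tau_nttp - fit$draws[, "b0"] - fit$draws[, "b2"]) /
    fit$draws[, "b1"]
  if (isTRUE(design$standardize_dose)) d <- d * max(dv)
  list(dose = nttp_next_dose(fit, nttp_xvals(design, dv), design$tau_nttp),
       suspend = FALSE, fit = fit, mtd_draws = d[is.finite(d)])
}

#' @export
final_mtd.nttp_design <- function(design, data, admissible, dose_values,
                                  seed = 1L, ...) {
  if (length(admissible) == 0L) return(NA_integer_)
  fit <- nttp_fit(nttp_scale_data(design, data, dose_values), design$prior,
                  seed = seed)
  nttp_next_dose(fit, nttp_xvals(design, dose_values), design$tau_nttp,
                 admissible)
}

#' @export
mtd_draws.nttp_design <- function(design, data, dose_values, seed = 1L, ...) {
  fit <- nttp_fit(nttp_scale_data(design, data, dose_values), design$prior,
                  seed = seed)
  d <- (design$tau_nttp - fit$draws[, "b0"] - fit$draws[, "b2"]) /
    fit$draws[, "b1"]
  if (isTRUE(design$standardize_dose)) d <- d * max(dose_values)
  d[is.finite(d)]
}
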