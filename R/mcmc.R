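#' MCMC configuration for the JAGS-based designs
#'
#' @param chains number of chains.
#' @param adapt adaptation iterations.
#' @param burn burn-in iterations after adaptation.
#' @param iter posterior draws per chain.
#' @param psrf_max convergence threshold on the potential scale reduction
#'   factor; a fit exceeding it is flagged and the trial engine retains
#'   the current dose for that decision.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4, adapt = 500, burn = 1000, iter = 2000,
                        psrf_max = 1.01) {
  structure(list(chains = chains, adapt = adapt, burn = burn, iter = iter,
                 psrf_max = psrf_max), class = "mcmc_config")
}

# run a JAGS model and return a draws matrix plus a convergence flag;
# the PSRF gate applies to conv_pars (the parameters entering decisions),
# not to nuisance variance components whose mixing is poor on tiny data
run_jags <- function(model_string, data, monitors, mcmc, seed = 1L,
                     conv_pars = monitors) {
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((seed + 977L * ch) %% 2147483646L) + 1L)
  })
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data, inits = inits,
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = TRUE)
  if (mcmc$burn > 0) stats::update(jm, mcmc$burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = mcmc$iter,
                              progress.bar = "none")
  converged <- TRUE
  if (mcmc$chains > 1) {
    sub <- samp[, intersect(conv_pars, coda::varnames(samp)), drop = FALSE]
    gd <- tryCatch(coda::gelman.diag(sub, autoburnin = FALSE,
                                     multivariate = FALSE),
                   error = function(e) NULL)
    if (!is.null(gd)) {
      converged <- all(gd$psrf[, 1] < mcmc$psrf_max, na.rm = TRUE)
    }
  }
  list(draws = as.matrix(samp), converged = converged)
}
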