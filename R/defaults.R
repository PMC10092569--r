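#' Construct a design with its calibrated hyper-parameters
#'
#' Convenience factory returning any of the eight designs pre-configured
#' with the calibrated prior values for the requested rule setting
#' (several designs share the same values in both settings; ICSDP, nTTP
#' and TITE-BOIN differ).
#'
#' @param name one of `"titecrm"`, `"titecrm2"`, `"icsdp"`, `"pomm"`,
#'   `"nttp"`, `"titeboin"`, `"titemtpi2"`, `"rmtpi2"`.
#' @param setting 1 (minimal stopping rules) or 2 (full stopping rules).
#' @param tau target DLT probability over the full follow-up period.
#' @param ... overrides passed to the design constructor.
#' @return a `latetox_design` object.
#' @export
standard_design <- function(name = c("titecrm", "titecrm2", "icsdp", "pomm",
                                     "nttp", "titeboin", "titemtpi2",
                                     "rmtpi2"),
                            setting = 1, tau = 0.391, ...) {
  name <- match.arg(name)
  stopifnot(setting %in% c(1, 2))
  switch(name,
    titecrm = titecrm_design(tau = tau, ...),
    titecrm2 = titecrm2_design(tau = tau, ...),
    icsdp = {
      prior <- if (setting == 1) list(pi1 = 0.2, piJ = 0.4, n0 = 6, decay = 1/3)
               else list(pi1 = 0.2, piJ = 0.3, n0 = 4, decay = 1/3)
      icsdp_design(prior = prior, tau = tau, ...)
    },
    pomm = pomm_design(tau = tau, ...),
    nttp = {
      prior <- if (setting == 1) list(mu_b0 = 0.1, var_b0 = 100,
                                      mu_b1 = 0.5, var_b1 = 100,
                                      mu_b2 = 0, var_b2 = 10)
               else list(mu_b0 = 0.05, var_b0 = 10,
                         mu_b1 = 0.1, var_b1 = 10,
                         mu_b2 = 0, var_b2 = 10)
      nttp_design(prior = prior, ...)
    },
    titeboin = {
      prior <- if (setting == 1) c(0.1, 0.9) else c(1, 1)
      titeboin_design(tau = tau, prior = prior, ...)
    },
    titemtpi2 = titemtpi2_design(tau = tau, ...),
    rmtpi2 = rmtpi2_design(tau = tau, ...))
}
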