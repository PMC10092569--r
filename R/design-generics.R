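#' Design interface used by the trial engine
#'
#' Every escalation design is an S3 object inheriting from
#' `"latetox_design"` and implementing these generics.  `decide_dose()`
#' proposes the dose for the next cohort from an interim dataset (or asks
#' for a suspension of accrual); `final_mtd()` makes the final
#' recommendation from the complete-follow-up data among the admissible
#' doses; `cycle1_prob()` returns the design's one-cycle-model posterior
#' probability that a dose's cycle-1 DLT probability exceeds a threshold
#' (used by the posterior safety stopping rules); `mtd_draws()` returns
#' posterior draws of the MTD on the dose scale (used by the precision
#' stopping rule) for model-based designs, and `NULL` for designs without
#' a dose-response model.
#'
#' @param design a design object.
#' @param data a `"toxdata"` interim dataset.
#' @param state engine state: list with `current_dose`, `any_dlt`,
#'   `n_assigned` (per dose), `consec`, `n_enrolled`.
#' @param admissible integer vector of admissible dose indices.
#' @param dose dose index.
#' @param tau_cycle1 cycle-1 toxicity threshold.
#' @param dose_values dose quantities.
#' @param seed optional seed for stochastic summaries.
#' @param ... further arguments passed to methods.
#' @name design-interface
NULL

#' @rdname design-interface
#' @export
decide_dose <- function(design, data, state, ...) UseMethod("decide_dose")

#' @rdname design-interface
#' @export
final_mtd <- function(design, data, admissible, ...) UseMethod("final_mtd")

#' @rdname design-interface
#' @export
cycle1_prob <- function(design, data, dose, tau_cycle1, ...) {
  UseMethod("cycle1_prob")
}

#' @rdname design-interface
#' @export
mtd_draws <- function(design, data, dose_values, seed = NULL, ...) {
  UseMethod("mtd_draws")
}

#' @rdname design-interface
#' @export
mtd_draws.default <- function(design, data, dose_values, seed = NULL, ...) NULL

#' @rdname design-interface
#' @export
cycle1_prob.default <- function(design, data, dose, tau_cycle1, ...) {
  # Beta-binomial fallback on observed cycle-1 data
  cnt <- cycle1_counts(data, dose)
  beta_tail_prob(cnt$n[dose], cnt$dlt[dose], tau_cycle1)
}

#' @export
print.latetox_design <- function(x, ...) {
  cat("<latetox design:", x$name, ">\n")
  for (nm in setdiff(names(x), "name")) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) <= 8)
      cat(" ", nm, "=", paste(signif(v, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
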