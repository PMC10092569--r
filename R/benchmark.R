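#' Geometric mean of proportions
#'
#' Used as the calibration score: \eqn{(\prod_m v_m)^{1/m}}, defined as 0
#' whenever any component is 0 so that a very poor performance in one
#' scenario is penalised maximally.
#'
#' @param values non-negative proportions.
#' @return geometric mean.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (any(values < 0)) stop("proportions must be non-negative")
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

#' Empirical optimal benchmark dose selection
#'
#' The benchmark exploits the latent-variable data generation: each
#' patient's latent determines their outcome on *every* dose, so the full
#' response profile of all patients on all doses is available.  The
#' benchmark selects the dose whose mean response over the maximum patient
#' count is closest to the target — the full-period DLT indicator against
#' `tau` for the binary-endpoint designs, or the cycle-1 nTTP value
#' against `tau_nttp` for the nTTP design.  Doses with identical true
#' probabilities produce identical responses under the shared latents, so
#' exact ties are common: among equally close doses the highest one is
#' selected when its mean is below the target (the best under-target MTD
#' candidate), the lowest otherwise.  The benchmark always uses every
#' patient and provides an upper reference for the proportion of correct
#' selections.
#'
#' @param pop a [patient_population()] (the same one the designs saw).
#' @param scn a [scenario()].
#' @param measure `"dlt"` or `"nttp"`.
#' @param tau target for the chosen measure (full-period DLT probability,
#'   or cycle-1 nTTP target).
#' @param weights,normalizer nTTP weight configuration (measure "nttp").
#' @return selected dose index.
#' @export
benchmark_select <- function(pop, scn, measure = c("dlt", "nttp"),
                             tau = scn$tau, weights = NULL,
                             normalizer = NULL) {
  measure <- match.arg(measure)
  J <- length(scn$dose_values)
  S <- scn$n_cycles
  if (measure == "dlt") {
    v <- 1 - pop$latents
    means <- vapply(seq_len(J), function(j) mean(v <= scn$ps[j, S]), 0)
  } else {
    if (is.null(weights)) weights <- nttp_weights_default()
    means <- vapply(seq_len(J), function(j) {
      mean(vapply(seq_len(pop$n), function(i) {
        patient_outcome(pop, i, scn, j, weights, normalizer)$nttp[1]
      }, 0))
    }, 0)
  }
  d <- abs(means - tau)
  tied <- which(d <= min(d) + 1e-12)
  below <- tied[means[tied] <= tau]
  if (length(below)) max(below) else min(tied)
}

#' Benchmark proportion of correct selections
#'
#' Replays the benchmark selection over `n_sims` replicate populations
#' drawn exactly as [simulate_ocs()] draws them (seed `seed + r` for
#' replicate `r`), so benchmark and designs consume identical latent
#' sequences.
#'
#' @inheritParams benchmark_select
#' @param n_sims replicates.
#' @param seed base seed.
#' @param n_patients patients per replicate (the trial maximum).
#' @return list with `pcs` (percent) and the per-replicate `selected`.
#' @export
empirical_benchmark <- function(scn, n_sims = 1000L, seed = 1L,
                                n_patients = 30L,
                                measure = c("dlt", "nttp"),
                                tau = scn$tau, weights = NULL,
                                normalizer = NULL) {
  measure <- match.arg(measure)
  sel <- integer(n_sims)
  for (r in seq_len(n_sims)) {
    pop <- patient_population(n_patients, scn$n_cycles, seed + r)
    sel[r] <- benchmark_select(pop, scn, measure, tau, weights, normalizer)
  }
  pcs <- if (scn$truth$type == "mtd") 100 * mean(sel == scn$truth$mtd)
         else NA_real_
  list(pcs = pcs, selected = sel)
}

#' Prior calibration by grid search
#'
#' Scores every candidate hyper-parameter combination by the geometric
#' mean of its per-scenario proportions of correct outcomes and returns
#' the argmax; ties break toward the first candidate in grid order.  By
#' default the score of a candidate in a scenario is obtained by
#' simulation ([simulate_ocs()] with `design_fun(candidate)`), but any
#' scoring function with the same signature can be substituted — e.g. a
#' deterministic stub when validating the harness itself.
#'
#' @param candidates a list of hyper-parameter combinations (each passed
#'   to `design_fun`), or a data.frame whose rows are combinations.
#' @param scenarios list of labelled [scenario()] objects.
#' @param design_fun function turning one candidate into a
#'   `latetox_design`.
#' @param n_sims simulations per candidate-scenario pair.
#' @param seed base seed (shared across candidates and scenarios so all
#'   candidates face identical patients).
#' @param config a [trial_config()].
#' @param pcs_fun optional override: `function(candidate, scenario)`
#'   returning a proportion in \[0, 1\].
#' @return list with `best` (the winning candidate), `best_index`,
#'   and `report` (data.frame of per-scenario PCS and geometric means,
#'   one row per candidate).
#' @export
calibrate_design <- function(candidates, scenarios, design_fun = NULL,
                             n_sims = 1000L, seed = 1L,
                             config = trial_config(), pcs_fun = NULL) {
  if (is.data.frame(candidates)) {
    candidates <- lapply(seq_len(nrow(candidates)),
                         function(i) as.list(candidates[i, , drop = FALSE]))
  }
  if (length(candidates) == 0L) stop("empty calibration grid")
  if (is.null(pcs_fun)) {
    if (is.null(design_fun)) stop("need 'design_fun' or 'pcs_fun'")
    pcs_fun <- function(candidate, scn) {
      oc <- simulate_ocs(design_fun(candidate), scn, n_sims, seed, config)
      oc$pcs / 100
    }
  }
  m <- length(scenarios)
  scores <- matrix(NA_real_, length(candidates), m)
  for (i in seq_along(candidates)) {
    for (s in seq_len(m)) {
      scores[i, s] <- pcs_fun(candidates[[i]], scenarios[[s]])
    }
  }
  gm <- apply(scores, 1, geometric_mean)
  best <- which.max(gm)   # first maximum in grid order
  report <- data.frame(candidate = seq_along(candidates), scores,
                       geomean = gm)
  names(report)[1 + seq_len(m)] <-
    vapply(seq_len(m), function(s) {
      lb <- scenarios[[s]]$label
      if (is.null(lb)) paste0("scenario", s) else lb
    }, "")
  list(best = candidates[[best]], best_index = best, report = report)
}

#' Calibration scenarios
#'
#' The six cycle-1 probability vectors used for prior calibration on the
#' reference dose grid: four scenarios moving the MTD through the dose
#' range (used in both settings), plus an all-unsafe and an all-very-safe
#' scenario used only when the safety stopping rules are active
#' (setting 2).
#'
#' @param setting 1 or 2.
#' @param tau full-period target used for truth labelling.
#' @return named list of [scenario()] objects.
#' @export
calibration_scenarios <- function(setting = 1, tau = 0.391) {
  p <- list(
    PS1 = list(c(0.300, 0.400, 0.450, 0.500, 0.550, 0.600), 1L),
    PS2 = list(c(0.050, 0.070, 0.100, 0.150, 0.200, 0.300), 6L),
    PS3 = list(c(0.100, 0.200, 0.300, 0.400, 0.500, 0.600), 3L),
    PS4 = list(c(0.150, 0.200, 0.250, 0.300, 0.350, 0.400), 4L),
    PS5 = list(c(0.400, 0.450, 0.500, 0.550, 0.600, 0.650), "all_unsafe"),
    PS6 = list(c(0.070, 0.090, 0.110, 0.130, 0.150, 0.170), "all_safe"))
  if (setting == 1) p <- p[1:4]
  out <- lapply(names(p), function(nm) {
    scenario(p[[nm]][[1]], tau = tau, truth = p[[nm]][[2]], label = nm)
  })
  stats::setNames(out, names(p))
}
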