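#' Interim view of trial data at a calendar week
#'
#' Builds the dataset a design is allowed to see at a decision time: each
#' enrolled patient contributes the cycles that have *completed* by `week`
#' (enrollment happens at cycle boundaries, so a cohort enrolled `k` cycles
#' ago has `min(k, S)` observable cycles), truncated at the DLT cycle — a
#' patient who left the study with a DLT contributes nothing afterwards.
#' No future information can leak by construction.
#'
#' @param enrolled data.frame with one row per enrolled patient: columns
#'   `id`, `dose` (index), `dose_value`, `enroll_week`, `dlt_cycle`
#'   (`NA` if none over full follow-up) and list-columns are not used;
#'   per-cycle outcomes are supplied via `outcomes`.
#' @param outcomes list of per-patient outcome lists from
#'   [patient_outcome()], parallel to `enrolled`.
#' @param week calendar week of the decision (a cycle boundary).
#' @param n_cycles follow-up length S.
#' @param cycle_weeks length of one cycle in weeks.
#' @return object of class `"toxdata"`: list with `patients` (one row per
#'   patient: `id`, `dose`, `dose_value`, `u` cycles observed, `dlt`
#'   observed-DLT flag, `dlt_cycle`) and `cycles` (one row per observed
#'   patient-cycle: `id`, `dose`, `dose_value`, `cycle`, `max_grade`, `cat`,
#'   `nttp`, `dlt`), plus `n_cycles`.
#' @export
observable_dataset <- function(enrolled, outcomes, week, n_cycles = 3L,
                               cycle_weeks = 6) {
  n <- nrow(enrolled)
  if (n == 0L) {
    return(structure(list(
      patients = data.frame(id = integer(), dose = integer(),
                            dose_value = numeric(), u = integer(),
                            dlt = integer(), dlt_cycle = integer()),
      cycles = data.frame(id = integer(), dose = integer(),
                          dose_value = numeric(), cycle = integer(),
                          max_grade = integer(), cat = integer(),
                          nttp = numeric(), dlt = integer()),
      n_cycles = as.integer(n_cycles)), class = "toxdata"))
  }
  elapsed <- pmax(0, floor((week - enrolled$enroll_week) / cycle_weeks))
  u <- pmin(elapsed, n_cycles)
  dlt_c <- enrolled$dlt_cycle
  u <- ifelse(!is.na(dlt_c) & dlt_c <= u, dlt_c, u)
  dlt_obs <- as.integer(!is.na(dlt_c) & dlt_c <= u & u > 0)
  patients <- data.frame(id = enrolled$id, dose = enrolled$dose,
                         dose_value = enrolled$dose_value, u = as.integer(u),
                         dlt = dlt_obs,
                         dlt_cycle = ifelse(dlt_obs == 1L, dlt_c, NA_integer_))
  rows <- lapply(seq_len(n), function(i) {
    ui <- u[i]
    if (ui == 0L) return(NULL)
    out <- outcomes[[i]]
    s <- seq_len(ui)
    data.frame(id = enrolled$id[i], dose = enrolled$dose[i],
               dose_value = enrolled$dose_value[i], cycle = s,
               max_grade = out$max_grade[s], cat = out$cat[s],
               nttp = out$nttp[s],
               dlt = as.integer(!is.na(out$dlt_cycle) & out$dlt_cycle == s))
  })
  cycles <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(cycles))
    cycles <- data.frame(id = integer(), dose = integer(),
                         dose_value = numeric(), cycle = integer(),
                         max_grade = integer(), cat = integer(),
                         nttp = numeric(), dlt = integer())
  structure(list(patients = patients, cycles = cycles,
                 n_cycles = as.integer(n_cycles)),
            class = "toxdata")
}

#' Flat per-patient-cycle audit table of a trial dataset
#'
#' @param data a `"toxdata"` object.
#' @return the `cycles` data.frame (one row per observed patient-cycle),
#'   suitable for writing to CSV.
#' @export
toxdata_frame <- function(data) {
  stopifnot(inherits(data, "toxdata"))
  data$cycles
}

#' Per-dose, per-cycle event/survivor counts
#'
#' Tabulates `r[j, s]`, the number of patients with a DLT in cycle `s` of
#' dose `j`, and `q[j, s]`, the number who completed cycle `s` on dose `j`
#' without a DLT — the sufficient statistics of the interval-censored
#' survival model.  Partially observed cycles contribute nothing.
#'
#' @param data a `"toxdata"` object.
#' @param n_dose number of doses J.
#' @return list of two J x S matrices `r` and `q`.
#' @export
cycle_counts <- function(data, n_dose) {
  S <- data$n_cycles
  r <- q <- matrix(0, n_dose, S)
  cy <- data$cycles
  for (k in seq_len(nrow(cy))) {
    j <- cy$dose[k]; s <- cy$cycle[k]
    if (cy$dlt[k] == 1L) r[j, s] <- r[j, s] + 1 else q[j, s] <- q[j, s] + 1
  }
  list(r = r, q = q)
}

#' Per-dose cycle-1 completion and DLT counts
#'
#' Counts used by the hard-safety rule and the Beta-binomial safety
#' models: patients whose cycle-1 outcome is observed, and how many of
#' those had a cycle-1 DLT.
#'
#' @param data a `"toxdata"` object.
#' @param n_dose number of doses J.
#' @return list with integer vectors `n` and `dlt` of length `n_dose`.
#' @export
cycle1_counts <- function(data, n_dose) {
  n <- dlt <- integer(n_dose)
  p <- data$patients
  obs <- p$u >= 1L
  for (j in seq_len(n_dose)) {
    sel <- obs & p$dose == j
    n[j] <- sum(sel)
    dlt[j] <- sum(sel & !is.na(p$dlt_cycle) & p$dlt_cycle == 1L)
  }
  list(n = n, dlt = dlt)
}
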