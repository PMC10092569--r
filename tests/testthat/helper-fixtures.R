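# fixtures are built in code: construct a toxdata object from per-patient
# specifications (u = cycles observed, dlt_cycle = NA for none)
make_toxdata <- function(dose, u, dlt_cycle = rep(NA_integer_, length(dose)),
                         dose_values = c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0),
                         n_cycles = 3L, cat = NULL, nttp = NULL) {
  n <- length(dose)
  dlt_obs <- !is.na(dlt_cycle) & dlt_cycle <= u
  patients <- data.frame(id = seq_len(n), dose = dose,
                         dose_value = dose_values[dose], u = as.integer(u),
                         dlt = as.integer(dlt_obs),
                         dlt_cycle = ifelse(dlt_obs, dlt_cycle, NA_integer_))
  rows <- lapply(seq_len(n), function(i) {
    ui <- min(u[i], if (dlt_obs[i]) dlt_cycle[i] else n_cycles)
    if (ui == 0L) return(NULL)
    s <- seq_len(ui)
    is_dlt <- dlt_obs[i] & s == dlt_cycle[i]
    data.frame(id = i, dose = dose[i], dose_value = dose_values[dose[i]],
               cycle = s,
               max_grade = ifelse(is_dlt, 3L, 0L),
               cat = if (is.null(cat)) ifelse(is_dlt, 3L, 1L)
                     else rep_len(cat, ui),
               nttp = if (is.null(nttp)) ifelse(is_dlt, 0.5, 0)
                      else rep_len(nttp, ui),
               dlt = as.integer(is_dlt))
  })
  cycles <- do.call(rbind, rows)
  if (is.null(cycles))
    cycles <- data.frame(id = integer(), dose = integer(),
                         dose_value = numeric(), cycle = integer(),
                         max_grade = integer(), cat = integer(),
                         nttp = numeric(), dlt = integer())
  structure(list(patients = patients, cycles = cycles,
                 n_cycles = as.integer(n_cycles)), class = "toxdata")
}

# engine state stub for direct decide_dose calls
make_state <- function(current_dose = 1L, any_dlt = FALSE,
                       dose_values = c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0),
                       n_cycles = 3L, n_enrolled = 0L, consec = 3L) {
  list(current_dose = current_dose, any_dlt = any_dlt,
       dose_values = dose_values, n_cycles = n_cycles,
       n_enrolled = n_enrolled, consec = consec)
}

# deterministic stub policy design for engine and calibration tests
stub_design <- function(policy, name = "stub") {
  structure(list(name = name, policy = policy, tau = 0.391,
                 prior = c(1, 1)),
            class = c("stub_design", "latetox_design"))
}
assign("decide_dose.stub_design",
       function(design, data, state, ...) {
         list(dose = design$policy(state), suspend = FALSE)
       }, envir = globalenv())
assign("final_mtd.stub_design",
       function(design, data, admissible, ...) {
         if (length(admissible)) admissible[1] else NA_integer_
       }, envir = globalenv())

# independent keyboard oracle: explicit key enumeration + Beta masses
oracle_keyboard <- function(n_eff, events, prior, tau1, tau2) {
  w <- tau2 - tau1
  lows <- tau1
  while (lows[1] - w > 1e-12) lows <- c(lows[1] - w, lows)
  ups <- tau2
  while (ups[length(ups)] + w < 1 - 1e-12) ups <- c(ups, ups[length(ups)] + w)
  bounds <- c(0, lows, ups, 1)
  target_key <- which(abs(bounds - tau1) < 1e-12)
  a <- prior[1] + events; b <- prior[2] + n_eff - events
  mass <- diff(pbeta(bounds, a, b))
  strongest <- max(which(mass >= max(mass) - 1e-12))
  if (strongest < target_key) "escalate"
  else if (strongest == target_key) "stay" else "deescalate"
}

# brute-force weighted monotone least squares: enumerate contiguous-block
# partitions (the optimum is piecewise-constant at block means)
brute_monotone_ls <- function(y, w) {
  n <- length(y)
  best <- NULL; bestv <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cutpts <- which(bitwAnd(mask, 2^(0:(max(n - 2, 0)))) > 0)
    starts <- c(1, cutpts + 1); ends <- c(cutpts, n)
    fit <- numeric(n); ok <- TRUE; prev <- -Inf
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      m <- sum(w[idx] * y[idx]) / sum(w[idx])
      if (m < prev - 1e-12) { ok <- FALSE; break }
      fit[idx] <- m; prev <- m
    }
    if (!ok) next
    v <- sum(w * (y - fit)^2)
    if (v < bestv - 1e-12) { bestv <- v; best <- fit }
  }
  best
}
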