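#' Cumulative probability of DLT up to a given cycle
#'
#' The data-generating mechanism assumes the per-cycle DLT hazard decays
#' geometrically over cycles: the conditional probability of a first DLT in
#' cycle \eqn{s}, given no DLT before, is \eqn{p_1 \cdot \mathrm{decay}^{s-1}}.
#' The cumulative probability \eqn{p_s} of a DLT in cycles \eqn{1..s} follows
#' the recursion \eqn{p_s = p_{s-1} + (1 - p_{s-1}) \, p_1 \mathrm{decay}^{s-1}}
#' with \eqn{p_0 = 0}.  With the default decay of 1/3 and three cycles,
#' \eqn{p_3 = p_1 + (1-p_1)p_1/3 + (1-p_1)(1-p_1/3)p_1/9}; a cycle-1
#' probability of 0.3 gives a three-cycle probability of 0.391.
#'
#' @param p1 probability of DLT in cycle 1, in \[0, 1\].  Vectorised.
#' @param s cycle index (>= 1); the cumulative probability covers cycles 1..s.
#' @param decay per-cycle hazard decay factor (default 1/3).
#' @return cumulative DLT probability \eqn{p_s}, same length as `p1`.
#' @export
cumulative_dlt_prob <- function(p1, s, decay = 1/3) {
  if (any(p1 < 0 | p1 > 1)) stop("'p1' must be in [0, 1]")
  if (length(s) != 1L || s < 1 || s != round(s)) stop("'s' must be a single integer >= 1")
  p <- rep(0, length(p1))
  for (k in seq_len(s)) {
    p <- p + (1 - p) * p1 * decay^(k - 1)
  }
  p
}

#' Define a true toxicity scenario
#'
#' A scenario is the ground truth of a simulation: the dose grid, the
#' per-dose probability of DLT in cycle 1, and the hazard-decay mechanism
#' that extends those probabilities over later cycles.  Cumulative per-cycle
#' probabilities are precomputed as a doses-by-cycles matrix `ps`.
#'
#' The optional truth label records what a "correct" trial outcome is:
#' recommending a specific maximum tolerated dose (MTD), stopping because
#' every dose is too toxic, or stopping because every dose is far below the
#' target.  If `truth` is `NULL` a label is derived from the target: the MTD
#' is the highest dose whose full-follow-up DLT probability does not exceed
#' `tau`; if no dose qualifies the scenario is labelled `"all_unsafe"`.
#' The `"all_safe"` label (all doses well below target) cannot be derived
#' from probabilities alone and must be given explicitly.
#'
#' @param p1 per-dose cycle-1 DLT probabilities.
#' @param dose_values strictly increasing dose quantities (MBq).
#' @param decay per-cycle hazard decay factor.
#' @param n_cycles number of treatment cycles S in the follow-up period.
#' @param tau target probability of DLT over the whole follow-up period,
#'   used only to derive a truth label when `truth` is `NULL`.
#' @param truth either `NULL`, a list `list(type =, mtd =)`, or one of
#'   `"all_unsafe"`, `"all_safe"`, or a dose index for the MTD.
#' @param label optional scenario name.
#' @return an object of class `"scenario"`.
#' @examples
#' sc <- scenario(c(0.05, 0.05, 0.05, 0.8, 0.8, 0.8))
#' sc$ps[, 3]   # full-period DLT probability per dose
#' @export
scenario <- function(p1,
                     dose_values = c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0),
                     decay = 1/3, n_cycles = 3L, tau = 0.391,
                     truth = NULL, label = NULL) {
  if (length(p1) != length(dose_values))
    stop("'p1' and 'dose_values' must have the same length")
  if (any(p1 < 0 | p1 > 1)) stop("'p1' must be in [0, 1]")
  if (any(diff(dose_values) <= 0)) stop("'dose_values' must be strictly increasing")
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  n_cycles <- as.integer(n_cycles)
  ps <- sapply(seq_len(n_cycles), function(s) cumulative_dlt_prob(p1, s, decay))
  ps <- matrix(ps, nrow = length(p1),
               dimnames = list(NULL, paste0("cycle", seq_len(n_cycles))))
  truth <- resolve_truth(truth, ps[, n_cycles], tau)
  structure(list(p1 = p1, dose_values = dose_values, decay = decay,
                 n_cycles = n_cycles, ps = ps, tau = tau,
                 truth = truth, label = label),
            class = "scenario")
}

resolve_truth <- function(truth, p_total, tau) {
  if (is.null(truth)) {
    ok <- which(p_total <= tau + 1e-9)
    if (length(ok) == 0L) return(list(type = "all_unsafe", mtd = NA_integer_))
    return(list(type = "mtd", mtd = max(ok)))
  }
  if (is.list(truth)) {
    stopifnot(truth$type %in% c("mtd", "all_unsafe", "all_safe"))
    if (identical(truth$type, "mtd") && is.na(truth$mtd))
      stop("truth type 'mtd' needs a dose index")
    truth$mtd <- if (identical(truth$type, "mtd")) as.integer(truth$mtd) else NA_integer_
    return(truth)
  }
  if (is.character(truth)) {
    truth <- match.arg(truth, c("all_unsafe", "all_safe"))
    return(list(type = truth, mtd = NA_integer_))
  }
  list(type = "mtd", mtd = as.integer(truth))
}

#' @export
print.scenario <- function(x, ...) {
  cat("Toxicity scenario", if (!is.null(x$label)) paste0("'", x$label, "'"), "\n")
  m <- rbind(dose = x$dose_values, p1 = x$p1, p_total = x$ps[, x$n_cycles])
  colnames(m) <- paste0("d", seq_along(x$p1))
  print(round(m, 3))
  cat("decay", format(x$decay, digits = 4), "over", x$n_cycles, "cycles;",
      "target tau =", x$tau, "\n")
  cat("truth:", x$truth$type,
      if (x$truth$type == "mtd") paste0("(dose ", x$truth$mtd, ")"), "\n")
  invisible(x)
}

#' Read or write a scenario file
#'
#' Scenarios are stored as plain-text key-value files (one `key: value` pair
#' per line, vectors comma-separated), so that simulation inputs can be kept
#' under version control next to results.
#'
#' @param file path to a scenario file.
#' @rdname scenario_io
#' @return `read_scenario()` returns a `"scenario"`; `write_scenario()`
#'   returns `file` invisibly.
#' @export
read_scenario <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1]]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")), "")
  get <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) return(default)
    vals[[i]]
  }
  num <- function(key, default = NULL) {
    v <- get(key)
    if (is.null(v)) return(default)
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  }
  truth <- get("truth")
  if (!is.null(truth) && !truth %in% c("all_unsafe", "all_safe"))
    truth <- as.integer(truth)
  scenario(p1 = num("p1"),
           dose_values = num("dose_values", c(1.5, 2.5, 3.5, 4.5, 6.0, 7.0)),
           decay = num("decay", 1/3),
           n_cycles = num("n_cycles", 3),
           tau = num("tau", 0.391),
           truth = truth,
           label = get("label"))
}

#' @param x a `"scenario"` object.
#' @rdname scenario_io
#' @export
write_scenario <- function(x, file) {
  stopifnot(inherits(x, "scenario"))
  lines <- c(
    if (!is.null(x$label)) paste0("label: ", x$label),
    paste0("dose_values: ", paste(x$dose_values, collapse = ",")),
    paste0("p1: ", paste(x$p1, collapse = ",")),
    paste0("decay: ", format(x$decay, digits = 15)),
    paste0("n_cycles: ", x$n_cycles),
    paste0("tau: ", x$tau),
    paste0("truth: ", if (x$truth$type == "mtd") x$truth$mtd else x$truth$type))
  writeLines(lines, file)
  invisible(file)
}
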