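#' Generate a patient population for one simulated trial
#'
#' Each patient carries a single latent toxicity variable \eqn{z_i \sim
#' U(0,1)} that determines their DLT cycle on *every* dose, plus auxiliary
#' uniforms (one pair per cycle) used only to resolve the grade/type detail
#' that the latent variable does not pin down.  Because the whole population
#' is drawn up front from the seed alone, every design — and the empirical
#' benchmark — sees exactly the same sequence of patients for a given seed,
#' and a design's dosing choices can never perturb the outcome draws.
#'
#' @param n number of patients (the trial maximum).
#' @param n_cycles follow-up length S in cycles.
#' @param seed integer seed.
#' @return object of class `"patient_population"`: list with `latents`
#'   (length `n`), and `aux_grade`, `aux_combo` (`n` x `n_cycles` matrices).
#' @export
patient_population <- function(n, n_cycles = 3L, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  latents <- stats::runif(n)
  aux_grade <- matrix(stats::runif(n * n_cycles), n, n_cycles, byrow = TRUE)
  aux_combo <- matrix(stats::runif(n * n_cycles), n, n_cycles, byrow = TRUE)
  structure(list(latents = latents, aux_grade = aux_grade,
                 aux_combo = aux_combo, n = n, n_cycles = as.integer(n_cycles),
                 seed = seed),
            class = "patient_population")
}

#' Cycle of first DLT implied by a latent toxicity variable
#'
#' A patient with latent \eqn{z} has a DLT in the unique cycle \eqn{s} with
#' \eqn{p_{s-1} < 1 - z \le p_s} (half-open on the left, so every
#' \eqn{1 - z \le p_S} maps to exactly one cycle), and no DLT at all if
#' \eqn{1 - z > p_S}.  Smaller latents are more toxic: on a fixed dose a
#' smaller `latent` never yields a later DLT cycle.
#'
#' @param latent latent value in (0, 1).
#' @param ps non-decreasing vector of cumulative DLT probabilities
#'   \eqn{(p_1, ..., p_S)} for the dose (a row of `scenario$ps`).
#' @return integer cycle index, or `NA` if no DLT within follow-up.
#' @export
dlt_cycle <- function(latent, ps) {
  v <- 1 - latent
  if (v > ps[length(ps)]) return(NA_integer_)
  as.integer(which(v <= ps)[1])
}

#' Realised multi-cycle outcome of one patient on one dose
#'
#' Deterministic given the population draw: the latent variable fixes the
#' DLT cycle and the cycle-1 maximum grade (stacked thresholds, with smaller
#' `1 - z` mapping to higher grades); auxiliary uniforms resolve
#' (i) the maximum grade in later non-DLT cycles, drawn from the scaled
#' grade masses renormalised over survivors (grades 0-2),
#' (ii) a later DLT cycle's grade (3 or 4 with equal probability), and
#' (iii) the grade/type triple, uniform over all combinations with the
#' realised maximum.  No outcomes exist after the DLT cycle.
#'
#' @param pop a [patient_population()].
#' @param i patient index.
#' @param scn a [scenario()].
#' @param dose dose index.
#' @param weights,normalizer nTTP weight configuration (see [nttp_value()]).
#' @return list with `dlt_cycle` (`NA` if none), `cycles_on_study`,
#'   `max_grade`, `cat` (ordinal category 1/2/3), `nttp` (per observed
#'   cycle), and `grades` (cycles x 3 matrix of type grades).
#' @export
patient_outcome <- function(pop, i, scn, dose,
                            weights = nttp_weights_default(),
                            normalizer = NULL) {
  S <- scn$n_cycles
  p1 <- scn$p1[dose]
  ps <- scn$ps[dose, ]
  v <- 1 - pop$latents[i]
  dlt_s <- dlt_cycle(pop$latents[i], ps)
  n_obs <- if (is.na(dlt_s)) S else dlt_s
  gd <- grade_distribution(p1)
  combos <- grade_combinations()

  max_grade <- rep(NA_integer_, S)
  grades <- matrix(NA_integer_, S, 3,
                   dimnames = list(NULL, c("renal", "hematological", "neurological")))
  nttp <- rep(NA_real_, S)

  for (s in seq_len(n_obs)) {
    if (s == 1L) {
      # stacked thresholds from grade 4 downward: small 1-z => high grade
      cuts <- cumsum(gd[c("g4", "g3", "g2", "g1", "g0")])
      g <- c(4L, 3L, 2L, 1L, 0L)[which(v <= cuts)[1]]
    } else if (!is.na(dlt_s) && s == dlt_s) {
      g <- if (pop$aux_grade[i, s] < 0.5) 4L else 3L
    } else {
      # survivor of cycle s: grades 0-2 with conditional masses g_k/(1-p1)
      q <- gd[c("g2", "g1", "g0")] / (1 - p1)
      g <- c(2L, 1L, 0L)[which(pop$aux_grade[i, s] <= cumsum(q))[1]]
    }
    max_grade[s] <- g
    cmb <- combos[[g + 1L]]
    idx <- min(floor(pop$aux_combo[i, s] * nrow(cmb)) + 1L, nrow(cmb))
    grades[s, ] <- cmb[idx, ]
    nttp[s] <- nttp_value(grades[s, ], weights, normalizer)
  }
  list(dlt_cycle = dlt_s, cycles_on_study = n_obs,
       max_grade = max_grade,
       cat = ifelse(is.na(max_grade), NA_integer_,
                    ifelse(max_grade >= 3, 3L, ifelse(max_grade == 2, 2L, 1L))),
       nttp = nttp, grades = grades)
}
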