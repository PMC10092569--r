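#' Distribution of the maximum toxicity grade in cycle 1
#'
#' Maximum observed grades (0-4) in the first cycle follow a piecewise
#' distribution driven entirely by the cycle-1 DLT probability `p1`: grades 3
#' and 4 (the DLT grades) each carry mass `p1/2`, grade 2 carries `min(p1,
#' 1 - p1)`, and grades 1 and 0 absorb what remains, vanishing as `p1` grows:
#' \deqn{p_{1}^{G1} = (1-2p_1)\,I(2/5 < p_1 < 1/2) + (p_1/2)\,I(p_1 \le 2/5),}
#' \deqn{p_{1}^{G0} = (1 - 5p_1/2)\,I(p_1 \le 2/5).}
#' The five masses always sum to 1 and the DLT mass (grades 3+4) equals `p1`
#' exactly, so the grade mechanism is consistent with the binary DLT
#' mechanism.
#'
#' @param p1 cycle-1 DLT probability, in \[0, 1\].
#' @return named numeric vector of length 5 (`g0` to `g4`) summing to 1.
#' @examples
#' grade_distribution(0.3)   # (0.25, 0.15, 0.30, 0.15, 0.15)
#' grade_distribution(0.6)   # (0, 0, 0.40, 0.30, 0.30)
#' @export
grade_distribution <- function(p1) {
  if (length(p1) != 1L || is.na(p1) || p1 < 0 || p1 > 1)
    stop("'p1' must be a single probability in [0, 1]")
  g4 <- p1 / 2
  g3 <- p1 / 2
  g2 <- if (p1 > 1/2) 1 - p1 else p1
  g1 <- if (p1 > 2/5 && p1 < 1/2) 1 - 2 * p1 else if (p1 <= 2/5) p1 / 2 else 0
  g0 <- if (p1 <= 2/5) 1 - 5 * p1 / 2 else 0
  c(g0 = g0, g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

#' Sub-stochastic grade masses for later cycles
#'
#' For cycles after the first, the grade masses are the cycle-1 masses scaled
#' by the fraction of patients still on study at the start of the cycle,
#' \eqn{1 - p_{s-1}}: the masses of cycle \eqn{s} total \eqn{1 - p_{s-1}}
#' rather than 1, the deficit being the patients who already left the study
#' with a DLT.
#'
#' @inheritParams grade_distribution
#' @param s cycle index, 2..S (use [grade_distribution()] for cycle 1).
#' @param decay per-cycle hazard decay factor used for the survivor fraction.
#' @return named numeric vector of length 5 with total mass \eqn{1-p_{s-1}}.
#' @export
later_grade_masses <- function(p1, s, decay = 1/3) {
  if (s < 2) stop("use grade_distribution() for cycle 1")
  surv <- 1 - cumulative_dlt_prob(p1, s - 1, decay)
  surv * grade_distribution(p1)
}

#' Enumerate grade/type combinations by maximum grade
#'
#' Three toxicity types (renal, hematological, neurological), each graded
#' 0-4, give 125 grade combinations.  They are partitioned by the maximum
#' grade of the triple; within a partition every combination is equally
#' likely.  The partition sizes are \eqn{(g+1)^3 - g^3}: 1, 7, 19, 37, 61.
#'
#' @return a list of five integer matrices (max grade 0..4); each row is a
#'   (renal, hematological, neurological) triple.
#' @export
grade_combinations <- function() {
  all <- as.matrix(expand.grid(renal = 0:4, hematological = 0:4,
                               neurological = 0:4, KEEP.OUT.ATTRS = FALSE))
  mx <- pmax(all[, 1], all[, 2], all[, 3])
  lapply(0:4, function(g) all[mx == g, , drop = FALSE])
}

#' Default nTTP weight table
#'
#' The normalized total toxicity profile (nTTP) summarises a triple of
#' maximum grades into one value in \[0, 1\] via a weighted Euclidean norm.
#' The published weight values for the three toxicity types are not
#' reproduced here; the package ships a synthetic default
#' (`inst/extdata/nttp_weights_synthetic.csv`) assigning weights 0.5, 0.75,
#' 1.0, 1.5 to grades 1-4 of every type (grade 0 has weight 0), which is
#' monotone in grade and symmetric in type.  Any 3 x 5 table can be supplied
#' instead wherever an nTTP weight table is accepted.
#'
#' @return a 3 x 5 numeric matrix (types by grades 0-4).
#' @export
nttp_weights_default <- function() {
  path <- system.file("extdata", "nttp_weights_synthetic.csv",
                      package = "latetox", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  as.matrix(df)
}

#' Normalized total toxicity profile of a grade triple
#'
#' \deqn{\mathrm{nTTP}(g) = \sqrt{\sum_t w_{t, g_t}^2} \; / \; v,}
#' where the normaliser \eqn{v} defaults to the value of the numerator at the
#' worst possible triple (all types at grade 4), so that nTTP lies in
#' \[0, 1\], is 0 for an all-zero triple, and is non-decreasing in every
#' grade coordinate.
#'
#' @param grades integer triple of maximum grades (0-4), one per toxicity
#'   type, in the row order of `weights`.
#' @param weights 3 x 5 weight matrix (types by grades 0-4); defaults to
#'   [nttp_weights_default()].
#' @param normalizer positive scalar; defaults to the worst-case norm.
#' @return nTTP value in \[0, 1\].
#' @examples
#' nttp_value(c(0, 0, 0))    # 0
#' nttp_value(c(3, 2, 0))
#' @export
nttp_value <- function(grades, weights = nttp_weights_default(),
                       normalizer = NULL) {
  if (is.null(weights)) stop("an nTTP weight table is required")
  if (length(grades) != nrow(weights) || any(grades < 0 | grades > 4))
    stop("'grades' must give one grade in 0..4 per toxicity type")
  if (is.null(normalizer))
    normalizer <- sqrt(sum(weights[, 5]^2))
  w <- weights[cbind(seq_len(nrow(weights)), grades + 1L)]
  sqrt(sum(w^2)) / normalizer
}

#' Expected cycle-1 nTTP at a given cycle-1 DLT probability
#'
#' Averages the nTTP value over the cycle-1 grade mechanism: the maximum
#' grade is drawn from [grade_distribution()] and, given the maximum, the
#' grade/type triple is uniform over the combinations with that maximum.
#' Used to set the default nTTP target [tau_nttp_default()].
#'
#' @inheritParams grade_distribution
#' @inheritParams nttp_value
#' @return expected nTTP in \[0, 1\].
#' @export
expected_cycle1_nttp <- function(p1, weights = nttp_weights_default(),
                                 normalizer = NULL) {
  gd <- grade_distribution(p1)
  combos <- grade_combinations()
  means <- vapply(combos, function(m) {
    mean(apply(m, 1, nttp_value, weights = weights, normalizer = normalizer))
  }, 0)
  sum(gd * means)
}

#' Default nTTP target
#'
#' The nTTP design needs a target cycle-1 nTTP value.  None is implied by a
#' binary DLT target, so the package default is the expected cycle-1 nTTP at
#' a dose sitting exactly on the cycle-1 DLT target (0.3 by default) under
#' the synthetic grade mechanism and the configured weight table.
#'
#' @param p1_target cycle-1 DLT probability defining the on-target dose.
#' @inheritParams nttp_value
#' @return target nTTP value.
#' @export
tau_nttp_default <- function(p1_target = 0.3, weights = nttp_weights_default(),
                             normalizer = NULL) {
  expected_cycle1_nttp(p1_target, weights, normalizer)
}
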