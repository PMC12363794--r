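#' Normalize a luminescence plate to relative viability
#'
#' Each well is divided by the mean of the control wells (dose (0, 0)) of
#' its own replicate; replicates are averaged after normalization.
#' Inhibition is 1 - viability clamped into [0, 1]; the number of clamped
#' wells is reported via a message and in the returned object.
#'
#' @param plate a `plate_grid` (see [read_plate_csv()] / [plate_grid()])
#' @return object of class `viability_grid`: list with `viability` and
#'   `inhibition` (doses_a x doses_b matrices, replicate-averaged),
#'   `replicate_inhibition` (per-replicate list), `doses_a`, `doses_b`,
#'   `n_clamped`
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_grid"))
  ia0 <- which(plate$doses_a == 0)
  ib0 <- which(plate$doses_b == 0)
  n_clamped <- 0L
  viab_reps <- lapply(plate$replicates, function(m) {
    ctrl <- mean(m[ia0, ib0])
    if (!is.finite(ctrl) || ctrl <= 0) stop("control-well mean must be > 0")
    m / ctrl
  })
  inhib_reps <- lapply(viab_reps, function(v) {
    inh <- 1 - v
    n_clamped <<- n_clamped + sum(inh < 0 | inh > 1)
    inh[] <- pmin(1, pmax(0, inh))
    inh
  })
  if (n_clamped > 0) {
    message(sprintf("clamped %d inhibition value(s) into [0, 1]", n_clamped))
  }
  viability <- Reduce(`+`, viab_reps) / length(viab_reps)
  inhibition <- Reduce(`+`, inhib_reps) / length(inhib_reps)
  structure(list(viability = viability, inhibition = inhibition,
                 replicate_inhibition = inhib_reps,
                 doses_a = plate$doses_a, doses_b = plate$doses_b,
                 n_clamped = n_clamped),
            class = "viability_grid")
}

#' Bliss-independence expected inhibition of a drug combination
#'
#' Under Bliss independence two drugs act through unconnected pathways and
#' the expected combined inhibition is `e_a + e_b - e_a * e_b`.
#'
#' @param e_a,e_b monotherapy inhibition fractions in [0, 1] (vectorized)
#' @return expected combination inhibition fraction in [0, 1]
#' @export
bliss_expected <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 1 | e_b < 0 | e_b > 1)) {
    stop("inhibition fractions must lie in [0, 1]")
  }
  e_a + e_b - e_a * e_b
}

#' Bliss synergy surface and landscape summary score
#'
#' For every combination well (both doses positive), the synergy score is
#' delta = 100 x (observed inhibition - Bliss expectation from the same
#' plate's monotherapy margins), in percentage points. The landscape
#' summary is the arithmetic mean of delta over combination wells only
#' (margins are excluded; delta is identically 0 there). Delta is computed
#' per replicate and then averaged; the SD of per-replicate summaries is
#' reported.
#'
#' @param viab a `viability_grid` from [normalize_plate()]
#' @return object of class `synergy_summary`: list with `delta`
#'   (doses_a x doses_b matrix, NA on margins), `summary_score`,
#'   `replicate_summaries`, `replicate_sd`, `n_wells`
#' @export
synergy_surface <- function(viab) {
  stopifnot(inherits(viab, "viability_grid"))
  a_pos <- viab$doses_a > 0
  b_pos <- viab$doses_b > 0
  if (!any(!a_pos) || !any(!b_pos)) {
    stop("plate must contain monotherapy margins (zero dose rows/columns)")
  }
  ia0 <- which(!a_pos); ib0 <- which(!b_pos)
  delta_rep <- lapply(viab$replicate_inhibition, function(inh) {
    e_a <- inh[, ib0[1]]           # dose_b = 0 margin
    e_b <- inh[ia0[1], ]           # dose_a = 0 margin
    expected <- outer(e_a, e_b, bliss_expected)
    d <- 100 * (inh - expected)
    d[!a_pos, ] <- NA
    d[, !b_pos] <- NA
    d
  })
  rep_summ <- vapply(delta_rep, function(d) mean(d, na.rm = TRUE), numeric(1))
  delta <- Reduce(`+`, delta_rep) / length(delta_rep)
  structure(list(delta = delta,
                 summary_score = mean(delta, na.rm = TRUE),
                 replicate_summaries = rep_summ,
                 replicate_sd = if (length(rep_summ) > 1) stats::sd(rep_summ) else NA_real_,
                 n_wells = sum(!is.na(delta)),
                 doses_a = viab$doses_a, doses_b = viab$doses_b),
            class = "synergy_summary")
}

#' @param x a `synergy_summary`
#' @param ... unused
#' @method print synergy_summary
#' @export
print.synergy_summary <- function(x, ...) {
  cat(sprintf("Bliss synergy summary: %.2f points over %d combination wells\n",
              x$summary_score, x$n_wells))
  if (!is.na(x$replicate_sd)) {
    cat(sprintf("  replicate summaries: %s (SD %.2f)\n",
                paste(sprintf("%.2f", x$replicate_summaries), collapse = ", "),
                x$replicate_sd))
  }
  invisible(x)
}
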