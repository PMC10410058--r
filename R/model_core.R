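# Analytic minimal model of senescence spread from a single cell:
# ligand capture probabilities, annulus spread rates, Poisson-binomial
# spread classification and phase-boundary scans.

#' Cumulative ligand binding-distance probability
#'
#' Probability that a paracrine ligand has bound (and been internalised) within
#' distance `r` of the emitting cell: `P(r) = r / (r + a)` with capture length
#' `a = 1.1 * DL / (nu * keff)`. With `koff = 0` (`nu = 1`) this reduces to the
#' first-binding law.
#'
#' @param r Distance from the emitter centre (cm); vectorised.
#' @param d A [derive_compound_params()] object.
#' @return Probabilities in `[0, 1)`.
#' @export
cumulative_binding_probability <- function(r, d) {
  stopifnot(inherits(d, "derived_params"))
  if (any(r < 0)) stop("r must be >= 0")
  r / (r + d$a)
}

#' Autocrine trajectory probability
#'
#' Probability that a ligand ends up bound to the cell that emitted it.
#'
#' @param d A [derive_compound_params()] object.
#' @param internalized If `TRUE` (default) return the internalisation variant
#'   `nu*Da / (nu*Da + 4/pi)`; otherwise the first-binding variant
#'   `Da / (Da + 4/pi)`.
#' @return A probability.
#' @export
autocrine_probability <- function(d, internalized = TRUE) {
  stopifnot(inherits(d, "derived_params"))
  if (internalized) d$Pau_in else d$Pau
}

# shared denominator for the annulus/per-cell capture kernels; the
# telescoping-exact form (r+a)^2 - rcell^2 conserves probability across
# contiguous annuli; paper_denominator = TRUE selects the alternative
# literal reading r^2 - rcell^2 + 2*a*rcell + a^2.
capture_denominator <- function(r, a, rcell, paper_denominator = FALSE) {
  if (paper_denominator) r^2 - rcell^2 + 2 * a * rcell + a^2
  else (r + a)^2 - rcell^2
}

#' Probability of a ligand binding in an annulus of width 2*rcell
#'
#' For an annulus of width `2*rcell` centred at distance `r` from the emitter,
#' the binding probability per emitted ligand is the telescoped difference of
#' the cumulative law at `r +/- rcell`, discounted by the autocrine fraction:
#' `(1 - Pau) * 2*a*rcell / ((r + a)^2 - rcell^2)`.
#'
#' @inheritParams cumulative_binding_probability
#' @param rcell Cell radius (cm).
#' @param paper_denominator Use the alternative flattened-text denominator
#'   `r^2 - rcell^2 + 2*a*rcell + a^2` (compatibility only; breaks exact
#'   telescoping).
#' @return Probabilities; vectorised over `r`.
#' @export
annulus_binding_probability <- function(r, d, rcell,
                                        paper_denominator = FALSE) {
  stopifnot(inherits(d, "derived_params"))
  if (any(r <= rcell)) stop("annulus overlaps emitter: need r > rcell")
  (1 - d$Pau_in) * 2 * d$a * rcell /
    capture_denominator(r, d$a, rcell, paper_denominator)
}

#' Probability of a ligand binding to one specific cell at distance r
#'
#' The annulus probability scaled by the area of one cell relative to the
#' annulus (`pi*rcell^2 / (4*pi*r*rcell) = rcell / (4*r)`):
#' `(1 - Pau) * a * rcell^2 / (2 * r * ((r + a)^2 - rcell^2))`.
#'
#' @inheritParams annulus_binding_probability
#' @return Probabilities; vectorised over `r`.
#' @export
per_cell_binding_probability <- function(r, d, rcell,
                                         paper_denominator = FALSE) {
  stopifnot(inherits(d, "derived_params"))
  if (any(r <= rcell)) stop("annulus overlaps emitter: need r > rcell")
  (1 - d$Pau_in) * d$a * rcell^2 /
    (2 * r * capture_denominator(r, d$a, rcell, paper_denominator))
}

#' Expected ligands bound per hour by a cell at distance r
#'
#' `lambda(r) = NE * per_cell_binding_probability(r)`; linear in the emission
#' rate `NE`, valid under the steady-state assumption that diffusion is much
#' faster than the signalling timescales.
#'
#' @param r Distance (cm); vectorised.
#' @param p A [kinetic_params()] object.
#' @param d Matching [derive_compound_params()] object.
#' @return Expected bound ligands per hour.
#' @export
expected_ligands_bound <- function(r, p, d) {
  stopifnot(inherits(p, "kinetic_params"))
  p$NE * per_cell_binding_probability(r, d, p$rcell)
}

#' Hourly senescence-induction probability for one cell at distance r
#'
#' A cell becomes senescent in an hour in which it binds at least `ND`
#' ligands. With `NE` emitted ligands as trials and the per-cell binding
#' probability as success probability, the hourly induction probability is the
#' binomial survival function `P[X >= ND]`, evaluated with the numerically
#' stable tail of [stats::pbinom()].
#'
#' @inheritParams expected_ligands_bound
#' @return Rate of senescence induction (h^-1); vectorised over `r`.
#' @export
induction_rate_per_cell <- function(r, p, d) {
  stopifnot(inherits(p, "kinetic_params"))
  pc <- per_cell_binding_probability(r, d, p$rcell)
  if (any(pc < 0 | pc > 1)) stop("per-cell binding probability outside [0,1]")
  binomial_tail(p$ND, p$NE, pc)
}

# P[X >= ND] for X ~ Binomial(NE, prob), tolerating non-integer ND
binomial_tail <- function(ND, NE, prob) {
  k <- ceiling(ND)
  if (k <= 0) return(rep_len(1, length(prob)))
  stats::pbinom(k - 1, size = NE, prob = prob, lower.tail = FALSE)
}

# P[X >= ND] for X ~ Poisson(lambda), tolerating non-integer ND
poisson_tail <- function(ND, lambda) {
  k <- ceiling(ND)
  if (k <= 0) return(rep_len(1, length(lambda)))
  stats::ppois(k - 1, lambda = lambda, lower.tail = FALSE)
}

#' Senescence spread rate from one emitter into an annulus
#'
#' An annulus of width `2*rcell` at distance `r` has area `4*pi*r*rcell` and
#' therefore contains on average `m(r) = 4*sigma*r/rcell` cells; the annulus
#' spread rate is `m(r)` times the per-cell induction rate.
#'
#' @inheritParams expected_ligands_bound
#' @return Rate (h^-1) of creating a senescent cell in the annulus.
#' @export
annulus_spread_rate <- function(r, p, d) {
  m <- 4 * p$sigma * r / p$rcell
  m * induction_rate_per_cell(r, p, d)
}

#' Probability of at least one induction in an annulus within time t
#'
#' `1 - exp(-lambda_spread(r) * t)`: one minus the Poisson-process probability
#' of no induction event in the window.
#'
#' @inheritParams expected_ligands_bound
#' @param t Time window (h).
#' @return Probabilities; vectorised over `r`.
#' @export
prob_spread_by_time <- function(r, t, p, d) {
  if (any(t < 0)) stop("t must be >= 0")
  -expm1(-annulus_spread_rate(r, p, d) * t)
}

#' Annulus grid around an emitting cell
#'
#' Contiguous annuli of width `2*rcell` with inner edge at `r_start`;
#' centre of annulus `k` (1-based) is `r_start + (k - 1/2) * 2*rcell`.
#'
#' @param r_start Inner radius of the first annulus (cm); must exceed `rcell`.
#' @param rcell Cell radius (cm).
#' @param n_annuli Number of annuli.
#' @return An object of class `annulus_grid` with fields `r_start`, `width`,
#'   `n_annuli` and `centers`.
#' @export
annulus_grid <- function(r_start, rcell, n_annuli = 50) {
  if (n_annuli < 1) stop("empty grid: n_annuli must be >= 1")
  width <- 2 * rcell
  centers <- r_start + (seq_len(n_annuli) - 0.5) * width
  if (any(centers <= rcell))
    stop("annulus centers must lie outside the emitting cell")
  structure(list(r_start = r_start, width = width, n_annuli = n_annuli,
                 centers = centers),
            class = "annulus_grid")
}

#' Probability of spread to at least one annulus
#'
#' The per-annulus events are independent Bernoulli trials with unequal
#' probabilities; the probability that at least one succeeds is the upper tail
#' of their Poisson-binomial law, `1 - prod(1 - p_k)`, evaluated in log space.
#'
#' @param grid An [annulus_grid()].
#' @param t Time window (h).
#' @inheritParams expected_ligands_bound
#' @param threshold Spread classification threshold on `p_spread`.
#' @return An object of class `spread_result`: `p_spread`, `per_annulus_p`,
#'   `classification` (`"spreads"` or `"contained"`) and `window`.
#' @export
prob_any_annulus_spread <- function(grid, t, p, d, threshold = 0.99) {
  stopifnot(inherits(grid, "annulus_grid"))
  pk <- prob_spread_by_time(grid$centers, t, p, d)
  p_spread <- -expm1(sum(log1p(-pk)))
  structure(list(p_spread = p_spread, per_annulus_p = pk,
                 classification = if (p_spread >= threshold) "spreads"
                                  else "contained",
                 window = t),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("Spread probability over %g h window: %.4g -> %s\n",
              x$window, x$p_spread, x$classification))
  invisible(x)
}

#' Classify whether senescence spread from a single cell is uncontrollable
#'
#' Builds the annulus grid of the minimal model, starting at the mean
#' cell-to-cell distance `r1 = sqrt(pi*rcell^2/sigma)`, or at `r2 = 2*r1`
#' when a ring of non-emitting juxtacrine senescent cells surrounds the
#' emitter, and evaluates the Poisson-binomial probability of at least one
#' induction within the window (2 days by default). Spread is classified as
#' uncontrollable (`"spreads"`) when that probability reaches `threshold`.
#'
#' @param p A [kinetic_params()] object.
#' @param juxtacrine_ring Account for a ring of SASP-null juxtacrine
#'   senescent cells around the emitter.
#' @param window Observation window (h); the body is assumed to remove a lone
#'   senescent cell within about 2 days.
#' @param threshold Probability treated as "~1" (default 0.99).
#' @param n_annuli Annuli in the grid (contributions decay as 1/r^3).
#' @param d Optional pre-computed [derive_compound_params()].
#' @return A `spread_result` (see [prob_any_annulus_spread()]) with the grid
#'   attached as attribute `"grid"`.
#' @export
classify_spread <- function(p, juxtacrine_ring = FALSE, window = 48,
                            threshold = 0.99, n_annuli = 50, d = NULL) {
  stopifnot(inherits(p, "kinetic_params"))
  if (is.null(d)) d <- derive_compound_params(p)
  r1 <- sqrt(pi * p$rcell^2 / p$sigma)
  first_center <- if (juxtacrine_ring) 2 * r1 else r1
  # first annulus centred on the mean cell-to-cell distance
  grid <- annulus_grid(first_center - p$rcell, p$rcell, n_annuli)
  res <- prob_any_annulus_spread(grid, window, p, d, threshold)
  attr(res, "grid") <- grid
  res
}

#' Phase boundary between spread and containment in the ND-Rtot plane
#'
#' For each receptor count, finds the largest induction threshold `ND` for
#' which senescence is still classified as spreading, by bisection over the
#' monotone classification (if spread occurs at `ND` it occurs at `ND - 1`).
#'
#' @param Rtot_values Receptor counts to scan.
#' @param base A [kinetic_params()] object providing every other parameter.
#' @param variants Named list of variants; each entry is a list with optional
#'   kinetic overrides (`ke`, `koff`, `sigma`, ...) and an optional logical
#'   `juxtacrine_ring`. Default: one variant named `"base"` with no overrides.
#' @param ND_max Upper bound of the search range.
#' @inheritParams classify_spread
#' @return A data.frame with columns `variant`, `Rtot`, `ND_boundary`
#'   (0 when not even `ND = 1` spreads).
#' @export
phase_boundary_scan <- function(Rtot_values, base,
                                variants = list(base = list()),
                                ND_max = 1000, window = 48, threshold = 0.99,
                                n_annuli = 50) {
  stopifnot(inherits(base, "kinetic_params"))
  rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    ring <- isTRUE(v$juxtacrine_ring)
    ov <- v[setdiff(names(v), "juxtacrine_ring")]
    for (Rtot in Rtot_values) {
      args <- utils::modifyList(unclass(base), c(ov, list(Rtot = Rtot)))
      pp <- do.call(kinetic_params, args)
      dd <- derive_compound_params(pp)
      spreads_at <- function(ND) {
        pp$ND <- ND
        classify_spread(pp, juxtacrine_ring = ring, window = window,
                        threshold = threshold, n_annuli = n_annuli,
                        d = dd)$classification == "spreads"
      }
      nd <- if (!spreads_at(1)) 0L else {
        lo <- 1L                      # spreads
        hi <- as.integer(ND_max) + 1L # treat as not spreading
        while (hi - lo > 1L) {
          mid <- (lo + hi) %/% 2L
          if (spreads_at(mid)) lo <- mid else hi <- mid
        }
        lo
      }
      rows[[length(rows) + 1L]] <-
        data.frame(variant = vn, Rtot = Rtot, ND_boundary = nd)
    }
  }
  do.call(rbind, rows)
}
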