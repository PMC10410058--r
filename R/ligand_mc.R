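# Particle-based validation of the ligand-capture law: Brownian ligands over
# a cell-covered plane under a reflecting media surface.

#' Place cells on a monolayer tile
#'
#' Non-overlapping discs of radius `rcell` at area fraction `sigma` on a
#' square tile, either by random sequential adsorption or on a square lattice
#' with spacing `sqrt(pi*rcell^2/sigma)`. The tile is treated as periodic by
#' the Brownian simulator, so a moderate tile represents an unbounded
#' monolayer. The emitter is the cell closest to the tile centre.
#'
#' @param sigma Target area fraction (must be attainable without overlap,
#'   roughly `sigma < 0.5` for random placement).
#' @param rcell Cell radius (cm).
#' @param domain_size Tile side length (cm).
#' @param mode `"random"` (random sequential adsorption) or `"lattice"`.
#' @param h Media height above the monolayer (cm). The default 0.8 cm is an
#'   order of magnitude above the capture length at mid-range parameters, so
#'   the reflecting ceiling does not compress the far tail of the
#'   binding-distance distribution (the analytic capture law assumes
#'   effectively unbounded media).
#' @return An object of class `monolayer_geometry`: `cell_centers` (two-column
#'   matrix, cm), `emitter_index`, `rcell`, `sigma` (realised), `domain_size`,
#'   `h`.
#' @export
place_cells <- function(sigma, rcell, domain_size, mode = c("random", "lattice"),
                        h = 0.8) {
  mode <- match.arg(mode)
  if (sigma < 0) stop("sigma must be >= 0")
  n_target <- max(1L, round(sigma * domain_size^2 / (pi * rcell^2)))
  if (mode == "lattice") {
    spacing <- sqrt(pi * rcell^2 / sigma)
    nside <- max(1L, floor(domain_size / spacing))
    g <- (seq_len(nside) - 0.5) * spacing
    centers <- as.matrix(expand.grid(x = g, y = g))
  } else {
    centers <- rsa_discs(n_target, rcell, domain_size)
  }
  realized <- nrow(centers) * pi * rcell^2 / domain_size^2
  emitter <- which.min((centers[, 1] - domain_size / 2)^2 +
                       (centers[, 2] - domain_size / 2)^2)
  structure(list(cell_centers = centers, emitter_index = emitter,
                 rcell = rcell, sigma = realized, domain_size = domain_size,
                 h = h, mode = mode),
            class = "monolayer_geometry")
}

# random sequential adsorption of n discs of radius rcell in [0, L]^2 with
# periodic boundary; errors if the target density is unreachable
rsa_discs <- function(n, rcell, L, max_tries = 200L) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  min2 <- (2 * rcell)^2
  tries <- 0L
  while (placed < n) {
    cx <- stats::runif(1, 0, L); cy <- stats::runif(1, 0, L)
    ok <- TRUE
    if (placed > 0L) {
      dx <- abs(xs[seq_len(placed)] - cx); dx <- pmin(dx, L - dx)
      dy <- abs(ys[seq_len(placed)] - cy); dy <- pmin(dy, L - dy)
      ok <- all(dx * dx + dy * dy >= min2)
    }
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries * n)
        stop("sigma too high for non-overlapping placement")
    }
  }
  cbind(x = xs, y = ys)
}

#' Simulate ligand trajectories by Brownian dynamics
#'
#' Each ligand starts just above the emitter centre, takes Gaussian steps,
#' reflects from the media surface at `z = h` and from the bare dish, and on
#' contact with a cell is captured with the Robin-boundary probability
#' `p_abs = kappa * sqrt(pi * dt / DL)`. Captured ligands internalise with
#' probability `nu`, otherwise they dissociate and continue; the final
#' (internalised) binding location is recorded.
#'
#' @param geom A [place_cells()] geometry.
#' @param d A [derive_compound_params()] object (supplies `kappa`, `nu`).
#' @param n Number of trajectories.
#' @param DL Diffusion coefficient (cm^2/s).
#' @param dt Near-surface time step (s); must satisfy
#'   `sqrt(2*DL*dt) <= rcell/10`. Default: the largest allowed step.
#' @param t_max Timeout (s); default `100*a^2/DL`, long enough that the
#'   escaped fraction is a fraction of a percent so the far tail of the
#'   binding-distance distribution is not truncated.
#' @param release `"uniform"` (default) releases each ligand from a uniform
#'   point on the emitter disc surface, matching the surface-emission
#'   assumption behind the capture law; `"center"` releases from the disc
#'   centre (slightly inflates the autocrine fraction).
#' @return A data.frame of class `trajectory_outcomes` with columns `fate`
#'   (`"bound_internalized"`, `"autocrine"`, `"escaped_timeout"`),
#'   `final_distance` (cm), `first_binding_time` (s), `n_binding_events`.
#' @export
simulate_trajectories <- function(geom, d, n, DL = 1e-6, dt = NULL,
                                  t_max = NULL,
                                  release = c("uniform", "center")) {
  stopifnot(inherits(geom, "monolayer_geometry"),
            inherits(d, "derived_params"))
  release <- match.arg(release)
  dt_lim <- geom$rcell^2 / (200 * DL)
  if (is.null(dt)) dt <- dt_lim
  if (sqrt(2 * DL * dt) > geom$rcell / 10 * (1 + 1e-12))
    stop("dt violates the resolution condition sqrt(2*DL*dt) <= rcell/10")
  if (is.null(t_max)) t_max <- 100 * d$a^2 / DL
  res <- .ligand_walk_cpp(geom$cell_centers[, 1], geom$cell_centers[, 2],
                          geom$rcell, geom$domain_size,
                          geom$emitter_index - 1L,
                          DL, d$kappa_cms, d$nu, geom$h,
                          as.integer(n), dt, t_max,
                          release == "uniform")
  out <- data.frame(
    fate = c("bound_internalized", "autocrine",
             "escaped_timeout")[res$fate + 1L],
    final_distance = res$final_distance,
    first_binding_time = res$first_binding_time,
    n_binding_events = res$n_binding_events,
    stringsAsFactors = FALSE)
  class(out) <- c("trajectory_outcomes", class(out))
  out
}

#' Empirical paracrine binding-distance CDF
#'
#' Distribution of final binding distances over paracrine (non-autocrine)
#' internalised trajectories, for comparison with the analytic law
#' `P(r) = r / (r + a)`.
#'
#' @param outcomes A [simulate_trajectories()] result.
#' @param min_bound Minimum number of paracrine bound outcomes required.
#' @return A `stats::ecdf` function with attribute `"n"` (outcomes used).
#' @export
binding_distance_cdf <- function(outcomes, min_bound = 1000) {
  dists <- outcomes$final_distance[outcomes$fate == "bound_internalized"]
  if (length(dists) < min_bound)
    stop("too few paracrine bound outcomes: ", length(dists),
         " < ", min_bound)
  f <- stats::ecdf(dists)
  attr(f, "n") <- length(dists)
  f
}

#' Maximum relative error of the analytic capture law against simulation
#'
#' Compares the empirical paracrine binding-distance CDF with the analytic
#' cumulative law over a central quantile range (the near-field zone close to
#' the emitter, where the homogenised boundary approximation is weakest, lies
#' below the default lower quantile).
#'
#' @param outcomes A [simulate_trajectories()] result.
#' @param d A [derive_compound_params()] object.
#' @param probs Quantile range of the empirical distribution to compare over.
#' @param n_eval Evaluation points across the range.
#' @return List with `max_rel_error`, the evaluation grid `r`, `empirical`
#'   and `analytic` CDF values.
#' @export
capture_law_relative_error <- function(outcomes, d, probs = c(0.1, 0.9),
                                       n_eval = 50) {
  cdf <- binding_distance_cdf(outcomes)
  dists <- outcomes$final_distance[outcomes$fate == "bound_internalized"]
  qs <- stats::quantile(dists, probs, names = FALSE)
  r <- seq(qs[1], qs[2], length.out = n_eval)
  emp <- cdf(r)
  ana <- cumulative_binding_probability(r, d)
  list(max_rel_error = max(abs(emp - ana) / ana), r = r,
       empirical = emp, analytic = ana)
}

#' Regression check that ligand capture is diffusion-limited
#'
#' For paracrine trajectories, regresses mean first-binding time (binned by
#' final distance) on squared distance; in a diffusion-limited process the
#' relation is linear through the origin with slope of order `1/DL`.
#'
#' @param outcomes A [simulate_trajectories()] result.
#' @param n_bins Distance bins.
#' @return List with `slope` (s/cm^2), `r_squared`, and the binned data
#'   (`dist2`, `mean_time`).
#' @export
diffusion_timing_check <- function(outcomes, n_bins = 12) {
  keep <- outcomes$fate == "bound_internalized" &
    is.finite(outcomes$first_binding_time)
  if (!any(keep)) stop("no bound outcomes with first_binding_time")
  dd <- outcomes$final_distance[keep]
  tt <- outcomes$first_binding_time[keep]
  br <- stats::quantile(dd, seq(0, 1, length.out = n_bins + 1), names = FALSE)
  bin <- cut(dd, unique(br), include.lowest = TRUE)
  d2 <- tapply(dd^2, bin, mean)
  mt <- tapply(tt, bin, mean)
  fit <- stats::lm(mt ~ d2)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       dist2 = as.numeric(d2), mean_time = as.numeric(mt))
}
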