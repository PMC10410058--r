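# Forward model of the seeded-circle experiment, summary statistics and
# ABC-SMC inference of the signalling parameters (NE, ND, Rtot, kon).

#' Design of the seeded-lesion experiment
#'
#' A disc of primary senescent cells of radius `rseed` is seeded at the centre
#' of a dish and the fraction of cells becoming senescent is scored at a set
#' of distances from the lesion centre. The experiment is stopped before the
#' maturation delay so that only the first wave of paracrine induction (from
#' the seeded cells alone) is observed.
#'
#' @param rseed Radius of the seeded lesion (cm). The default 0.1 cm (1 mm)
#'   matches the scale of seeded-circle experiments in which secondary
#'   senescence is observed about 1 mm from the seeded cells, and places the
#'   senescent front well beyond the capture length, where the flux kernel is
#'   most sensitive to the trapping parameters.
#' @param duration Experiment duration (h); must be shorter than the
#'   maturation delay.
#' @param delay Maturation delay (h), used only to check the first-wave
#'   condition.
#' @param eval_distances Increasing distances from the lesion centre (cm) at
#'   which the senescent fraction is scored. Default: 20 points between
#'   `rseed + 2*rcell_hint` and `6*rseed`, with half of them packed densely
#'   around the anticipated half-crossing distance `S_anticipated` so the
#'   position, slope and sharpness of the senescent front are all resolved
#'   (the front carries essentially all the information about the signalling
#'   parameters).
#' @param S_anticipated Anticipated half-crossing distance (cm) used only to
#'   place the dense default points; in practice this comes from a pilot run
#'   of the forward model at the literature parameter estimates.
#' @param cells_per_distance Cells scored per distance when sampling a
#'   synthetic observation.
#' @param rcell_hint Cell radius (cm), used only for the default distances.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(rseed = 0.1, duration = 120, delay = 144,
                              eval_distances = NULL,
                              cells_per_distance = 200,
                              rcell_hint = 10e-4, S_anticipated = 0.26) {
  if (duration >= delay)
    stop("first-wave condition violated: duration must be < delay")
  if (is.null(eval_distances)) {
    lo <- rseed * (1 + 2 * rcell_hint / rseed)
    eval_distances <- sort(unique(c(
      exp(seq(log(lo), log(0.88 * S_anticipated), length.out = 5)),
      seq(0.9 * S_anticipated, 1.12 * S_anticipated, length.out = 10),
      exp(seq(log(1.18 * S_anticipated), log(6 * rseed), length.out = 5)))))
  }
  if (any(diff(eval_distances) <= 0) || any(eval_distances <= 0))
    stop("eval_distances must be positive and increasing")
  structure(list(rseed = rseed, duration = duration, delay = delay,
                 eval_distances = eval_distances,
                 cells_per_distance = cells_per_distance),
            class = "experiment_design")
}

# capture kernel of one emitting cell: expected ligands bound per emitted
# ligand by a test cell at distance x (telescoping-exact denominator)
capture_kernel <- function(x, d, rcell) {
  (1 - d$Pau_in) * d$a * rcell^2 / (2 * x * ((x + d$a)^2 - rcell^2))
}

#' Expected hourly ligand flux onto a test cell from the seeded disc
#'
#' Integrates the per-cell capture kernel against the areal emission density
#' `NE * sigma / (pi * rcell^2)` of the seeded disc by adaptive quadrature
#' (relative tolerance `tol`). In polar coordinates centred on the test
#' cell, circles of radius `s` intersect the seeded disc over a half-angle
#' `phi(s) = acos((s^2 + r^2 - rseed^2) / (2 s r))`, which collapses the
#' area integral to the smooth one-dimensional integral
#' `int 2 phi(s) kernel(s) s ds` over `s` in `[r - rseed, r + rseed]` — well
#' behaved even when the evaluation point sits just outside the lesion edge,
#' where the kernel is sharply peaked.
#'
#' @param r Distance of the test cell from the lesion centre (cm); must
#'   exceed `rseed + rcell`.
#' @param design An [experiment_design()].
#' @param p A [kinetic_params()] object.
#' @param d Matching [derive_compound_params()].
#' @param tol Relative tolerance of the quadrature.
#' @return Expected ligands bound per hour (scalar; vectorised over `r`).
#' @export
disc_flux_integral <- function(r, design, p, d, tol = 1e-6) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(p, "kinetic_params"))
  if (any(r <= design$rseed + p$rcell))
    stop("evaluation point inside (or touching) the lesion")
  areal <- p$NE * p$sigma / (pi * p$rcell^2)
  R <- design$rseed
  vapply(r, function(ri) {
    f <- function(s) {
      cphi <- (s^2 + ri^2 - R^2) / (2 * s * ri)
      2 * acos(pmin(pmax(cphi, -1), 1)) * capture_kernel(s, d, p$rcell) * s
    }
    areal * stats::integrate(f, ri - R, ri + R, rel.tol = tol,
                             subdivisions = 400L)$value
  }, 0)
}

# fast fixed-order evaluation of the same disc flux, used inside the ABC
# forward model. Polar coordinates centred on the test cell reduce the area
# integral to a smooth 1D integral: circles of radius s around the test
# point intersect the seeded disc over half-angle
# phi(s) = acos((s^2 + r^2 - rseed^2) / (2 s r)), so
# flux = areal * int_{r-rseed}^{r+rseed} 2 phi(s) kernel(s) s ds.
disc_flux_gl <- local({
  cache <- list()
  function(r, design, p, d, n_s = 96) {
    key <- as.character(n_s)
    if (is.null(cache[[key]]))
      cache[[key]] <<- pracma::gaussLegendre(n_s, -1, 1)
    g <- cache[[key]]
    areal <- p$NE * p$sigma / (pi * p$rcell^2)
    R <- design$rseed
    # affine map of the reference nodes to [ri - R, ri + R] for each ri
    s <- outer(R * g$x, r, "+")                       # n_s x length(r)
    r2 <- matrix(r, n_s, length(r), byrow = TRUE)
    cphi <- (s^2 + r2^2 - R^2) / (2 * s * r2)
    phi <- acos(pmin(pmax(cphi, -1), 1))
    vals <- 2 * phi * capture_kernel(s, d, p$rcell) * s
    areal * R * as.vector(g$w %*% vals)
  }
})

#' Expected fraction of senescent cells versus distance
#'
#' For each evaluation distance: the bound-ligand count per hour is Poisson
#' with the disc-flux mean, the hourly induction probability is the Poisson
#' tail `P[N >= ND]`, and the probability of induction by the end of the
#' experiment compounds over whole hours,
#' `F = 1 - (1 - p_hour)^duration` (the continuous-compounding alternative
#' `1 - exp(-p_hour * duration)` is available via `compounding`).
#'
#' @inheritParams disc_flux_integral
#' @param compounding `"discrete"` (default) or `"exponential"`.
#' @param quadrature `"gauss"` (fast fixed-order, default) or `"adaptive"`.
#' @return Vector of expected senescent fractions at `design$eval_distances`.
#' @export
fraction_senescent_curve <- function(design, p, d = NULL,
                                     compounding = c("discrete",
                                                     "exponential"),
                                     quadrature = c("gauss", "adaptive")) {
  compounding <- match.arg(compounding)
  quadrature <- match.arg(quadrature)
  if (is.null(d)) d <- derive_compound_params(p)
  flux <- if (quadrature == "gauss")
    disc_flux_gl(design$eval_distances, design, p, d)
  else disc_flux_integral(design$eval_distances, design, p, d)
  p_hour <- poisson_tail(p$ND, flux)
  if (design$duration == 0) return(rep(0, length(p_hour)))
  if (compounding == "discrete") 1 - (1 - p_hour)^design$duration
  else -expm1(-p_hour * design$duration)
}

#' Summary statistics of a fraction-versus-distance curve
#'
#' `S` is the distance at which the senescent fraction first crosses 0.5
#' going outward (linear interpolation between grid points). When the curve
#' never crosses: all below 0.5 gives `S` = the first evaluation distance,
#' all above gives the last; the convention used is flagged.
#'
#' @param F Senescent fractions aligned with `design$eval_distances`.
#' @param design An [experiment_design()].
#' @return An object of class `summary_stats`: `S` (cm), `F`, and
#'   `S_convention` (`"crossing"`, `"all_below"`, `"all_above"`).
#' @export
summary_stats <- function(F, design) {
  x <- design$eval_distances
  if (length(F) == 0L) stop("empty fraction vector")
  if (length(F) != length(x))
    stop("F must align with design$eval_distances")
  conv <- "crossing"
  if (all(F < 0.5)) {
    S <- x[1]; conv <- "all_below"
  } else if (all(F >= 0.5)) {
    S <- x[length(x)]; conv <- "all_above"
  } else {
    i <- which(F[-length(F)] >= 0.5 & F[-1] < 0.5)[1]
    if (is.na(i)) {                      # non-monotone edge case
      i <- max(which(F >= 0.5))
      if (i == length(F)) i <- i - 1L
    }
    S <- x[i] + (0.5 - F[i]) * (x[i + 1] - x[i]) / (F[i + 1] - F[i])
  }
  structure(list(S = S, F = F, S_convention = conv), class = "summary_stats")
}

#' Sample a synthetic observation of the seeded-lesion experiment
#'
#' Draws the observed senescent fraction at each distance as
#' `Binomial(cells_per_distance, F_model) / cells_per_distance` and computes
#' the summary statistics, emulating the cell-counting noise of the proposed
#' experiment.
#'
#' @param design An [experiment_design()].
#' @param true_params A [kinetic_params()] object (the ground truth).
#' @param seed RNG seed for reproducibility.
#' @return A `summary_stats` object with attribute `"model_F"` (the
#'   noise-free curve).
#' @export
generate_synthetic_observation <- function(design, true_params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Fm <- fraction_senescent_curve(design, true_params)
  n <- design$cells_per_distance
  Fobs <- stats::rbinom(length(Fm), n, Fm) / n
  out <- summary_stats(Fobs, design)
  attr(out, "model_F") <- Fm
  out
}

#' Distance between two summary-statistic pairs
#'
#' `d = sqrt(d1^2 + d2^2)` with `d1 = S_model - S_data` and `d2` the
#' Euclidean norm of the difference of the fraction vectors.
#'
#' @param model,data `summary_stats` objects on the same distance grid.
#' @return Non-negative scalar.
#' @export
stat_distance <- function(model, data) {
  if (length(model$F) != length(data$F))
    stop("mismatched distance grids")
  d1 <- model$S - data$S
  d2 <- sqrt(sum((model$F - data$F)^2))
  sqrt(d1^2 + d2^2)
}

#' Uniform priors over the inferred signalling parameters
#'
#' Independent uniform ranges for the four parameters inferred from the
#' seeded-lesion experiment. Defaults: `Rtot` over its literature range
#' 1e4-1e6 (two decades, genuinely unknown); `kon` within a factor ~2 of the
#' literature point estimate 1e8 M^-1 min^-1; `NE` around the
#' IL-6/IL-8/Activin-A emission estimate; `ND` broad (the quantity the
#' experiment is designed to pin down). Note the capture model depends on
#' `Rtot` and `kon` only through their product (the trapping rate constant),
#' so the relative widths of these two priors decide which of the pair the
#' data can identify.
#'
#' @param NE,ND,Rtot,kon Length-2 numeric ranges `c(min, max)`.
#' @return A data.frame of class `abc_priors` with columns `param`, `min`,
#'   `max`.
#' @export
abc_priors <- function(NE = c(500, 5000), ND = c(1, 100),
                       Rtot = c(1e4, 1e6), kon = c(8e7, 1.25e8)) {
  pr <- data.frame(param = c("NE", "ND", "Rtot", "kon"),
                   min = c(NE[1], ND[1], Rtot[1], kon[1]),
                   max = c(NE[2], ND[2], Rtot[2], kon[2]),
                   stringsAsFactors = FALSE)
  if (any(pr$max <= pr$min)) stop("invalid prior range")
  class(pr) <- c("abc_priors", class(pr))
  pr
}

# forward model: summary stats at a parameter vector theta = (NE, ND, Rtot, kon)
forward_stats <- function(theta, design, base) {
  p <- base
  p$NE <- theta[["NE"]]; p$ND <- theta[["ND"]]
  p$Rtot <- theta[["Rtot"]]; p$kon <- theta[["kon"]]
  d <- derive_compound_params(p)
  summary_stats(fraction_senescent_curve(design, p, d), design)
}

#' ABC-SMC inference of signalling parameters from a seeded-lesion observation
#'
#' Sequential approximate Bayesian computation: population 0 is sampled from
#' the priors; each subsequent population resamples accepted particles by
#' weight, perturbs them with a multivariate Gaussian kernel whose covariance
#' is twice the weighted covariance of the previous population, and accepts
#' proposals whose summary-statistic distance to the observation falls below
#' an epsilon adapted as the `quantile` of the previous population's accepted
#' distances. Importance weights follow the standard SMC correction; priors
#' are uniform, so weights reduce to the inverse kernel mixture density.
#'
#' @param design An [experiment_design()].
#' @param observed A `summary_stats` observation.
#' @param priors An [abc_priors()] data.frame.
#' @param base A [kinetic_params()] object supplying the fixed parameters.
#' @param n_particles Particles per population.
#' @param n_populations Number of populations (including population 0).
#' @param quantile Epsilon adaptation quantile of accepted distances. The
#'   default 0.2 is aggressive so that a desk-scale schedule (6 populations)
#'   reaches the observation noise floor; raise towards 0.5 when running many
#'   populations.
#' @param max_attempts Proposal budget per population; exceeded with zero
#'   acceptances aborts with a diagnostic.
#' @param seed RNG seed.
#' @return An object of class `abc_posterior`: `particles` (data.frame with
#'   the four parameters, `weight`, `distance`, `population`), `epsilon`
#'   (schedule), `acceptance` (fractions), `priors`, `n_particles`.
#' @export
abc_smc <- function(design, observed, priors = abc_priors(),
                    base = kinetic_params(), n_particles = 200,
                    n_populations = 6, quantile = 0.2,
                    max_attempts = 50 * n_particles, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pn <- priors$param
  npar <- length(pn)
  lo <- stats::setNames(priors$min, pn)
  hi <- stats::setNames(priors$max, pn)

  sample_prior <- function() stats::setNames(stats::runif(npar, lo, hi), pn)
  in_prior <- function(th) all(th >= lo & th <= hi)

  dist_of <- function(th)
    stat_distance(forward_stats(th, design, base), observed)

  # population 0: plain prior sampling, all particles kept
  theta <- t(vapply(seq_len(n_particles), function(i) sample_prior(),
                    numeric(npar)))
  colnames(theta) <- pn
  dists <- apply(theta, 1, dist_of)
  w <- rep(1 / n_particles, n_particles)
  eps_hist <- numeric(0)
  acc_hist <- 1
  store <- list(data.frame(theta, weight = w, distance = dists,
                           population = 0))

  for (pop in seq_len(n_populations - 1)) {
    eps <- stats::quantile(dists, quantile, names = FALSE)
    eps_hist <- c(eps_hist, eps)
    Sig <- 2 * stats::cov.wt(theta, wt = w)$cov
    Sig <- Sig + diag(1e-12 * pmax(diag(Sig), (hi - lo)^2 * 1e-12))
    ch <- chol(Sig)
    new_theta <- matrix(NA_real_, n_particles, npar,
                        dimnames = list(NULL, pn))
    new_d <- numeric(n_particles)
    accepted <- 0L
    attempts <- 0L
    while (accepted < n_particles) {
      if (attempts >= max_attempts) {
        if (accepted == 0L)
          stop("ABC-SMC: zero acceptances in population ", pop,
               " at epsilon ", signif(eps, 4))
        # fill remaining slots by resampling what was accepted
        idx <- sample.int(accepted, n_particles - accepted, replace = TRUE)
        new_theta[(accepted + 1):n_particles, ] <-
          new_theta[idx, , drop = FALSE]
        new_d[(accepted + 1):n_particles] <- new_d[idx]
        accepted <- n_particles
        break
      }
      attempts <- attempts + 1L
      j <- sample.int(n_particles, 1L, prob = w)
      prop <- theta[j, ] + drop(stats::rnorm(npar) %*% ch)
      if (!in_prior(prop)) next
      dd <- dist_of(prop)
      if (dd <= eps) {
        accepted <- accepted + 1L
        new_theta[accepted, ] <- prop
        new_d[accepted] <- dd
      }
    }
    # importance weights: uniform prior / kernel mixture density
    new_w <- vapply(seq_len(n_particles), function(i) {
      diff <- sweep(theta, 2, new_theta[i, ])
      z <- forwardsolve(t(ch), t(diff))
      dens <- exp(-0.5 * colSums(z^2)) /
        ((2 * pi)^(npar / 2) * prod(diag(ch)))
      1 / sum(w * dens)
    }, 0)
    new_w <- new_w / sum(new_w)
    theta <- new_theta; dists <- new_d; w <- new_w
    acc_hist <- c(acc_hist, n_particles / attempts)
    store[[pop + 1]] <- data.frame(theta, weight = w, distance = dists,
                                   population = pop)
  }
  structure(list(particles = do.call(rbind, store), epsilon = eps_hist,
                 acceptance = acc_hist, priors = priors,
                 n_particles = n_particles),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  last <- x$particles[x$particles$population ==
                        max(x$particles$population), ]
  cat(sprintf("ABC-SMC posterior: %d populations x %d particles\n",
              max(x$particles$population) + 1, x$n_particles))
  cat("  epsilon schedule:", paste(signif(x$epsilon, 3), collapse = " > "),
      "\n")
  for (pm in x$priors$param) {
    ci <- weighted_quantile(last[[pm]], last$weight, c(0.025, 0.5, 0.975))
    cat(sprintf("  %-5s median %.4g  95%% CI [%.4g, %.4g]\n",
                pm, ci[2], ci[1], ci[3]))
  }
  invisible(x)
}

#' Weighted quantiles of a particle set
#'
#' @param x Values.
#' @param w Weights (need not be normalised).
#' @param probs Quantile probabilities.
#' @return Quantile values.
#' @export
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], 0)
}

#' Central credible interval and relative width of a posterior marginal
#'
#' @param posterior An [abc_smc()] result.
#' @param param Parameter name.
#' @param level Credibility level.
#' @return List with `lower`, `upper`, `median` and `relative_width`
#'   (interval width divided by the prior range).
#' @export
posterior_interval <- function(posterior, param, level = 0.95) {
  last <- posterior$particles[posterior$particles$population ==
                                max(posterior$particles$population), ]
  a <- (1 - level) / 2
  q <- weighted_quantile(last[[param]], last$weight, c(a, 0.5, 1 - a))
  pr <- posterior$priors[posterior$priors$param == param, ]
  list(lower = q[1], upper = q[3], median = q[2],
       relative_width = (q[3] - q[1]) / (pr$max - pr$min))
}
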