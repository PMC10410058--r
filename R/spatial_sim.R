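# Event-driven stochastic simulation of senescence spread from a lesion:
# Gillespie sampling of paracrine induction with delayed maturation,
# juxtacrine fire-break rules and secondary-SASP scaling.

#' Configuration for the spatial senescence-spread simulation
#'
#' @param domain Square side length in units of `rcell` (default 100).
#' @param kinetic A [kinetic_params()] object.
#' @param lesion Lesion specification: `list(radius = r_cm)` seeds every cell
#'   whose centre lies within `r_cm` of the domain centre, or
#'   `list(ids = c(...))` seeds explicit cell ids.
#' @param delay Maturation delay between induction and full senescence (h);
#'   default 144 (6 days).
#' @param juxtacrine_enabled Do fully senescent cells induce juxtacrine
#'   senescence in contacting neighbours?
#' @param juxtacrine_timing `"at_maturation"` (neighbours are induced when the
#'   inducer becomes fully senescent) or `"at_induction"` (the dynamic-SASP
#'   limiting case: juxtacrine capability precedes the SASP, so neighbours are
#'   induced the moment the inducer starts transitioning).
#' @param paracrine_secondary_juxtacrine Can paracrine secondary senescent
#'   cells induce juxtacrine senescence in their neighbours (tertiary
#'   induction)? Juxtacrine secondaries never can.
#' @param secondary_sasp_scale Multiplier in `[0, 1]` on `NE` for paracrine
#'   secondary senescent cells (primaries emit at scale 1; juxtacrine
#'   secondaries do not emit).
#' @param contact_radius Contact distance for juxtacrine induction, as a
#'   multiplier on `rcell` (centre-to-centre; default 2.2, i.e. touching discs
#'   with 10% tolerance).
#' @param t_max Simulation horizon (h).
#' @param placement `"random"` (random sequential adsorption) or `"lattice"`.
#' @param seed Optional RNG seed recorded in the config; [simulate_spread()]
#'   applies it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(domain = 100, kinetic = kinetic_params(),
                       lesion = list(radius = 5 * kinetic$rcell),
                       delay = 144,
                       juxtacrine_enabled = TRUE,
                       juxtacrine_timing = c("at_maturation", "at_induction"),
                       paracrine_secondary_juxtacrine = FALSE,
                       secondary_sasp_scale = 1,
                       contact_radius = 2.2,
                       t_max = 168,
                       placement = c("random", "lattice"),
                       seed = NULL) {
  stopifnot(inherits(kinetic, "kinetic_params"))
  juxtacrine_timing <- match.arg(juxtacrine_timing)
  placement <- match.arg(placement)
  if (delay < 0) stop("delay must be >= 0")
  if (secondary_sasp_scale < 0 || secondary_sasp_scale > 1)
    stop("secondary_sasp_scale must lie in [0, 1]")
  if (contact_radius < 2)
    stop("contact_radius must be >= 2 (non-overlapping discs touch at 2)")
  structure(list(domain = domain, kinetic = kinetic, lesion = lesion,
                 delay = delay, juxtacrine_enabled = juxtacrine_enabled,
                 juxtacrine_timing = juxtacrine_timing,
                 paracrine_secondary_juxtacrine = paracrine_secondary_juxtacrine,
                 secondary_sasp_scale = secondary_sasp_scale,
                 contact_radius = contact_radius, t_max = t_max,
                 placement = placement, seed = seed),
            class = "sim_config")
}

#' Initialise the cell population for a spread simulation
#'
#' Places cells on the simulation domain and seeds the primary senescent
#' lesion at time 0 (state `senescent`, mechanism `primary`, SASP scale 1);
#' all other cells start `normal`.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame of class `cell_population` with columns `id`, `x`,
#'   `y` (cm), `state`, `mechanism`, `t_induced`, `t_mature`, `sasp_scale`.
#' @export
initialize_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$kinetic
  side <- cfg$domain * k$rcell
  geom <- place_cells(k$sigma, k$rcell, side, mode = cfg$placement)
  n <- nrow(geom$cell_centers)
  pop <- data.frame(id = seq_len(n),
                    x = geom$cell_centers[, 1], y = geom$cell_centers[, 2],
                    state = "normal", mechanism = "none",
                    t_induced = NA_real_, t_mature = NA_real_,
                    sasp_scale = 0, stringsAsFactors = FALSE)
  if (!is.null(cfg$lesion$ids)) {
    seed_ids <- cfg$lesion$ids
    if (!all(seed_ids %in% pop$id)) stop("lesion ids outside population")
  } else {
    r <- sqrt((pop$x - side / 2)^2 + (pop$y - side / 2)^2)
    seed_ids <- pop$id[r <= cfg$lesion$radius]
  }
  if (length(seed_ids) == 0L) stop("lesion specification selects no cells")
  pri <- pop$id %in% seed_ids
  pop$state[pri] <- "senescent"
  pop$mechanism[pri] <- "primary"
  pop$t_induced[pri] <- 0
  pop$t_mature[pri] <- 0
  pop$sasp_scale[pri] <- 1
  class(pop) <- c("cell_population", class(pop))
  attr(pop, "side") <- side
  pop
}

#' Poisson induction rate of one normal cell given the current emitters
#'
#' The bound-ligand count of a cell is approximated as Poisson with mean equal
#' to the sum of the single-emitter means `sasp_scale_i * NE * p_cell(r_i)`;
#' the hourly induction rate is the Poisson survival probability
#' `P[Pois(lambda_tot) >= ND]`.
#'
#' @param cell Row index of the (normal) cell in `population`.
#' @param population A [initialize_population()] data.frame.
#' @param kinetic A [kinetic_params()] object.
#' @param d Matching [derive_compound_params()].
#' @return Rate (h^-1).
#' @export
per_cell_induction_rate <- function(cell, population, kinetic, d) {
  em <- population$state == "senescent" & population$sasp_scale > 0
  if (!any(em)) return(0)
  r <- sqrt((population$x[em] - population$x[cell])^2 +
            (population$y[em] - population$y[cell])^2)
  lam <- sum(population$sasp_scale[em] * kinetic$NE *
             per_cell_binding_probability(r, d, kinetic$rcell))
  poisson_tail(kinetic$ND, lam)
}

#' One step of the Gillespie direct method
#'
#' Draws the waiting time to the next event, exponential with the total rate,
#' and the identity of the reacting cell with probability proportional to its
#' rate.
#'
#' @param rates Non-negative per-cell rates (h^-1).
#' @param t_now Current time (h).
#' @return List with `t_next` (`Inf` when the total rate is zero) and
#'   `cell` (index, `NA` when no event is possible).
#' @export
gillespie_step <- function(rates, t_now) {
  if (any(rates < 0)) stop("negative rate")
  R <- sum(rates)
  if (R <= 0 || !is.finite(R)) return(list(t_next = Inf, cell = NA_integer_))
  list(t_next = t_now + stats::rexp(1, R),
       cell = sample.int(length(rates), 1L, prob = rates))
}

# indices of normal cells in contact with `inducer`
contact_neighbors <- function(population, inducer, contact_r) {
  d2 <- (population$x - population$x[inducer])^2 +
        (population$y - population$y[inducer])^2
  which(population$state == "normal" & d2 <= contact_r^2 &
        population$id != population$id[inducer])
}

# does this cell's mechanism permit it to induce juxtacrine senescence?
juxtacrine_qualifies <- function(mechanism, cfg) {
  if (!cfg$juxtacrine_enabled) return(FALSE)
  switch(mechanism,
         primary = TRUE,
         paracrine = isTRUE(cfg$paracrine_secondary_juxtacrine),
         FALSE)   # juxtacrine secondaries never induce further juxtacrine
}

#' Apply juxtacrine induction from a newly senescent (or transitioning) cell
#'
#' Every normal cell within `contact_radius * rcell` of the inducer becomes a
#' juxtacrine secondary senescent cell: it stops being inducible, carries SASP
#' scale 0 (juxtacrine secondaries do not emit), and never induces further
#' juxtacrine senescence. Returns the population unchanged when the inducer's
#' mechanism does not qualify.
#'
#' @param inducer Row index of the inducing cell.
#' @param population A `cell_population` data.frame.
#' @param cfg A [sim_config()].
#' @param t Event time (h).
#' @return List with `population` (updated) and `induced` (row indices of the
#'   newly juxtacrine-induced neighbours, possibly empty).
#' @export
apply_juxtacrine <- function(inducer, population, cfg, t = 0) {
  if (!juxtacrine_qualifies(population$mechanism[inducer], cfg))
    return(list(population = population, induced = integer()))
  nb <- contact_neighbors(population, inducer,
                          cfg$contact_radius * cfg$kinetic$rcell)
  if (length(nb)) {
    population$state[nb] <- "transitioning"
    population$mechanism[nb] <- "juxtacrine"
    population$t_induced[nb] <- t
    population$t_mature[nb] <- t + cfg$delay
    population$sasp_scale[nb] <- 0
  }
  list(population = population, induced = nb)
}

#' Run the delayed-reaction stochastic simulation
#'
#' Main loop of the spread simulator. Paracrine induction events are drawn by
#' the Gillespie direct method from the current per-cell Poisson-tail rates;
#' whenever a pending maturation precedes the candidate event, the maturing
#' cell is promoted first (activating its SASP and, under
#' `juxtacrine_timing = "at_maturation"`, inducing its contacting
#' neighbours), the candidate draw is discarded and rates are recomputed from
#' the maturation time — valid because the system is Markovian.
#'
#' @param population A [initialize_population()] data.frame.
#' @param cfg The matching [sim_config()].
#' @param stop_after Stop after this many paracrine induction events
#'   (default unlimited); used for spread/no-spread replicate studies.
#' @return List of class `spread_sim`: `population` (final states), `events`
#'   (data.frame `t`, `cell_id`, `event`, `mechanism`), `t_end`, `config`.
#' @export
advance_with_delays <- function(population, cfg, stop_after = Inf) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$kinetic
  d <- derive_compound_params(k)
  n <- nrow(population)
  ev_t <- numeric(0); ev_id <- integer(0)
  ev_type <- character(0); ev_mech <- character(0)
  log_event <- function(t, id, type, mech) {
    ev_t[length(ev_t) + 1L] <<- t
    ev_id[length(ev_id) + 1L] <<- id
    ev_type[length(ev_type) + 1L] <<- type
    ev_mech[length(ev_mech) + 1L] <<- mech
  }

  lam <- numeric(n)  # per-cell Poisson mean from all active emitters
  add_emitter <- function(i, scale) {
    if (scale <= 0) return(invisible())
    r <- sqrt((population$x - population$x[i])^2 +
              (population$y - population$y[i])^2)
    r[i] <- Inf
    lam <<- lam + scale * k$NE *
      per_cell_binding_probability(pmax(r, 2 * k$rcell), d, k$rcell)
    invisible()
  }

  do_juxtacrine <- function(i, t) {
    res <- apply_juxtacrine(i, population, cfg, t)
    population <<- res$population
    for (j in res$induced) log_event(t, population$id[j],
                                     "induced_juxtacrine", "juxtacrine")
    invisible()
  }

  # t = 0: primaries are fully senescent, emit, and induce juxtacrine
  primaries <- which(population$mechanism == "primary")
  for (i in primaries) add_emitter(i, population$sasp_scale[i])
  for (i in primaries) do_juxtacrine(i, 0)

  t <- 0
  n_inductions <- 0L
  repeat {
    normal <- population$state == "normal"
    rates <- numeric(n)
    rates[normal] <- poisson_tail(k$ND, lam[normal])
    step <- gillespie_step(rates, t)

    trans <- which(population$state == "transitioning")
    t_mat <- if (length(trans)) min(population$t_mature[trans]) else Inf

    if (t_mat <= min(step$t_next, cfg$t_max)) {
      # maturation precedes the candidate induction: promote, discard draw
      i <- trans[which.min(population$t_mature[trans])]
      t <- t_mat
      population$state[i] <- "senescent"
      log_event(t, population$id[i], "matured", population$mechanism[i])
      add_emitter(i, population$sasp_scale[i])
      if (cfg$juxtacrine_timing == "at_maturation") do_juxtacrine(i, t)
      next
    }
    if (!is.finite(step$t_next) || step$t_next > cfg$t_max) break

    # commit the paracrine induction
    t <- step$t_next
    i <- step$cell
    population$state[i] <- "transitioning"
    population$mechanism[i] <- "paracrine"
    population$t_induced[i] <- t
    population$t_mature[i] <- t + cfg$delay
    population$sasp_scale[i] <- cfg$secondary_sasp_scale
    log_event(t, population$id[i], "induced_paracrine", "paracrine")
    if (cfg$juxtacrine_timing == "at_induction") do_juxtacrine(i, t)
    n_inductions <- n_inductions + 1L
    if (n_inductions >= stop_after) break
  }

  events <- data.frame(t = ev_t, cell_id = ev_id, event = ev_type,
                       mechanism = ev_mech, stringsAsFactors = FALSE)
  events <- events[order(events$t, seq_len(nrow(events))), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(population = population, events = events, t_end = t,
                 config = cfg),
            class = "spread_sim")
}

#' Initialise and run a spread simulation
#'
#' Convenience wrapper: applies `cfg$seed` (if any), builds the population and
#' runs [advance_with_delays()].
#'
#' @param cfg A [sim_config()].
#' @param stop_after Passed to [advance_with_delays()].
#' @return A `spread_sim` object.
#' @export
simulate_spread <- function(cfg, stop_after = Inf) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- initialize_population(cfg)
  advance_with_delays(pop, cfg, stop_after = stop_after)
}

#' @export
print.spread_sim <- function(x, ...) {
  tab <- table(factor(x$population$mechanism,
                      levels = c("primary", "paracrine", "juxtacrine")))
  cat(sprintf("Spread simulation: %d cells, t_end = %.2f h\n",
              nrow(x$population), x$t_end))
  cat(sprintf("  primary %d | paracrine %d | juxtacrine %d | events %d\n",
              tab[1], tab[2], tab[3], nrow(x$events)))
  invisible(x)
}

#' Summarise a spread simulation
#'
#' Cumulative counts of induced cells by mechanism at query times (a cell
#' counts from its induction time), plus a radial histogram of senescent and
#' transitioning cells by distance from the lesion centroid.
#'
#' @param sim A [simulate_spread()] result.
#' @param times Query times (h).
#' @param n_bins Radial bins.
#' @return List with `counts` (data.frame `t`, `primary`, `paracrine`,
#'   `juxtacrine`, `total`) and `radial` (data.frame `r_mid`, `count`).
#' @export
summarize_spread <- function(sim, times = NULL, n_bins = 20) {
  pop <- sim$population
  if (is.null(times)) times <- seq(0, sim$t_end, length.out = 25)
  cum_count <- function(mech, t)
    sum(pop$mechanism == mech & !is.na(pop$t_induced) & pop$t_induced <= t)
  counts <- data.frame(
    t = times,
    primary = vapply(times, function(t) cum_count("primary", t), 0),
    paracrine = vapply(times, function(t) cum_count("paracrine", t), 0),
    juxtacrine = vapply(times, function(t) cum_count("juxtacrine", t), 0))
  counts$total <- counts$primary + counts$paracrine + counts$juxtacrine
  sen <- pop$state != "normal"
  pri <- pop$mechanism == "primary"
  cx <- mean(pop$x[pri]); cy <- mean(pop$y[pri])
  r <- sqrt((pop$x[sen] - cx)^2 + (pop$y[sen] - cy)^2)
  br <- seq(0, max(r) * 1.0001 + 1e-12, length.out = n_bins + 1)
  h <- hist(r, breaks = br, plot = FALSE)
  list(counts = counts,
       radial = data.frame(r_mid = h$mids, count = h$counts))
}

#' Cross-validate the stochastic simulation against the minimal model
#'
#' For a lattice-placed single-emitter scenario with juxtacrine induction off
#' and no maturation delay, compares the fraction of simulation replicates in
#' which at least one cell is induced within the window against the minimal
#' model's analytic spread probability, for each induction threshold `ND`.
#'
#' @param base A [kinetic_params()] object (its `ND` is overridden).
#' @param ND_values Induction thresholds to sweep.
#' @param n_reps Replicates per grid point (the study uses 100).
#' @param window Observation window (h).
#' @param domain Domain side in cell radii.
#' @param placement `"lattice"` or `"random"`.
#' @return Data.frame with `ND`, `p_model` (analytic), `p_empirical`,
#'   `n_reps`, and `deviation_se` (difference in binomial standard-error
#'   units, computed at the analytic probability).
#' @export
compare_to_minimal <- function(base, ND_values, n_reps = 100, window = 48,
                               domain = 100, placement = "lattice") {
  stopifnot(inherits(base, "kinetic_params"))
  out <- lapply(ND_values, function(nd) {
    k <- base; k$ND <- nd
    p_model <- classify_spread(k, juxtacrine_ring = FALSE,
                               window = window)$p_spread
    spread <- logical(n_reps)
    for (rep in seq_len(n_reps)) {
      cfg <- sim_config(domain = domain, kinetic = k,
                        lesion = list(ids = NA), delay = 0,
                        juxtacrine_enabled = FALSE, t_max = window,
                        placement = placement)
      pop <- initialize_population_single_center(cfg)
      sim <- advance_with_delays(pop, cfg, stop_after = 1)
      spread[rep] <- any(sim$events$event == "induced_paracrine")
    }
    p_emp <- mean(spread)
    se <- sqrt(p_model * (1 - p_model) / n_reps)
    dev <- if (se > 0) (p_emp - p_model) / se
           else if (p_emp == p_model) 0 else Inf
    data.frame(ND = nd, p_model = p_model, p_empirical = p_emp,
               n_reps = n_reps, deviation_se = dev)
  })
  do.call(rbind, out)
}

# population with the single cell nearest the domain centre as the lesion
initialize_population_single_center <- function(cfg) {
  side <- cfg$domain * cfg$kinetic$rcell
  cfg$lesion <- list(radius = side)        # placeholder; replaced below
  pop <- local({
    k <- cfg$kinetic
    geom <- place_cells(k$sigma, k$rcell, side, mode = cfg$placement)
    n <- nrow(geom$cell_centers)
    data.frame(id = seq_len(n),
               x = geom$cell_centers[, 1], y = geom$cell_centers[, 2],
               state = "normal", mechanism = "none",
               t_induced = NA_real_, t_mature = NA_real_,
               sasp_scale = 0, stringsAsFactors = FALSE)
  })
  ctr <- which.min((pop$x - side / 2)^2 + (pop$y - side / 2)^2)
  pop$state[ctr] <- "senescent"
  pop$mechanism[ctr] <- "primary"
  pop$t_induced[ctr] <- 0
  pop$t_mature[ctr] <- 0
  pop$sasp_scale[ctr] <- 1
  class(pop) <- c("cell_population", class(pop))
  attr(pop, "side") <- side
  pop
}
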