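# Event-driven stochastic spread simulation.

test_that("population initialisation seeds the lesion and hits the density", {
  k <- mid_params(ND = 62)
  cfg <- sim_config(domain = 100, kinetic = k,
                    lesion = list(radius = 5 * k$rcell), seed = 1)
  set.seed(1)
  pop <- initialize_population(cfg)
  expected_n <- 0.35 * (100 * k$rcell)^2 / (pi * k$rcell^2)
  expect_lt(abs(nrow(pop) - expected_n) / expected_n, 0.02)
  expect_true(all(pop$mechanism[pop$state == "senescent"] == "primary"))
  expect_true(all(pop$sasp_scale[pop$mechanism == "primary"] == 1))
  expect_gt(sum(pop$state == "senescent"), 0)

  cfg0 <- sim_config(domain = 30, kinetic = k, lesion = list(radius = 0))
  set.seed(1)
  expect_error(initialize_population(cfg0), "no cells")
  cfg_ids <- sim_config(domain = 30, kinetic = k, lesion = list(ids = 7))
  set.seed(1)
  pop_ids <- initialize_population(cfg_ids)
  expect_identical(which(pop_ids$state == "senescent"), 7L)
})

test_that("per-cell induction rate sums emitter Poisson means", {
  k <- mid_params(ND = 10)
  d <- derive_compound_params(k)
  pop <- tiny_population(k$rcell)
  expect_equal(per_cell_induction_rate(2, tiny_population(k$rcell)[-1, ],
                                       k, d), 0)  # no emitters
  # single emitter: the Poisson tail at lambda(r)
  r2 <- sqrt((pop$x[2] - pop$x[1])^2 + (pop$y[2] - pop$y[1])^2)
  lam2 <- expected_ligands_bound(r2, k, d)
  expect_equal(per_cell_induction_rate(2, pop, k, d),
               stats::ppois(9, lam2, lower.tail = FALSE))
  # two emitters: tail of the summed mean, against a Monte-Carlo oracle
  pop2 <- pop
  pop2$state[5] <- "senescent"; pop2$mechanism[5] <- "paracrine"
  pop2$sasp_scale[5] <- 1
  r25 <- sqrt((pop$x[2] - pop$x[5])^2 + (pop$y[2] - pop$y[5])^2)
  lam_tot <- lam2 + expected_ligands_bound(r25, k, d)
  rate <- per_cell_induction_rate(2, pop2, k, d)
  expect_equal(rate, stats::ppois(9, lam_tot, lower.tail = FALSE))
  set.seed(9)
  draws <- stats::rpois(1e5, lam2) +
    stats::rpois(1e5, expected_ligands_bound(r25, k, d))
  mc <- mean(draws >= 10)
  se <- sqrt(rate * (1 - rate) / 1e5)
  expect_lt(abs(mc - rate), 3 * se + 1e-12)
})

test_that("gillespie_step draws exponential times and rate-weighted cells", {
  set.seed(5)
  s <- gillespie_step(c(0.7, 0), 2)
  expect_identical(s$cell, 1L)
  expect_identical(gillespie_step(c(0, 0), 0)$t_next, Inf)
  expect_error(gillespie_step(c(-1, 1), 0), "negative")
  set.seed(6)
  lam <- 0.37
  waits <- replicate(1e4, gillespie_step(lam, 0)$t_next)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("event log respects the senescence state machine", {
  k <- mid_params(ND = 62)
  cfg <- sim_config(domain = 100, kinetic = k,
                    lesion = list(radius = 10 * k$rcell), delay = 144,
                    juxtacrine_enabled = TRUE,
                    paracrine_secondary_juxtacrine = TRUE,
                    t_max = 200, seed = 13)
  sim <- simulate_spread(cfg)
  ev <- sim$events
  expect_true(all(diff(ev$t) >= 0))
  ind <- ev[startsWith(ev$event, "induced"), ]
  expect_false(any(duplicated(ind$cell_id)))   # each cell induced once
  # maturation exactly delay after induction
  mat <- ev[ev$event == "matured", ]
  for (i in seq_len(nrow(mat))) {
    t_ind <- ind$t[ind$cell_id == mat$cell_id[i]]
    expect_equal(mat$t[i], t_ind + 144, tolerance = 1e-9)
  }
  # secondary SASP cannot act before the first maturation at t = delay
  expect_true(all(mat$t >= 144))
  pop <- sim$population
  expect_true(all(pop$state %in% c("normal", "transitioning", "senescent")))
  expect_true(all(pop$sasp_scale[pop$mechanism == "juxtacrine"] == 0))
})

test_that("juxtacrine induction converts contacting normal neighbours only", {
  k <- mid_params()
  cfg <- sim_config(domain = 30, kinetic = k, lesion = list(ids = 1),
                    contact_radius = 2.2)
  pop <- tiny_population(k$rcell)
  # cell 2 at 3 rcell is out of contact (2.2 rcell): nothing happens
  res <- apply_juxtacrine(1, pop, cfg, t = 0)
  expect_length(res$induced, 0)
  # widen the contact radius: cells 2 (3 rcell) and 3 (3.6 rcell) are caught
  cfg4 <- sim_config(domain = 30, kinetic = k, lesion = list(ids = 1),
                     contact_radius = 4)
  res4 <- apply_juxtacrine(1, pop, cfg4, t = 2)
  expect_setequal(res4$induced, c(2L, 3L))
  expect_true(all(res4$population$mechanism[res4$induced] == "juxtacrine"))
  expect_true(all(res4$population$sasp_scale[res4$induced] == 0))
  # juxtacrine cells never induce further juxtacrine senescence
  pop_j <- res4$population
  expect_length(apply_juxtacrine(2, pop_j, cfg4, t = 3)$induced, 0)
  # paracrine secondaries induce only when the tertiary flag is on
  pop_p <- pop; pop_p$mechanism[1] <- "paracrine"
  expect_length(apply_juxtacrine(1, pop_p, cfg4, t = 0)$induced, 0)
  cfg4t <- cfg4; cfg4t$paracrine_secondary_juxtacrine <- TRUE
  expect_gt(length(apply_juxtacrine(1, pop_p, cfg4t, t = 0)$induced), 0)
})

test_that("summaries are cumulative and partition by mechanism", {
  k <- mid_params(ND = 62)
  cfg <- sim_config(domain = 100, kinetic = k,
                    lesion = list(radius = 10 * k$rcell), delay = 0,
                    juxtacrine_enabled = TRUE,
                    paracrine_secondary_juxtacrine = TRUE,
                    t_max = 48, seed = 2)
  sim <- simulate_spread(cfg)
  s <- summarize_spread(sim, times = c(0, 2, 5, 10, 20, 48))
  for (col in c("primary", "paracrine", "juxtacrine", "total"))
    expect_true(all(diff(s$counts[[col]]) >= 0))
  expect_equal(s$counts$total,
               s$counts$primary + s$counts$paracrine + s$counts$juxtacrine)
  expect_equal(sum(s$radial$count), sum(sim$population$state != "normal"))
})

test_that("delay = 0 collapses maturation onto induction", {
  k <- mid_params(ND = 62)
  cfg <- sim_config(domain = 60, kinetic = k,
                    lesion = list(radius = 10 * k$rcell), delay = 0,
                    juxtacrine_enabled = FALSE, t_max = 24, seed = 3)
  sim <- simulate_spread(cfg)
  ev <- sim$events
  ind <- ev[ev$event == "induced_paracrine", ]
  mat <- ev[ev$event == "matured", ]
  expect_equal(sort(ind$t), sort(mat$t[mat$cell_id %in% ind$cell_id]))
})

test_that("SASP-null secondaries keep the lesion bounded over a lifespan", {
  k <- mid_params(ND = 25)
  cfg <- sim_config(domain = 100, kinetic = k,
                    lesion = list(radius = 3 * k$rcell), delay = 0,
                    juxtacrine_enabled = TRUE,
                    paracrine_secondary_juxtacrine = TRUE,
                    secondary_sasp_scale = 0, t_max = 5e5, seed = 4)
  sim <- simulate_spread(cfg)
  n_sen <- sum(sim$population$state != "normal")
  expect_gt(n_sen, sum(sim$population$mechanism == "primary"))  # some spread
  expect_lt(n_sen, 0.05 * nrow(sim$population))                 # but bounded
})

test_that("tau-leap oracle reproduces the first-event distribution", {
  # 5-cell fixture: constant rates until the first event, so the empirical
  # first-event CDF must match a fine-timestep Bernoulli-chain oracle
  k <- mid_params(ND = 6)
  d <- derive_compound_params(k)
  pop <- tiny_population(k$rcell)
  cfg <- sim_config(domain = 100, kinetic = k, lesion = list(ids = 1),
                    delay = 144, juxtacrine_enabled = FALSE, t_max = 60)
  rates <- vapply(2:5, function(i) per_cell_induction_rate(i, pop, k, d), 0)
  R <- sum(rates)
  expect_gt(R, 1e-4)   # fixture is active
  set.seed(8)
  first <- replicate(500, {
    sim <- advance_with_delays(pop, cfg, stop_after = 1)
    if (nrow(sim$events)) sim$events$t[1] else Inf
  })
  dt <- 0.01
  oracle_cdf <- function(t) 1 - (1 - R * dt)^(t / dt)   # Bernoulli chain
  for (tq in c(5, 15, 40)) {
    p_or <- oracle_cdf(tq)
    se <- sqrt(p_or * (1 - p_or) / 500)
    expect_lt(abs(mean(first <= tq) - p_or), 3 * se)
  }
})
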