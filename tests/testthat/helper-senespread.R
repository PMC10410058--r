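# Shared fixtures. The Brownian run is expensive, so one mid-range simulation
# is computed lazily and reused across ligand-capture tests.

.fixtures <- new.env(parent = emptyenv())

# mid-range kinetic parameters (sigma 0.35, Rtot 1e5, ke = koff = 0.2/min)
mid_params <- function(...) kinetic_params(...)

std_mc <- function() {
  if (is.null(.fixtures$mc)) {
    p <- mid_params()
    d <- derive_compound_params(p)
    set.seed(101)
    geom <- place_cells(p$sigma, p$rcell, 200 * p$rcell, mode = "random")
    out <- simulate_trajectories(geom, d, n = 6000, DL = p$DL)
    .fixtures$mc <- list(p = p, d = d, geom = geom, out = out)
  }
  .fixtures$mc
}

# five-cell population: one central emitter, four normal cells at fixed
# positions (distances chosen a few cell radii out)
tiny_population <- function(rcell = 10e-4) {
  pop <- data.frame(id = 1:5,
                    x = rcell * c(50, 53, 47, 50, 56),
                    y = rcell * c(50, 50, 52, 55, 44),
                    state = c("senescent", rep("normal", 4)),
                    mechanism = c("primary", rep("none", 4)),
                    t_induced = c(0, rep(NA_real_, 4)),
                    t_mature = c(0, rep(NA_real_, 4)),
                    sasp_scale = c(1, 0, 0, 0, 0),
                    stringsAsFactors = FALSE)
  class(pop) <- c("cell_population", class(pop))
  pop
}
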