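# Shared fixtures, built once per test run. The toy genome plants 8
# in-range SbfI-EcoRI fragments, 3 short, 1 long, 4 near-canonical SbfI
# sites, 2 SbfI-SbfI fragments and 1 duplicated tag; simulations run 8
# individuals at modest depth so the whole suite stays desk-scale.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

shared_toy <- function() {
  fixture("toy", function() {
    make_toy_genome(n_in_range = 8L, n_short = 3L, n_long = 1L, n_star = 4L,
                    n_bb = 2L, n_duplications = 1L, seed = 42L)
  })
}

# zero-error run: clean round trips and exact concordance
shared_run0 <- function() {
  fixture("run0", function() {
    toy <- shared_toy()
    sim <- simulate_ddrad(
      toy, cfg = population_config(n_individuals = 8L),
      reads_per_individual = 600L, error_rate = 0, seed = 7L,
      star = star_activity_model(rate_edge = 0, rate_internal = 0,
                                 chimera_rate = 0)
    )
    res <- run_ddrad_pipeline(sim$reads, sim$barcode_map, genome = sim$genome)
    list(sim = sim, res = res)
  })
}

# sequencing-error run at the paper-scale 0.1% per-base rate
shared_run_err <- function() {
  fixture("run_err", function() {
    toy <- shared_toy()
    sim <- simulate_ddrad(
      toy, cfg = population_config(n_individuals = 8L),
      reads_per_individual = 900L, error_rate = 0.001, seed = 11L,
      star = star_activity_model(rate_edge = 0, rate_internal = 0,
                                 chimera_rate = 0)
    )
    res <- run_ddrad_pipeline(sim$reads, sim$barcode_map, genome = sim$genome)
    list(sim = sim, res = res)
  })
}

# artifact-rich simulation (star activity + chimeras on, defaults)
shared_run_star <- function() {
  fixture("run_star", function() {
    toy <- fixture("toy_star", function() {
      make_toy_genome(n_in_range = 10L, n_short = 2L, n_long = 1L,
                      n_star = 24L, n_bb = 3L, n_duplications = 0L,
                      seed = 99L)
    })
    sim <- simulate_ddrad(
      toy, cfg = population_config(n_individuals = 12L),
      reads_per_individual = 800L, error_rate = 0, seed = 13L,
      star = star_activity_model(rate_edge = 0.8, rate_internal = 0.8 / 28.87,
                                 chimera_rate = 0.05)
    )
    res <- run_ddrad_pipeline(sim$reads, sim$barcode_map, genome = sim$genome,
                              screen = FALSE)
    list(toy = toy, sim = sim, res = res)
  })
}
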