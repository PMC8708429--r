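# Shared synthetic fixtures, generated once per test run.

small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, taxon_pool = 30,
             stations_per_area = c(BS = 4, AS = 4, wGF = 4, eGF = 4),
             samples_per_area = c(BS = 30, AS = 30, wGF = 40, eGF = 30),
             water_bodies_per_area = c(BS = 2, AS = 3, wGF = 3, eGF = 2),
             ...)
}

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_survey(small_cfg())
    cache
  }
})

small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_trait_pipeline(small_bundle())
    cache
  }
})

# full-size default survey (the stated monitoring design: 912 samples)
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_survey(sim_config(seed = 1))
    cache
  }
})

default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_trait_pipeline(default_bundle())
    cache
  }
})

fixture_table <- function() {
  load_trait_table(system.file("extdata", "example_trait_table.csv",
                               package = "planktraits"))
}
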