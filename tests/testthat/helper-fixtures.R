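# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small whitelist at the guaranteed-correction distance
small_whitelist <- function() {
  cached("wl_small", generate_whitelist(n = 100L, min_distance = 5L, seed = 99L))
}

# full-size array whitelist + default layout
full_whitelist <- function() {
  cached("wl_full", generate_whitelist(seed = 42L))
}

full_layout <- function() {
  cached("layout_full", array_layout(full_whitelist()))
}

# small zero-error single-species experiment used by several modules
small_sim <- function() {
  cached("sim_small", {
    cfg <- simulation_config(seed = 7L, error_rate = 0, swap_rate = 0,
                             reads_per_molecule = 1.3,
                             genes_per_species = 60L,
                             mean_meanlog = log(1.2))
    simulate_experiment(cfg, full_whitelist(), full_layout())
  })
}

# the small sim pushed through the full counting pipeline
small_sim_pipeline <- function() {
  cached("pipe_small", {
    sim <- small_sim()
    txi <- build_transcript_index(sim$transcriptome)
    run_counting_pipeline(sim$r1, sim$r2, sim$whitelist, sim$genes, txi)
  })
}

# gene ids removed by the default read filters for a given sim
filtered_gene_ids <- function(sim) {
  sim$genes$gene_id[sim$genes$is_ribosomal | sim$genes$symbol == "MALAT1"]
}
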