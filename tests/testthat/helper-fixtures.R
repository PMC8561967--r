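## Shared desk-scale fixtures, built once per test session.
## `mini_*`: a 6-well superpool on a 100 kb genome (seconds to simulate),
## used by most module tests. The full toy-preset run used by the
## acceptance tests is built lazily via toy_run().

suppressMessages(library(data.table))

mini_layout <- capss::build_layout(1, 1, 2, 3)
mini_genome <- capss::simulate_genome(1, 1e5, 1, 300, seed = 2)
mini_clones <- capss::place_clones(mini_genome, mini_layout,
                                   insert_mean = 3000, insert_sd = 800,
                                   insert_min = 1000, insert_max = 8000,
                                   seed = 3)
mini_vector <- capss::make_vector(seed = 4)
mini_index <- capss::make_index_table(mini_layout, seed = 5)
mini_truth <- capss::truth_tables(mini_clones, mini_genome)
mini_host <- local({ set.seed(7); c(host = capss:::random_dna(2e4, 0.5)) })
mini_reads <- capss::simulate_pool_reads(
  mini_clones, mini_genome, mini_layout, mini_vector, mini_index,
  host_genome = mini_host, depth_per_pool = 30, error_rate = 0,
  host_fraction = 0.1, seed = 6)

## one preprocessed pool (ROW:0) with its true member clones
mini_pool <- local({
  dmx <- capss::demultiplex(mini_reads$library_X, mini_index)
  dmx$pools[["ROW:0"]]
})

## Short-BES extraction over every mini pool, and the resulting CAPSS
## assignment, shared across the assign/genmap tests.
.mini_pools_bes <- local({
  dmx <- c(capss::demultiplex(mini_reads$library_X, mini_index)$pools,
           capss::demultiplex(mini_reads$library_Y, mini_index)$pools)
  lapply(dmx, capss::extract_short_bes, vector = mini_vector)
})
.mini_bes_table <- rbindlist(lapply(names(.mini_pools_bes), function(nm)
  if (nrow(.mini_pools_bes[[nm]]) > 0)
    cbind(data.table(pool_axis = sub(":.*", "", nm),
                     pool_index = as.integer(sub(".*:", "", nm))),
          .mini_pools_bes[[nm]])))
.mini_assignments <- capss::resolve_conflicts(capss::match_pools(
  .mini_bes_table[pool_axis == "ROW"], .mini_bes_table[pool_axis == "COL"],
  mini_layout))

## Lazily built toy-preset pipeline run shared by the acceptance tests.
.toy_cache <- new.env(parent = emptyenv())
toy_run <- function() {
  if (is.null(.toy_cache$run)) {
    cfg <- capss::capss_config("toy", seed = 20240901)
    .toy_cache$run <- capss::run_pipeline(cfg)
  }
  .toy_cache$run
}
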