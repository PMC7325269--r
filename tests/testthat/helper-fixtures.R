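# shared fixtures built in code

fixture_tree <- function() {
  read_mutation_tree(system.file("extdata", "five_lineage_tree_synthetic.nwk",
                                 package = "rhoclock"))
}

worked_example_table <- function() period_table(c(2, 3, 4, 5), c(3, 6, 2, 5))

worked_example_tsv <- function() {
  system.file("extdata", "five_lineage_periods.tsv", package = "rhoclock")
}

# a batch of small simulated genealogies for property tests
random_trees <- function(seeds = 1:12, n_range = 3:10) {
  lapply(seeds, function(s) {
    n <- n_range[1 + (s %% length(n_range))]
    simulate_kingman_tree(sim_config(n_tips = n, Ne = 800, seed = s))$tree
  })
}
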