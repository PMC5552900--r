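# Shared fixtures, all built in code.

X5 <- as.character(1:5)
X6 <- as.character(1:6)
X8 <- as.character(1:8)

# the 17-split worked example on {1..8}: 8 trivial splits plus 9 nontrivial
# ones read off a 4-cycle/6-cycle figure
example_system_8 <- function() {
  nt <- list(c("8", "1"), c("7", "8"), c("7", "8", "1"), c("2", "3", "4"),
             c("3", "4"), c("3", "4", "5"), c("2", "3", "4", "5"),
             c("3", "4", "5", "6"), c("5", "6"))
  ss_union(split_system(nt, taxa = X8), all_trivial_splits(X8))
}

# the explicitly drawn network: a 4-cycle (leaves 7, 8, 1) and a 6-cycle
# (leaves 2..6) joined by one cut edge
figure_network_8 <- function() {
  edges <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 1),
    c(1, 11), c(2, 12), c(3, 13),
    c(4, 5),
    c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 10), c(10, 5),
    c(6, 14), c(7, 15), c(8, 16), c(9, 17), c(10, 18))
  labels <- c(rep(NA, 10), "7", "8", "1", "2", "3", "4", "5", "6")
  uprooted_network(edges, labels)
}

# random 1-nested network, degrading the cycle count when the sampled tree
# cannot host it (cycle feasibility depends on interior adjacency)
random_net_retry <- function(n, k, cycle_length = 4:5, resolve_probability = 0.5) {
  repeat {
    net <- tryCatch(
      random_1nested_network(n, n_cycles = k, cycle_length = cycle_length,
                             resolve_probability = resolve_probability),
      error = function(e) NULL)
    if (!is.null(net)) return(net)
    k <- k - 1L
  }
}

cycle_lengths_of <- function(net) {
  cycles <- Filter(function(cy) cy$is_cycle, onenest:::net_cycles(net))
  sort(vapply(cycles, function(cy) length(cy$vertices), integer(1)))
}
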