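test_that("buneman_tree realizes the splits equivalence theorem", {
  # all trivial splits: star
  triv <- all_trivial_splits(as.character(1:4))
  star <- buneman_tree(triv)
  expect_identical(sum(is.na(star$labels)), 1L)
  expect_true(ss_equal(splits_of(star)$system, triv))

  # quartet
  sigq <- ss_union(triv, split_system(list(c("1", "2")), taxa = as.character(1:4)))
  tq <- buneman_tree(sigq)
  expect_true(ss_equal(splits_of(tq)$system, sigq))

  # random compatible fixtures: round trip and route agreement
  set.seed(97)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    tr <- random_1nested_network(n, n_cycles = 0)
    sig <- splits_of(tr)$system
    t_lam <- buneman_tree(sig)
    expect_true(ss_equal(splits_of(t_lam)$system, sig))
    expect_true(networks_isomorphic(t_lam, tr))
    t_bun <- buneman_tree(sig, route = "buneman")
    expect_true(networks_isomorphic(t_lam, t_bun))
  }
  expect_error(buneman_tree(split_system(list(c("1", "2")), taxa = X5)),
               "trivial")
  expect_error(buneman_tree(ss_union(all_trivial_splits(X5),
                                     split_system(list(c("1", "2"), c("2", "3")),
                                                  taxa = X5))),
               "not compatible")
})

test_that("component quotients find blocks and the unique block cycle", {
  comp1 <- split_system(list(c("8", "1"), c("7", "8")), taxa = X8)
  cq1 <- component_quotient(comp1)
  expect_identical(length(cq1$blocks), 4L)
  expect_true(setequal(vapply(cq1$blocks, paste, character(1), collapse = ","),
                       c("8", "1", "7", "2,3,4,5,6")))
  # the block cycle places 8 between 7 and 1
  ordv <- unclass(cq1$ordering)
  reps <- names(cq1$blocks)
  pos <- match(c("7", "8", "1"), ordv)
  expect_true(abs(pos[1] - pos[2]) %in% c(1L, length(ordv) - 1L))
  expect_true(abs(pos[2] - pos[3]) %in% c(1L, length(ordv) - 1L))

  # the 5-split component of the worked example quotients to 5 blocks
  comps <- incompatibility_components(nontrivial_splits(example_system_8()))
  big <- comps$systems[[which.max(lengths(comps$members))]]
  cq2 <- component_quotient(big)
  expect_identical(length(cq2$blocks), 5L)
  expect_true(setequal(vapply(cq2$blocks, paste, character(1), collapse = ","),
                       c("2", "3,4", "5", "6", "1,7,8")))

  # a non-circular component fails cleanly
  bad <- split_system(list(c("1", "2"), c("1", "3"), c("1", "4"), c("2", "3")),
                      taxa = X5)
  expect_error(component_quotient(bad), "not circular")
})

test_that("the worked example reconstructs to its optimal network", {
  sig <- example_system_8()
  # the printed system is itself I-intersection closed and circular, so the
  # optimal network displays exactly these 17 splits
  expect_true(is_i_closed(sig))
  net <- minimal_1nested(sig)
  expect_true(validate_network(net)$is_1_nested)
  sm <- splits_of(net)
  expect_true(ss_equal(sm$system, sig))
  expect_identical(cycle_lengths_of(net), c(4L, 5L))
  # strictly below the naive simple level-1 bound C(8,2) = 28
  expect_lt(n_splits(sm$system), 28L)
  # independent brute-force minimal-cut oracle agrees
  bf <- splits_of_bruteforce(net)
  expect_true(ss_equal(bf$system, sm$system))
})

test_that("compatible systems reconstruct to trees; trivial splits auto-added", {
  sig <- ss_union(all_trivial_splits(X6),
                  split_system(list(c("1", "2"), c("1", "2", "3")), taxa = X6))
  net <- minimal_1nested(sig)
  expect_identical(cycle_lengths_of(net), integer(0))
  expect_true(ss_equal(splits_of(net)$system, sig))
  expect_warning(minimal_1nested(split_system(list(c("1", "2"), c("2", "3")),
                                              taxa = X5)),
                 "trivial")
  expect_error(suppressWarnings(minimal_1nested(
    split_system(list(c("1", "2"), c("1", "3"), c("1", "4")), taxa = X5))),
    "not circular")
})

test_that("round trip: random 1-nested networks are recovered exactly", {
  set.seed(101)
  for (rep in 1:15) {
    n <- sample(5:10, 1)
    net <- random_net_retry(n, sample(0:min(3L, (n - 2L) %/% 2L), 1))
    sig <- splits_of(net)$system
    rec <- minimal_1nested(sig)
    expect_true(ss_equal(splits_of(rec)$system, sig))
    expect_true(isomorphic_up_to_resolution(rec, net))
  }
})

test_that("minimality: exhaustive search finds nothing smaller (scaled down)", {
  # over all generator-reachable 1-nested networks at small n, none displays
  # the input with fewer total splits than the reconstruction
  set.seed(103)
  for (rep in 1:3) {
    n <- 6
    sig <- random_circular_system(n, subsample_fraction = 0.4)
    best <- n_splits(splits_of(minimal_1nested(sig))$system)
    for (trial in 1:40) {
      cand <- random_net_retry(n, sample(0:2, 1), cycle_length = 4:6,
                               resolve_probability = 0.5)
      sm <- splits_of(cand)$system
      if (ss_issubset(sig, sm)) expect_gte(n_splits(sm), best)
    }
    # and never below the input itself
    expect_gte(best, n_splits(sig))
  }
})

test_that("monotone sanity: displayed size is bounded by the maximal system", {
  set.seed(107)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    sig <- random_circular_system(n, subsample_fraction = runif(1, 0.2, 0.9))
    w <- attr(sig, "ordering")
    sz <- n_splits(splits_of(minimal_1nested(sig))$system)
    expect_lte(sz, n * (n - 1) / 2)
    expect_identical(sz == n * (n - 1) / 2,
                     is_maximal_circular_closure(sig, ordering = w))
  }
})

test_that("the Buneman route agrees with the component route", {
  set.seed(109)
  sig <- example_system_8()
  n1 <- minimal_1nested(sig)
  n2 <- network_from_buneman(sig)
  expect_true(ss_equal(splits_of(n2)$system, sig))
  expect_true(isomorphic_up_to_resolution(n1, n2))
  # compatible input: identical to the Buneman tree
  compat <- ss_union(all_trivial_splits(X6),
                     split_system(list(c("1", "2"), c("4", "5")), taxa = X6))
  expect_true(networks_isomorphic(network_from_buneman(compat),
                                  buneman_tree(compat)))
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    sig <- random_circular_system(n, subsample_fraction = runif(1, 0.2, 0.8))
    a <- minimal_1nested(sig)
    b <- network_from_buneman(sig)
    expect_true(ss_equal(splits_of(a)$system, splits_of(b)$system))
    expect_true(isomorphic_up_to_resolution(a, b))
  }
})

test_that("resolution rule: cycle vertices resolved iff their m-split is input", {
  sig <- example_system_8()
  nb <- network_from_buneman(sig)      # satisfies the rule by construction
  nm <- resolve_by_splits(minimal_1nested(sig), sig)
  expect_true(networks_isomorphic(nb, nm))
  keys <- onenest:::system_keys(sig)
  cycles <- Filter(function(cy) cy$is_cycle, onenest:::net_cycles(nm))
  for (cy in cycles) {
    for (v in cy$order) {
      hang <- onenest:::reachable_leafset(nm, v, cy$edges, sig$taxa)
      if (!hang[1]) hang <- !hang
      in_sigma <- onenest:::split_key(hang) %in% keys
      non_cyc <- setdiff(onenest:::incident_edges(nm, v), cy$edges)
      if (in_sigma) {
        # partially resolved: exactly one incident cut edge
        expect_identical(length(non_cyc), 1L)
      } else {
        # unresolved: several subtrees attach directly
        expect_gte(length(non_cyc), 2L)
      }
    }
  }
})

test_that("level-1 characterization via absent compatible splits", {
  # maximal partially resolved level-1 fixture: no absent compatible split
  net <- simple_level1_from_ordering(circular_ordering(X6))
  expect_null(level1_absent_split(net))
  set.seed(113)
  tr <- random_1nested_network(7, n_cycles = 1, cycle_length = 4:4,
                               resolve_probability = 1)
  tr <- maximal_partial_resolution(tr)
  if (validate_network(tr)$is_level_1 &&
      all(onenest:::net_degrees(tr)[is.na(tr$labels)] == 3L)) {
    expect_null(level1_absent_split(tr))
  }
  # a star (degree-4 hub, not level-1-maximal) admits an absent compatible split
  star <- uprooted_network(cbind(5L, 1:4), c("1", "2", "3", "4", NA))
  s <- level1_absent_split(star)
  expect_false(is.null(s))
  expect_false(ss_contains(splits_of(star)$system, s))
})
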