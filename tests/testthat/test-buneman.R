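test_that("vertex enumeration matches the 2^m brute-force filter", {
  set.seed(79)
  systems <- list(
    all_trivial_splits(as.character(1:3)),
    split_system(list(c("1", "2"), c("2", "3")), taxa = as.character(1:4)),
    random_circular_system(6, subsample_fraction = 0.5),
    ss_union(all_trivial_splits(X5), split_system(list(c("1", "2")), taxa = X5)))
  for (sig in systems) {
    g <- buneman_graph(sig)
    m <- n_splits(sig)
    # brute force over all 2^m selections
    count <- 0L
    for (code in 0:(2^m - 1)) {
      sel <- as.logical(bitwAnd(code, 2^(0:(m - 1))) > 0)
      sides <- lapply(seq_len(m), function(s)
        if (sel[s]) sig$blocks[s, ] else !sig$blocks[s, ])
      ok <- TRUE
      for (a in seq_len(m - 1)) {
        for (b in (a + 1):m) {
          if (!any(sides[[a]] & sides[[b]])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) count <- count + 1L
    }
    expect_identical(nrow(g$selections), count)
  }
})

test_that("trivial-split stars and incompatible pairs give known graphs", {
  g3 <- buneman_graph(all_trivial_splits(as.character(1:3)))
  expect_identical(nrow(g3$selections), 4L)
  expect_identical(nrow(g3$edges), 3L)
  degs <- tabulate(g3$edges, nbins = 4)
  expect_identical(sort(which(degs == 1L)), sort(unname(g3$kuratowski)))

  # two incompatible splits: the 4-cycle
  g4 <- buneman_graph(split_system(list(c("1", "2"), c("2", "3")),
                                   taxa = as.character(1:4)))
  expect_identical(nrow(g4$selections), 4L)
  expect_identical(nrow(g4$edges), 4L)
  expect_true(all(tabulate(g4$edges, nbins = 4) == 2L))
})

test_that("Kuratowski maps are leaves and realize separation distances", {
  sig <- example_system_8()
  g <- buneman_graph(sig)
  degs <- tabulate(g$edges, nbins = nrow(g$selections))
  expect_identical(sort(which(degs == 1L)), sort(unname(g$kuratowski)))
  for (x in c("1", "4", "7")) {
    phi <- kuratowski_map(x, sig)
    expect_true(all(vapply(seq_len(n_splits(sig)), function(s) {
      side <- if (phi[s]) sig$blocks[s, ] else !sig$blocks[s, ]
      side[match(x, sig$taxa)]
    }, logical(1))))
  }
  # D(phi_x, phi_y) = number of separating splits
  for (pair in list(c("1", "2"), c("3", "7"))) {
    dxy <- sum(kuratowski_map(pair[1], sig) != kuratowski_map(pair[2], sig))
    sep <- sum(sig$blocks[, match(pair[1], sig$taxa)] !=
                 sig$blocks[, match(pair[2], sig$taxa)])
    expect_identical(dxy, sep)
  }
  expect_error(kuratowski_map("9", sig), "not in ground set")
})

test_that("graph distance equals the selection Hamming distance", {
  sig <- example_system_8()
  g <- buneman_graph(sig)
  gi <- igraph::add_edges(igraph::make_empty_graph(nrow(g$selections),
                                                   directed = FALSE),
                          as.vector(t(g$edges)))
  D <- igraph::distances(gi)
  H <- as.matrix(dist(g$selections * 1, method = "manhattan"))
  expect_true(all(D == H))
})

test_that("Bu-displayed splits are exactly the generating system", {
  set.seed(83)
  systems <- list(example_system_8(),
                  random_circular_system(6, subsample_fraction = 0.7),
                  ss_union(all_trivial_splits(X5),
                           split_system(list(c("1", "2")), taxa = X5)))
  for (sig in systems) {
    g <- buneman_graph(sig)
    expect_true(ss_equal(bu_displayed_splits(g), sig))
  }
  # tree case: each ladder is a single edge
  compat <- ss_union(all_trivial_splits(X5),
                     split_system(list(c("1", "2")), taxa = X5))
  g <- buneman_graph(compat)
  expect_true(all(table(g$edge_split) == 1L))
})

test_that("degree law: deg(phi) counts minimal distinct images", {
  sig <- example_system_8()
  g <- buneman_graph(sig)
  degs <- tabulate(g$edges, nbins = nrow(g$selections))
  for (v in seq_len(nrow(g$selections))) {
    sel <- g$selections[v, ]
    imgs <- lapply(seq_len(n_splits(sig)), function(s)
      which(if (sel[s]) sig$blocks[s, ] else !sig$blocks[s, ]))
    keyset <- vapply(imgs, paste, character(1), collapse = ",")
    minimal <- vapply(seq_along(imgs), function(i) {
      !any(vapply(seq_along(imgs), function(j)
        j != i && length(imgs[[j]]) < length(imgs[[i]]) &&
          all(imgs[[j]] %in% imgs[[i]]), logical(1)))
    }, logical(1))
    expect_identical(length(unique(keyset[minimal])), degs[v])
  }
})

test_that("blocks correspond to incompatibility components, isometrically", {
  sig <- example_system_8()
  g <- buneman_graph(sig)
  bb <- buneman_blocks(g)
  expect_identical(length(bb$blocks), length(bb$components$members))
  # singleton components give single-edge blocks
  for (ci in seq_along(bb$blocks)) {
    comp <- bb$components$members[[ci]]
    blk <- bb$blocks[[ci]]
    if (length(comp) == 1L) {
      expect_identical(length(blk), 2L)
    } else {
      # the block is a copy of G(component): same vertex count, and
      # the block vertices restricted to the component coordinates enumerate
      # exactly the vertices of G(component)
      gsub <- buneman_graph(ss_subset(sig, comp))
      expect_identical(length(blk), nrow(gsub$selections))
      ksub <- apply(gsub$selections, 1, paste, collapse = "")
      kblk <- apply(g$selections[blk, comp, drop = FALSE], 1, paste, collapse = "")
      expect_true(setequal(ksub, kblk))
    }
  }
  # one incompatible pair plus trivial splits: one 4-cycle block, rest edges
  sig2 <- ss_union(all_trivial_splits(as.character(1:4)),
                   split_system(list(c("1", "2"), c("2", "3")),
                                taxa = as.character(1:4)))
  bb2 <- buneman_blocks(buneman_graph(sig2))
  sizes <- sort(lengths(bb2$blocks))
  expect_identical(sizes, c(rep(2L, 4L), 4L))
})

test_that("gates satisfy the metric gate identity", {
  sig <- example_system_8()
  g <- buneman_graph(sig)
  gi <- igraph::add_edges(igraph::make_empty_graph(nrow(g$selections),
                                                   directed = FALSE),
                          as.vector(t(g$edges)))
  D <- igraph::distances(gi)
  bb <- buneman_blocks(g)
  for (ci in seq_along(bb$blocks)) {
    comp <- bb$components$members[[ci]]
    blk <- bb$blocks[[ci]]
    for (x in sig$taxa) {
      phi <- kuratowski_map(x, sig)
      gt <- gate(phi, g, comp)
      vphi <- g$kuratowski[[x]]
      vg <- which(g$keys == paste(as.integer(gt), collapse = ""))
      expect_true(vg %in% blk)
      # phi already in the block: the gate is phi itself
      if (vphi %in% blk) expect_identical(vg, vphi)
      for (psi in blk) {
        expect_identical(D[psi, vphi], D[psi, vg] + D[vg, vphi])
      }
    }
  }
})

test_that("marguerites coincide with the Buneman graph for k = 4, 5 only", {
  for (k in 4:5) {
    mg <- marguerite(k)
    gk <- buneman_graph(mg$sigma)
    expect_identical(nrow(mg$selections), nrow(gk$selections))
    expect_identical(nrow(mg$edges), nrow(gk$edges))
  }
  mg6 <- marguerite(6)
  g6 <- buneman_graph(mg6$sigma)
  expect_lt(nrow(mg6$selections), nrow(g6$selections))
  expect_error(marguerite(3), "k >= 4")
})

test_that("marguerite vertices/edges live in G(Sigma_k); identifications hold", {
  for (k in 5:7) {
    mg <- marguerite(k)
    gk <- buneman_graph(mg$sigma)
    keys_g <- apply(gk$selections, 1, function(r) paste(as.integer(r), collapse = ""))
    keys_m <- apply(mg$selections, 1, function(r) paste(as.integer(r), collapse = ""))
    expect_true(all(keys_m %in% keys_g))
    # every marguerite edge is an edge of G (Hamming distance one, both ends
    # vertices of G) -- verified computationally
    for (e in seq_len(nrow(mg$edges))) {
      a <- mg$selections[mg$edges[e, 1], ]; b <- mg$selections[mg$edges[e, 2], ]
      expect_identical(sum(a != b), 1L)
    }
    # phi_i^{k-3} = phi_{i+1}^0 identification happened: k external vertices
    expect_identical(length(unique(mg$external_vertices)), k)
    # empirical boundary identifications of the psi chains are recorded in
    # all_ids: every declared (kind,i,j) landed on a vertex
    expect_false(anyNA(mg$all_ids$vertex))
  }
})

test_that("non-pair splits are Bu-displayed by 4 marguerite edges, 2 external", {
  for (k in 6:7) {
    mg <- marguerite(k)
    sp_sizes <- pmin(rowSums(mg$sigma$blocks), k - rowSums(mg$sigma$blocks))
    diffs <- apply(mg$edges, 1, function(e)
      which(mg$selections[e[1], ] != mg$selections[e[2], ]))
    for (s in which(sp_sizes > 2)) {
      ladder <- which(diffs == s)
      expect_identical(length(ladder), 4L)
      expect_identical(sum(mg$external_edges[ladder]), 2L)
    }
  }
})

test_that("network embedding is a bijection onto the gates", {
  sig <- example_system_8()
  net <- minimal_1nested(sig)
  emb <- embed_network(net)
  nl <- which(is.na(net$labels))
  expect_false(anyNA(emb$vertex_map))
  expect_false(anyDuplicated(emb$vertex_map[nl]) > 0)
  expect_true(setequal(emb$vertex_map[nl], buneman_gates(emb$graph)))
  # leaves map to Kuratowski vertices
  expect_true(all(emb$vertex_map[!is.na(net$labels)] %in% emb$graph$kuratowski))

  # binary tree: internal vertices <-> Steiner points
  set.seed(89)
  tr <- random_1nested_network(6, n_cycles = 0)
  emb <- embed_network(tr)
  nl <- which(is.na(tr$labels))
  expect_identical(length(unique(emb$vertex_map[nl])), length(nl))
  expect_true(setequal(emb$vertex_map[nl], buneman_gates(emb$graph)))

  # simple level-1 network: cycle vertices map to the marguerite externals,
  # i.e. the gates of the unique big block
  net <- simple_level1_from_ordering(circular_ordering(X6))
  emb <- embed_network(net)
  nl <- which(is.na(net$labels))
  expect_true(setequal(emb$vertex_map[nl], buneman_gates(emb$graph)))

  # random fixtures: injectivity onto gates
  for (rep in 1:4) {
    net <- maximal_partial_resolution(random_net_retry(sample(6:8, 1), 2))
    emb <- embed_network(net)
    nl <- which(is.na(net$labels))
    expect_identical(length(unique(emb$vertex_map[nl])), length(nl))
    expect_true(setequal(emb$vertex_map[nl], buneman_gates(emb$graph)))
  }
})

test_that("adjacent cycle vertices embed at marguerite path distance k-3", {
  net <- simple_level1_from_ordering(circular_ordering(X6))
  emb <- embed_network(net)
  cyc <- Filter(function(cy) cy$is_cycle, onenest:::net_cycles(net))[[1]]
  k <- length(cyc$order)
  img <- emb$vertex_map[cyc$order]
  for (i in seq_len(k)) {
    a <- img[i]; b <- img[(i %% k) + 1]
    expect_identical(sum(emb$graph$selections[a, ] != emb$graph$selections[b, ]),
                     k - 3L)
  }
})

test_that("the enumeration cap guards the exponential blow-up", {
  sig <- interval_splits(circular_ordering(X8))  # 28 splits
  expect_error(buneman_graph(sig, cap = 25), "cap exceeded")
  expect_silent(g <- buneman_graph(sig, cap = 30))
})
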