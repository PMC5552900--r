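## Reconstruction: Buneman tree for compatible systems, the minimal 1-nested
## network via incompatibility-component quotients, the Buneman-graph route,
## and the resolution rule.

#' Unique phylogenetic tree of a compatible split system
#'
#' For a compatible split system containing all trivial splits there is a
#' unique (up to isomorphism) unrooted phylogenetic tree whose displayed
#' splits are exactly the system (the splits equivalence theorem).  The
#' `"laminar"` route builds the hierarchy of clusters directly (fast, no
#' enumeration cap); the `"buneman"` route reinterprets the Buneman graph as
#' a network and serves as the independent cross-check.
#'
#' @param sigma A compatible `split_system` containing all trivial splits.
#' @param route `"laminar"` (default) or `"buneman"`.
#' @return An `uprooted_network` with no cycles.
#' @export
buneman_tree <- function(sigma, route = c("laminar", "buneman")) {
  route <- match.arg(route)
  if (!has_all_trivial_splits(sigma)) stop("missing trivial splits")
  if (!is_compatible_system(sigma)) stop("split system is not compatible")
  if (route == "buneman") {
    g <- buneman_graph(sigma)
    labels <- rep(NA_character_, nrow(g$selections))
    labels[g$kuratowski] <- sigma$taxa
    return(uprooted_network(g$edges, labels, n_vertices = nrow(g$selections)))
  }
  tree_from_compatible_splits(sigma)
}

# laminar-hierarchy construction, rooted at the minimum taxon
tree_from_compatible_splits <- function(sigma) {
  taxa <- sigma$taxa
  n <- length(taxa)
  r <- 1L
  # clusters: for each split, the side avoiding the root taxon
  cl_rows <- sigma$blocks
  flip <- cl_rows[, r]
  cl_rows[flip, ] <- !cl_rows[flip, , drop = FALSE]
  cl_rows <- cl_rows[!duplicated(apply(cl_rows, 1L, split_key)), , drop = FALSE]
  sizes <- rowSums(cl_rows)
  ord <- order(-sizes, apply(cl_rows, 1L, split_key), method = "radix")
  cl_rows <- cl_rows[ord, , drop = FALSE]
  sizes <- sizes[ord]
  nc <- nrow(cl_rows)
  # parent: smallest cluster strictly containing it (clusters are laminar)
  parent <- integer(nc)
  for (i in seq_len(nc)) {
    parent[i] <- 0L
    for (j in rev(seq_len(i - 1L))) {
      if (sizes[j] > sizes[i] && all(cl_rows[j, ] | !cl_rows[i, ])) {
        parent[i] <- j
        break
      }
    }
  }
  # vertices: leaves 1..n, internal node per nontrivial cluster
  internal <- which(sizes >= 2L)
  vid <- integer(nc)
  nv <- n
  for (i in internal) { nv <- nv + 1L; vid[i] <- nv }
  for (i in which(sizes == 1L)) vid[i] <- which(cl_rows[i, ])
  root_cluster <- which(sizes == n - 1L)  # X - {r}, present via r's trivial split
  if (length(root_cluster) != 1L) stop("missing trivial splits")
  edges <- list()
  for (i in seq_len(nc)) {
    if (i == root_cluster) {
      edges[[length(edges) + 1L]] <- c(r, vid[i])
    } else if (parent[i] == 0L) {
      edges[[length(edges) + 1L]] <- c(vid[root_cluster], vid[i])
    } else {
      edges[[length(edges) + 1L]] <- c(vid[parent[i]], vid[i])
    }
  }
  labels <- c(taxa, rep(NA_character_, nv - n))
  compact_network(do.call(rbind, edges), labels)
}

#' Quotient of an incompatibility component and its block cycle
#'
#' Collapses the taxa to the classes on which every split of the component
#' agrees, grows the I-intersection closure of the quotient system (capped
#' at `m(m-1)/2` splits for m blocks, which a circular component can never
#' exceed), and reads the unique cyclic ordering of the blocks off the
#' closure's 2-splits.  Fails with "component not circular" when the cap is
#' exceeded or the 2-splits do not form a single Hamiltonian cycle.
#'
#' @param component A `split_system`: one connected component (>= 2 splits)
#'   of the incompatibility graph of a larger system.
#' @return A list with `blocks` (list of character vectors, named by their
#'   representative, in cycle order), `quotient` (the quotient
#'   `split_system`), `closure` (its I-closure), `ordering` (a
#'   `circular_ordering` of the representatives).
#' @export
component_quotient <- function(component) {
  if (n_splits(component) < 2L) stop("component must have at least 2 splits")
  taxa <- component$taxa
  sig <- apply(component$blocks, 2L, split_key)
  classes <- split(taxa, factor(sig, levels = unique(sig)))
  reps <- vapply(classes, function(cl) natural_sort(cl)[1L], character(1))
  names(classes) <- reps
  m <- length(classes)
  if (m < 4L) stop("component not circular: fewer than 4 blocks")
  rep_cols <- match(reps, taxa)
  quotient <- new_split_system(natural_sort(reps),
                               component$blocks[, rep_cols[order(natural_key(reps))],
                                                drop = FALSE])
  cap <- m * (m - 1L) / 2L
  cl <- i_closure(quotient, cap = cap)
  if (cl$truncated || n_splits(cl$system) != cap) {
    stop("component not circular: quotient closure is not maximal circular")
  }
  qt <- cl$system$taxa
  adj <- matrix(FALSE, m, m, dimnames = list(qt, qt))
  for (i in seq_len(n_splits(cl$system))) {
    blk <- cl$system$blocks[i, ]
    for (sd in list(blk, !blk)) {
      if (sum(sd) == 2L) {
        pr <- which(sd)
        adj[pr[1L], pr[2L]] <- adj[pr[2L], pr[1L]] <- TRUE
      }
    }
  }
  if (!all(rowSums(adj) == 2L)) stop("component not circular: block adjacencies do not form a cycle")
  # walk the Hamiltonian cycle
  ordering <- qt[1L]
  prev <- NA_character_
  cur <- qt[1L]
  for (step in seq_len(m - 1L)) {
    nbrs <- qt[adj[cur, ]]
    nxt <- setdiff(nbrs, prev)[1L]
    if (is.na(nxt) || nxt %in% ordering) stop("component not circular: block adjacencies do not form a cycle")
    ordering <- c(ordering, nxt)
    prev <- cur
    cur <- nxt
  }
  if (!adj[cur, qt[1L]]) stop("component not circular: block adjacencies do not form a cycle")
  ordering <- circular_ordering(ordering)
  list(blocks = classes[unclass(ordering)], quotient = quotient,
       closure = cl$system, ordering = ordering)
}

# core constructor: trivial splits are ensured silently; errors when the
# input is not circular
build_1nested <- function(sigma) {
  taxa <- sigma$taxa
  trivials <- all_trivial_splits(taxa)
  sigma2 <- ss_union(sigma, trivials)
  comps <- incompatibility_components(sigma2)
  backbone_rows <- list()
  expansions <- list()
  for (ci in seq_along(comps$members)) {
    comp_sys <- comps$systems[[ci]]
    if (n_splits(comp_sys) == 1L) {
      backbone_rows[[length(backbone_rows) + 1L]] <- comp_sys$blocks[1L, ]
    } else {
      cq <- component_quotient(comp_sys)
      k <- length(cq$blocks)
      mrows <- matrix(FALSE, k, length(taxa))
      for (j in seq_len(k)) {
        mrows[j, ] <- taxa %in% cq$blocks[[j]]
      }
      for (j in seq_len(k)) backbone_rows[[length(backbone_rows) + 1L]] <- mrows[j, ]
      expansions[[length(expansions) + 1L]] <- cq
    }
  }
  backbone_rows <- c(backbone_rows, lapply(seq_len(nrow(trivials$blocks)),
                                           function(i) trivials$blocks[i, ]))
  sigma_prime <- new_split_system(taxa, do.call(rbind, backbone_rows))
  if (!is_compatible_system(sigma_prime)) {
    stop("input split system is not circular: backbone splits are incompatible")
  }
  net <- tree_from_compatible_splits(sigma_prime)
  for (cq in expansions) {
    net <- expand_placeholder(net, cq)
  }
  net
}

# replace the tree vertex whose removal induces the block partition of `cq`
# by a cycle whose vertices carry the blocks in `cq`'s cyclic order
expand_placeholder <- function(net, cq) {
  taxa <- net_taxa(net)
  k <- length(cq$blocks)
  block_keys <- vapply(cq$blocks, function(cl) {
    blk <- taxa %in% cl
    split_key(blk)
  }, character(1))
  cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
  on_cycle <- cycle_membership_count(net, cycles) > 0L
  degs <- net_degrees(net)
  target <- NA_integer_
  nbr_of_block <- NULL
  for (v in which(degs >= 4L & !on_cycle & is.na(net$labels))) {
    inc <- incident_edges(net, v)
    if (length(inc) != k) next
    nbrs <- vapply(inc, function(e) sum(net$edges[e, ]) - v, integer(1))
    sides <- vapply(seq_along(inc), function(t) {
      split_key(reachable_leafset(net, nbrs[t], inc[t], taxa))
    }, character(1))
    hit <- match(block_keys, sides)
    if (!anyNA(hit)) {
      target <- v
      nbr_of_block <- nbrs[hit]
      break
    }
  }
  if (is.na(target)) stop("input split system is not circular: no placeholder vertex matches a component")
  # new cycle vertices w_1..w_k in block-cycle order
  w <- net$n_vertices + seq_len(k)
  keep <- !(net$edges[, 1L] == target | net$edges[, 2L] == target)
  edges <- net$edges[keep, , drop = FALSE]
  cyc_edges <- cbind(w, c(w[-1L], w[1L]))
  attach_edges <- cbind(w, nbr_of_block)
  labels <- c(net$labels, rep(NA_character_, k))
  compact_network(rbind(edges, cyc_edges, attach_edges), labels)
}

#' Minimal 1-nested network displaying a circular split system
#'
#' Builds, from a circular split system containing all trivial splits, the
#' 1-nested network `N` with `sigma` contained in its displayed splits and
#' `|Sigma(N)|` minimal; `N` is unique up to isomorphism and partial
#' resolution.  The construction splits the system into incompatibility
#' components, reads each component's cycle off the I-closure of its
#' quotient, builds the compatible backbone tree, and expands each
#' placeholder vertex into its cycle.  Trivial splits are added with a
#' warning when absent.  Non-circular input raises an error.
#'
#' @param sigma A circular `split_system`.
#' @return An `uprooted_network` (1-nested).
#' @export
minimal_1nested <- function(sigma) {
  if (!has_all_trivial_splits(sigma)) {
    warning("adding missing trivial splits")
    sigma <- ss_union(sigma, all_trivial_splits(sigma$taxa))
  }
  net <- build_1nested(sigma)
  if (!ss_issubset(sigma, splits_of(net)$system)) {
    stop("internal error: constructed network does not display the input")
  }
  net
}

#' Minimal 1-nested network via the Buneman graph
#'
#' The independent route to the same (unique) network: build the Buneman
#' graph, identify its blocks, locate each block's marguerite external
#' vertices (the gates), wire them into a cycle, delete the block interiors
#' and replace Kuratowski leaves by their taxa.  The resulting network
#' realizes the resolution rule: a cycle vertex is partially resolved
#' exactly when the split displayed by its two flanking cycle edges belongs
#' to `sigma`.
#'
#' @param sigma A circular `split_system` containing all trivial splits
#'   (added with a warning when absent).
#' @param cap Buneman enumeration cap (see [buneman_graph()]).
#' @return An `uprooted_network`.
#' @export
network_from_buneman <- function(sigma, cap = 25L) {
  if (!has_all_trivial_splits(sigma)) {
    warning("adding missing trivial splits")
    sigma <- ss_union(sigma, all_trivial_splits(sigma$taxa))
  }
  g <- buneman_graph(sigma, cap = cap)
  bb <- buneman_blocks(g)
  nv <- nrow(g$selections)
  drop_vertex <- logical(nv)
  drop_edge <- logical(nrow(g$edges))
  new_edges <- list()
  for (ci in seq_along(bb$components$members)) {
    comp <- bb$components$members[[ci]]
    if (length(comp) == 1L) next
    block <- bb$blocks[[ci]]
    gates <- sort(unique(vapply(g$sigma$taxa, function(x) {
      gv <- bg_vertex_index(g, gate(kuratowski_map(x, g$sigma), g, comp))
      if (is.null(gv)) stop("gate is not a vertex")
      gv
    }, integer(1))))
    if (!all(gates %in% block)) stop("gates fall outside their block")
    k <- length(gates)
    if (k < 4L) stop("block with fewer than 4 gates")
    if (k > 10L) stop("block with more than 10 gates: cyclic ordering search too large")
    # cyclic order of the gates: the unique circular ordering of the gate set
    # under which every component split (restricted to the gates) is an
    # interval; found by the exact exhaustive circularity test
    gate_taxa <- as.character(seq_len(k))
    mini <- new_split_system(gate_taxa, t(g$selections[gates, comp, drop = FALSE]))
    ordw <- is_circular_brute(mini)
    if (is.null(ordw)) stop("gate selections are not cyclically orderable")
    cyc <- gates[as.integer(unclass(ordw))]
    new_edges[[length(new_edges) + 1L]] <- cbind(cyc, c(cyc[-1L], cyc[1L]))
    interior <- setdiff(block, gates)
    drop_vertex[interior] <- TRUE
    drop_edge[g$edge_split %in% comp] <- TRUE
  }
  if (any(drop_vertex)) {
    touches_dropped <- drop_vertex[g$edges[, 1L]] | drop_vertex[g$edges[, 2L]]
    if (any(touches_dropped & !drop_edge)) {
      stop("a non-block edge is attached to a block interior vertex")
    }
  }
  edges <- rbind(g$edges[!drop_edge, , drop = FALSE],
                 do.call(rbind, new_edges))
  labels <- rep(NA_character_, nv)
  labels[g$kuratowski] <- g$sigma$taxa
  net <- compact_network(edges, labels)
  suppress_degree2(net)
}

# contract non-cycle degree-2 vertices (safety pass; none are expected)
suppress_degree2 <- function(net) {
  repeat {
    d <- net_degrees(net)
    on_cycle <- cycle_membership_count(net) > 0L
    bad <- which(d == 2L & !on_cycle & is.na(net$labels))
    if (length(bad) == 0L) return(net)
    v <- bad[1L]
    inc <- incident_edges(net, v)
    nbrs <- vapply(inc, function(e) sum(net$edges[e, ]) - v, integer(1))
    edges <- net$edges[-inc, , drop = FALSE]
    edges <- rbind(edges, sort(nbrs))
    net <- compact_network(edges, net$labels)
  }
}

#' Apply the resolution rule of the optimal network
#'
#' Normalizes a minimal network for `sigma` so that a cycle vertex is
#' partially resolved (carries a cut edge) exactly when the split displayed
#' by its two flanking cycle edges belongs to `sigma`: attachments whose
#' m-split is absent from `sigma` are contracted onto the cycle, and cycle
#' vertices holding several subtrees whose m-split is present are pulled
#' out.
#'
#' @param net A 1-nested `uprooted_network` displaying `sigma`.
#' @param sigma The `split_system` that `net` was built for.
#' @return An `uprooted_network`.
#' @export
resolve_by_splits <- function(net, sigma) {
  if (!ss_issubset(sigma, splits_of(net)$system)) {
    stop("network does not display the split system")
  }
  keys <- system_keys(sigma)
  taxa <- sigma$taxa
  repeat {
    cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
    if (length(cycles) == 0L) return(net)
    cyc_count <- cycle_membership_count(net, cycles)
    degs <- net_degrees(net)
    changed <- FALSE
    for (ci in seq_along(cycles)) {
      cy <- cycles[[ci]]
      for (v in cy$vertices) {
        hang <- reachable_leafset(net, v, cy$edges, taxa)
        if (!hang[1L]) hang <- !hang
        in_sigma <- split_key(hang) %in% keys
        non_cyc <- setdiff(incident_edges(net, v), cy$edges)
        if (in_sigma && length(non_cyc) >= 2L && cyc_count[v] == 1L) {
          net <- partially_resolve(net, v)
          changed <- TRUE
          break
        }
        if (!in_sigma && length(non_cyc) == 1L && degs[v] == 3L) {
          e <- non_cyc
          w <- sum(net$edges[e, ]) - v
          if (is.na(net$labels[w]) && unresolve_eligible(net, e)) {
            net <- contract_edge(net, e)
            changed <- TRUE
            break
          }
        }
      }
      if (changed) break
    }
    if (!changed) return(net)
  }
}

#' Absent split compatible with everything a network displays
#'
#' Searches all `2^(n-1) - 1` splits of the taxon set for one that is not
#' displayed by the network yet compatible with every displayed split.  A
#' maximal partially resolved 1-nested network is level-1 exactly when no
#' such split exists.
#'
#' @param net A 1-nested `uprooted_network` (n at most 16 taxa).
#' @return An `nsplit`, or `NULL` when none exists.
#' @export
level1_absent_split <- function(net) {
  taxa <- net_taxa(net)
  n <- length(taxa)
  if (n > 16L) stop("exhaustive split search limited to 16 taxa")
  sys <- splits_of(net)$system
  keys <- system_keys(sys)
  for (code in seq_len(2^(n - 1L) - 1L)) {
    block <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2L))) > 0))
    # block always contains the first taxon; skip the full set
    if (all(block)) next
    if (split_key(block) %in% keys) next
    ok <- TRUE
    for (i in seq_len(n_splits(sys))) {
      if (!compatible_blocks(block, sys$blocks[i, ])) { ok <- FALSE; break }
    }
    if (ok) return(new_split_raw(taxa, block))
  }
  NULL
}
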