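## Uprooted networks as leaf-labeled graphs; split extraction via minimal
## cuts with multiplicities; structural predicates.
##
## Representation: vertices are opaque integers 1..n_vertices; `edges` is a
## 2-column integer matrix (u < v per row); `labels` is a character vector
## with the taxon on each leaf and NA on interior vertices.  Only leaf
## labels are semantic.

#' Construct an uprooted phylogenetic network
#'
#' An uprooted network is a simple connected leaf-labeled graph with no
#' degree-2 vertices and no cycle shorter than 4.  It is 1-nested when no
#' two cycles share an edge (every block is an edge or a cycle), level-1
#' when no two cycles share a vertex, and simple when all cut edges are
#' pendant.  Construction only checks basic well-formedness; use
#' [validate_network()] for the full diagnostic.
#'
#' @param edges Two-column integer matrix (or list of length-2 vectors) of
#'   undirected edges between vertex ids `1..n_vertices`.
#' @param labels Character vector of length `n_vertices`; taxon labels on
#'   leaves, `NA` on interior vertices.
#' @param n_vertices Number of vertices (default: inferred).
#' @return An object of class `uprooted_network`.
#' @export
uprooted_network <- function(edges, labels, n_vertices = length(labels)) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- t(apply(edges, 1L, sort))
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  labels <- as.character(labels)
  if (any(edges < 1L) || any(edges > n_vertices)) stop("edge endpoint out of range")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loop")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) stop("duplicate edge")
  taxa <- labels[!is.na(labels)]
  if (anyDuplicated(taxa)) stop("duplicate leaf label")
  structure(list(n_vertices = as.integer(n_vertices), edges = edges,
                 labels = labels),
            class = "uprooted_network")
}

#' @export
print.uprooted_network <- function(x, ...) {
  d <- net_degrees(x)
  cat(sprintf("Uprooted network: %d vertices, %d edges, %d leaves (%s)\n",
              x$n_vertices, nrow(x$edges), sum(!is.na(x$labels)),
              paste(natural_sort(x$labels[!is.na(x$labels)]), collapse = " ")))
  invisible(x)
}

net_taxa <- function(net) natural_sort(net$labels[!is.na(net$labels)])

net_degrees <- function(net) {
  tabulate(net$edges, nbins = net$n_vertices)
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_vertices, directed = FALSE)
  igraph::add_edges(g, as.vector(t(net$edges)))
}

# incident edge row indices per vertex
incident_edges <- function(net, v) {
  which(net$edges[, 1L] == v | net$edges[, 2L] == v)
}

## ---- cycles (blocks) ------------------------------------------------------

# Blocks of the graph; for each, the edge row indices and whether it is a
# cycle (in a 1-nested network every non-bridge block is a chordless cycle).
# Cycles are returned with vertices in cyclic order.
net_cycles <- function(net) {
  g <- as_igraph(net)
  bc <- igraph::biconnected_components(g)
  cycles <- list()
  for (ce in bc$component_edges) {
    eidx <- as.integer(ce)
    if (length(eidx) < 2L) next
    sub <- net$edges[eidx, , drop = FALSE]
    verts <- sort(unique(as.vector(sub)))
    is_cycle <- length(eidx) == length(verts) &&
      all(tabulate(sub, nbins = net$n_vertices)[verts] == 2L)
    cyc_order <- NULL
    if (is_cycle) {
      # walk the cycle starting from its smallest vertex
      adj <- lapply(verts, function(v) setdiff(as.vector(sub[sub[, 1L] == v | sub[, 2L] == v, ]), v))
      names(adj) <- as.character(verts)
      start <- verts[1L]
      prev <- start
      cur <- min(adj[[as.character(start)]])
      cyc_order <- c(start)
      while (cur != start) {
        cyc_order <- c(cyc_order, cur)
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        prev <- cur
        cur <- nxt
      }
    }
    cycles[[length(cycles) + 1L]] <- list(edges = eidx, vertices = verts,
                                          order = cyc_order, is_cycle = is_cycle)
  }
  cycles
}

# integer vector: number of cycles each vertex lies on
cycle_membership_count <- function(net, cycles = net_cycles(net)) {
  cnt <- integer(net$n_vertices)
  for (cy in cycles) {
    if (cy$is_cycle) cnt[cy$vertices] <- cnt[cy$vertices] + 1L
  }
  cnt
}

net_bridges <- function(net) {
  g <- as_igraph(net)
  as.integer(igraph::bridges(g))
}

## ---- validation -----------------------------------------------------------

#' Validate an uprooted network and classify its structure
#'
#' Reports every violated invariant (connectivity, simplicity, no degree-2
#' vertices, girth at least 4, leaf-labeling bijection) and classifies the
#' network: `is_1_nested` (no two cycles share an edge), `is_level_1` (no
#' two cycles share a vertex), `is_simple_network` (all cut edges pendant).
#'
#' @param net An `uprooted_network`.
#' @return A list with `valid`, `problems` (character), `is_1_nested`,
#'   `is_level_1`, `is_simple_network`.
#' @export
validate_network <- function(net) {
  problems <- character(0)
  g <- as_igraph(net)
  if (!igraph::is_connected(g)) problems <- c(problems, "graph is not connected")
  d <- net_degrees(net)
  if (any(d == 2L)) {
    problems <- c(problems, sprintf("degree-2 vertices: %s",
                                    paste(which(d == 2L), collapse = ",")))
  }
  if (any(d == 0L)) problems <- c(problems, "isolated vertices")
  gir <- suppressWarnings(igraph::girth(g)$girth)
  if (is.finite(gir) && gir > 0 && gir < 4) {
    problems <- c(problems, sprintf("cycle of length %d (< 4)", gir))
  }
  leaves <- which(d == 1L)
  labeled <- which(!is.na(net$labels))
  if (!setequal(leaves, labeled)) {
    problems <- c(problems,
                  "leaf labels must sit exactly on the degree-1 vertices")
  }
  bc <- net_cycles(net)
  one_nested <- all(vapply(bc, function(cy) cy$is_cycle, logical(1)))
  level1 <- one_nested && all(cycle_membership_count(net, bc) <= 1L)
  br <- net_bridges(net)
  simple_net <- all(vapply(br, function(e) {
    any(d[net$edges[e, ]] == 1L)
  }, logical(1)))
  list(valid = length(problems) == 0L,
       problems = problems,
       is_1_nested = length(problems) == 0L && one_nested,
       is_level_1 = length(problems) == 0L && level1,
       is_simple_network = length(problems) == 0L && simple_net)
}

## ---- split extraction -----------------------------------------------------

# leaves reachable from vertex v without crossing the given forbidden edge
# rows; returns logical over taxa (natural order)
reachable_leafset <- function(net, v, forbidden, taxa) {
  seen <- logical(net$n_vertices)
  stack <- v
  seen[v] <- TRUE
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (e in incident_edges(net, cur)) {
      if (e %in% forbidden) next
      w <- sum(net$edges[e, ]) - cur
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  taxa %in% net$labels[seen & !is.na(net$labels)]
}

#' Splits displayed by a 1-nested network, with multiplicities
#'
#' Enumerates every minimal cut of the network -- each cut edge, and each
#' unordered pair of distinct edges within one cycle -- and returns the
#' induced split system together with the multiplicity of each split (the
#' number of distinct minimal cuts inducing it; 1, 2 or 3 for 1-nested
#' networks) and the per-cycle split systems.
#'
#' @param net A 1-nested `uprooted_network`.
#' @return An object of class `split_multiset`: list with `system` (a
#'   `split_system`), `multiplicity` (integer aligned with the rows of
#'   `system`), `cycle_systems` (list of `split_system`, one per cycle) and
#'   `n_cuts`.
#' @export
splits_of <- function(net) {
  diag <- validate_network(net)
  if (!diag$valid) stop("invalid network: ", paste(diag$problems, collapse = "; "))
  if (!diag$is_1_nested) stop("splits_of requires a 1-nested network")
  taxa <- net_taxa(net)
  cut_keys <- character(0)
  rows <- list()
  add_cut <- function(block) {
    if (!block[1L]) block <- !block
    rows[[length(rows) + 1L]] <<- block
    cut_keys[[length(cut_keys) + 1L]] <<- split_key(block)
  }
  for (e in net_bridges(net)) {
    add_cut(reachable_leafset(net, net$edges[e, 1L], e, taxa))
  }
  cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
  cycle_systems <- list()
  for (cy in cycles) {
    k <- length(cy$order)
    # leaves hanging off each cycle vertex (outside the cycle edges)
    hang <- lapply(cy$order, function(v) reachable_leafset(net, v, cy$edges, taxa))
    first_key <- length(cut_keys)
    # deleting the cycle edges (v_i, v_{i+1}) and (v_j, v_{j+1}) leaves the
    # arc v_{i+1}..v_j on one side
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        side <- rep(FALSE, length(taxa))
        for (t in (i + 1L):j) side <- side | hang[[t]]
        add_cut(side)
      }
    }
    cyc_keys <- cut_keys[(first_key + 1L):length(cut_keys)]
    cycle_systems[[length(cycle_systems) + 1L]] <-
      new_split_system(taxa, do.call(rbind, rows[(first_key + 1L):length(rows)]))
  }
  blocks <- do.call(rbind, rows)
  system <- new_split_system(taxa, blocks)
  mult <- as.integer(table(factor(cut_keys, levels = system_keys(system))))
  structure(list(system = system, multiplicity = mult,
                 cycle_systems = cycle_systems, n_cuts = length(cut_keys)),
            class = "split_multiset")
}

#' @export
print.split_multiset <- function(x, ...) {
  cat(sprintf("Split multiset: %d distinct splits from %d minimal cuts; multiplicities %s\n",
              n_splits(x$system), x$n_cuts,
              paste(sort(unique(x$multiplicity)), collapse = "/")))
  invisible(x)
}

#' Brute-force minimal-cut enumeration (oracle)
#'
#' Enumerates ALL subsets of at most `max_cut` edges, keeps those whose
#' deletion leaves exactly two components with no proper disconnecting
#' subset, and returns the induced splits with multiplicities.  Exponential;
#' intended as an independent oracle for [splits_of()] on small fixtures.
#'
#' @param net An `uprooted_network`.
#' @param max_cut Maximum cut size to enumerate (default 2).
#' @return A list with `system` and `multiplicity` as in [splits_of()].
#' @export
splits_of_bruteforce <- function(net, max_cut = 2L) {
  taxa <- net_taxa(net)
  g <- as_igraph(net)
  m <- nrow(net$edges)
  n_comp_without <- function(eidx) {
    igraph::count_components(igraph::delete_edges(g, eidx))
  }
  cuts <- list()
  for (size in seq_len(max_cut)) {
    for (eset in utils::combn(m, size, simplify = FALSE)) {
      if (n_comp_without(eset) != 2L) next
      minimal <- TRUE
      if (size > 1L) {
        for (drop in seq_along(eset)) {
          if (n_comp_without(eset[-drop]) != 1L) { minimal <- FALSE; break }
        }
      }
      if (minimal) cuts[[length(cuts) + 1L]] <- eset
    }
  }
  rows <- lapply(cuts, function(eset) {
    block <- reachable_leafset(net, net$edges[eset[1L], 1L], eset, taxa)
    if (!block[1L]) block <- !block
    block
  })
  keys <- vapply(rows, split_key, character(1))
  system <- new_split_system(taxa, do.call(rbind, rows))
  mult <- as.integer(table(factor(keys, levels = system_keys(system))))
  list(system = system, multiplicity = mult,
       max_cut_size = max(lengths(cuts)))
}

## ---- leaf ordering --------------------------------------------------------

#' Circular leaf ordering induced by a 1-nested network
#'
#' Reads a circular ordering of the taxa off the network by an Euler-style
#' traversal of its block-cut structure, walking around each cycle in
#' rotational order.  Every split displayed by the network is an interval
#' split of the returned ordering.
#'
#' @param net A 1-nested `uprooted_network`.
#' @return A `circular_ordering`.
#' @export
leaf_ordering <- function(net) {
  cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
  cyc_of_vertex <- vector("list", net$n_vertices)
  for (ci in seq_along(cycles)) {
    for (v in cycles[[ci]]$vertices) {
      cyc_of_vertex[[v]] <- c(cyc_of_vertex[[v]], ci)
    }
  }
  cycle_edge <- logical(nrow(net$edges))
  for (cy in cycles) cycle_edge[cy$edges] <- TRUE
  out <- character(0)
  emit <- function(x) out <<- c(out, x)
  visited_cycle <- logical(length(cycles))

  # traverse outward from vertex v, having arrived via edge `via` (0 = root);
  # `skip_cycles`: cycle ids already being walked at v
  traverse <- function(v, via, skip_cycles) {
    if (!is.na(net$labels[v])) {
      emit(net$labels[v])
      return(invisible(NULL))
    }
    mycycles <- setdiff(cyc_of_vertex[[v]], skip_cycles)
    mycycles <- mycycles[!visited_cycle[mycycles]]
    # first the plain (non-cycle) edges at v
    for (e in incident_edges(net, v)) {
      if (e == via || cycle_edge[e]) next
      traverse(sum(net$edges[e, ]) - v, e, integer(0))
    }
    # then walk each cycle through v in rotational order
    for (ci in mycycles) {
      visited_cycle[ci] <<- TRUE
      ord <- cycles[[ci]]$order
      k <- length(ord)
      start <- match(v, ord)
      for (step in seq_len(k - 1L)) {
        w <- ord[((start - 1L + step) %% k) + 1L]
        traverse_at_cycle_vertex(w, ci)
      }
    }
    invisible(NULL)
  }
  # visit everything hanging at cycle vertex w, excluding cycle ci's edges
  traverse_at_cycle_vertex <- function(w, ci) {
    if (!is.na(net$labels[w])) {
      emit(net$labels[w])
      return(invisible(NULL))
    }
    for (e in incident_edges(net, w)) {
      if (e %in% cycles[[ci]]$edges) next
      if (cycle_edge[e]) next
      traverse(sum(net$edges[e, ]) - w, e, integer(0))
    }
    # other cycles sharing w
    for (cj in setdiff(cyc_of_vertex[[w]], ci)) {
      if (visited_cycle[cj]) next
      visited_cycle[cj] <<- TRUE
      ord <- cycles[[cj]]$order
      k <- length(ord)
      start <- match(w, ord)
      for (step in seq_len(k - 1L)) {
        u <- ord[((start - 1L + step) %% k) + 1L]
        traverse_at_cycle_vertex(u, cj)
      }
    }
    invisible(NULL)
  }

  root <- which(!is.na(net$labels))[1L]
  e0 <- incident_edges(net, root)[1L]
  emit(net$labels[root])
  traverse(sum(net$edges[e0, ]) - root, e0, integer(0))
  circular_ordering(out)
}

#' Simple level-1 network realizing a circular ordering
#'
#' Builds the cycle network with one interior vertex per taxon (in the given
#' cyclic order), each carrying a pendant leaf; its displayed splits are
#' exactly the interval splits of the ordering.  For n = 3 the construction
#' degenerates (cycles must have length >= 4) and the star tree is returned.
#'
#' @param ordering A `circular_ordering` (or coercible vector).
#' @return An `uprooted_network`.
#' @export
simple_level1_from_ordering <- function(ordering) {
  if (!inherits(ordering, "circular_ordering")) ordering <- circular_ordering(ordering)
  n <- length(ordering)
  if (n == 3L) {
    return(uprooted_network(cbind(4L, 1:3),
                            c(unclass(ordering), NA_character_)))
  }
  # interior cycle vertices 1..n, leaf vertices n+1..2n
  cyc <- cbind(1:n, c(2:n, 1L))
  pend <- cbind(1:n, n + 1:n)
  uprooted_network(rbind(cyc, pend),
                   c(rep(NA_character_, n), unclass(ordering)))
}
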