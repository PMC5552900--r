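## Synthetic fixtures: random 1-nested networks and random circular split
## systems.  A single seeded PRNG stream drives every stochastic choice, in
## documented order, so identical arguments and seed give identical output.

#' Generate a random 1-nested network
#'
#' Builds a random unrooted binary tree on the taxa by random leaf addition,
#' then expands `n_cycles` interior vertices into cycles: an interior vertex
#' is grown by contracting adjacent interior tree edges until its degree
#' reaches the sampled cycle length, and is then replaced by a cycle with
#' one neighbour per cycle vertex (a maximal partially resolved attachment).
#' With probability `1 - resolve_probability` each eligible attachment is
#' afterwards contracted back onto its cycle, yielding partially unresolved
#' variants.  The output always validates as 1-nested.
#'
#' @param n_taxa Number of taxa (>= 3); labels default to `"1".."n"`.
#' @param n_cycles Exact number of cycles to create (infeasible requests
#'   error: each cycle of length L consumes L-2 of the n-2 interior
#'   vertices).
#' @param cycle_length Integer vector of admissible cycle lengths (>= 4)
#'   sampled uniformly per cycle, clipped to what remains feasible.
#' @param resolve_probability Probability that an eligible cycle attachment
#'   stays pulled out as a cut edge (default 0.5).
#' @param taxa Optional explicit taxon labels.
#' @param seed Optional integer seed.
#' @return A 1-nested `uprooted_network`.
#' @export
random_1nested_network <- function(n_taxa, n_cycles = 1L,
                                   cycle_length = 4:6,
                                   resolve_probability = 0.5,
                                   taxa = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) taxa <- as.character(seq_len(n_taxa))
  taxa <- check_ground_set(taxa)
  n <- length(taxa)
  if (any(cycle_length < 4L)) stop("cycle lengths must be at least 4")
  net <- random_binary_tree(taxa)
  if (n_cycles > 0L && n == 3L) stop("infeasible: no cycles fit on 3 taxa")
  for (ci in seq_len(n_cycles)) {
    # a cycle of length L consumes a CONNECTED cluster of L - 2 interior
    # tree vertices (a vertex plus L - 3 contractions of adjacent ones)
    ic <- interior_components(net)
    room <- if (length(ic$sizes) == 0L) 0L else max(ic$sizes)
    feasible <- cycle_length[cycle_length - 2L <= room]
    if (length(feasible) == 0L) {
      stop(sprintf("infeasible: no room for cycle %d (largest interior cluster %d)",
                   ci, room))
    }
    L <- feasible[sample.int(length(feasible), 1L)]
    net <- grow_cycle(net, L)
  }
  # stochastic partial unresolution
  repeat {
    cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
    if (length(cycles) == 0L) break
    degrees <- net_degrees(net)
    el <- which(vapply(seq_len(nrow(net$edges)),
                       function(e) unresolve_eligible(net, e, cycles, degrees),
                       logical(1)))
    el <- el[stats::runif(length(el)) > resolve_probability]
    if (length(el) == 0L) break
    net <- contract_edge(net, el[1L])
  }
  stopifnot(validate_network(net)$is_1_nested)
  net
}

# random unrooted binary tree by leaf addition to a random edge
random_binary_tree <- function(taxa) {
  n <- length(taxa)
  # leaves 1..n, interior vertices appended
  labels <- c(taxa, NA_character_)
  edges <- rbind(c(1L, n + 1L), c(2L, n + 1L), c(3L, n + 1L))
  nv <- n + 1L
  for (leaf in seq_len(n)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1L)
    u <- edges[e, 1L]; v <- edges[e, 2L]
    nv <- nv + 1L
    labels <- c(labels, NA_character_)
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(u, nv), c(v, nv), c(leaf, nv))
  }
  uprooted_network(edges, labels, n_vertices = nv)
}

# contract interior tree edges around a random interior vertex until its
# degree reaches L, then blow it up into a cycle of length L
# connected components of the subgraph induced on interior non-cycle vertices
interior_components <- function(net) {
  on_cycle <- cycle_membership_count(net) > 0L
  interior <- is.na(net$labels) & !on_cycle & net_degrees(net) >= 3L
  parent <- seq_len(net$n_vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(net$edges))) {
    u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
    if (interior[u] && interior[v]) {
      ru <- find(u); rv <- find(v)
      if (ru != rv) parent[ru] <- rv
    }
  }
  comp <- rep(NA_integer_, net$n_vertices)
  comp[interior] <- vapply(which(interior), find, integer(1))
  sizes <- table(comp)
  list(comp = comp, sizes = as.integer(sizes),
       size_of = stats::setNames(as.integer(sizes), names(sizes)))
}

grow_cycle <- function(net, L) {
  ic <- interior_components(net)
  cand <- which(!is.na(ic$comp) &
                  ic$size_of[as.character(ic$comp)] >= L - 2L)
  if (length(cand) == 0L) {
    stop("infeasible: no interior vertex can host a cycle of length ", L)
  }
  for (v in cand[sample.int(length(cand))]) {
    res <- try_grow_at(net, v, L)
    if (!is.null(res)) return(res)
  }
  stop("infeasible: no interior vertex can host a cycle of length ", L)
}

try_grow_at <- function(net, v, L) {
  while (net_degrees(net)[v] < L) {
    on_cycle <- cycle_membership_count(net) > 0L
    inc <- incident_edges(net, v)
    ok <- inc[vapply(inc, function(e) {
      w <- sum(net$edges[e, ]) - v
      is.na(net$labels[w]) && !on_cycle[w]
    }, logical(1))]
    if (length(ok) == 0L) return(NULL)
    e <- ok[sample.int(length(ok), 1L)]
    w <- sum(net$edges[e, ]) - v
    # contract w into v (keep v's id stable)
    edges <- net$edges[-e, , drop = FALSE]
    edges[edges == w] <- v
    net <- uprooted_network(edges, net$labels, n_vertices = net$n_vertices)
  }
  # v now has degree exactly L (each contraction adds one)
  inc <- incident_edges(net, v)
  nbrs <- vapply(inc, function(e) sum(net$edges[e, ]) - v, integer(1))
  nbrs <- nbrs[sample.int(length(nbrs))]
  w <- net$n_vertices + seq_len(L)
  keep <- !(net$edges[, 1L] == v | net$edges[, 2L] == v)
  edges <- rbind(net$edges[keep, , drop = FALSE],
                 cbind(w, c(w[-1L], w[1L])),
                 cbind(w, nbrs))
  compact_network(edges, c(net$labels, rep(NA_character_, L)))
}

#' Generate a random circular split system
#'
#' Draws a uniform random circular ordering of the taxa and subsamples its
#' interval splits: all trivial splits are always kept, and each nontrivial
#' interval split is kept independently with probability
#' `subsample_fraction` (at least one is kept).  The result is circular by
#' construction; the generating ordering is attached as attribute
#' `"ordering"`.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param subsample_fraction Probability of keeping each nontrivial interval
#'   split (default 0.5; 1 reproduces the full maximal circular system).
#' @param taxa Optional explicit taxon labels.
#' @param seed Optional integer seed.
#' @return A `split_system` with attribute `"ordering"`.
#' @export
random_circular_system <- function(n_taxa, subsample_fraction = 0.5,
                                   taxa = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) taxa <- as.character(seq_len(n_taxa))
  taxa <- check_ground_set(taxa)
  ordering <- circular_ordering(sample(taxa))
  full <- interval_splits(ordering)
  triv <- all_trivial_splits(taxa)
  nt <- ss_setdiff(full, triv)
  keep <- which(stats::runif(n_splits(nt)) <= subsample_fraction)
  if (length(keep) == 0L) keep <- sample.int(n_splits(nt), 1L)
  sigma <- ss_union(triv, ss_subset(nt, keep))
  attr(sigma, "ordering") <- ordering
  sigma
}
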