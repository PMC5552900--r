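## Embedding of a partially resolved 1-nested network into the Buneman graph
## of its displayed split system: non-leaf vertices map bijectively to gates.

#' Embed a 1-nested network into its Buneman graph
#'
#' Maps every non-leaf vertex `v` of the network to a gate of the Buneman
#' graph of its displayed splits: for a vertex on a cycle `C`, the selection
#' agrees with a reference taxon on the nontrivial splits displayed by `C`
#' and picks `max(S | .)` elsewhere; for a tree vertex the same with the
#' split of one incident cut edge.  The map is a bijection onto the gates
#' (checked by the caller via [buneman_gates()]); leaves map to their
#' Kuratowski vertices.
#'
#' @param net A 1-nested `uprooted_network` with no vertex shared by two
#'   cycles (apply [maximal_partial_resolution()] first if needed).
#' @param g Optional pre-built `buneman_graph` of `splits_of(net)$system`.
#' @return A list with `graph` (the `buneman_graph`), `vertex_map` (integer
#'   vector over network vertex ids: index of the image vertex in the graph,
#'   with leaves mapped to their Kuratowski vertices) and `sigma`.
#' @export
embed_network <- function(net, g = NULL) {
  diag <- validate_network(net)
  if (!diag$is_1_nested) stop("embed_network requires a 1-nested network")
  cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
  if (any(cycle_membership_count(net, cycles) > 1L)) {
    stop("network is not partially resolved: two cycles share a vertex")
  }
  sm <- splits_of(net)
  sigma <- sm$system
  if (is.null(g)) g <- buneman_graph(sigma)
  taxa <- sigma$taxa
  keys <- system_keys(sigma)
  comps <- incompatibility_components(sigma)
  # component index of every split
  comp_of <- integer(n_splits(sigma))
  for (ci in seq_along(comps$members)) comp_of[comps$members[[ci]]] <- ci
  vertex_map <- rep(NA_integer_, net$n_vertices)
  for (x in taxa) {
    vertex_map[which(net$labels == x)] <- g$kuratowski[[x]]
  }
  for (v in seq_len(net$n_vertices)) {
    if (!is.na(net$labels[v])) next
    ci <- which(vapply(cycles, function(cy) v %in% cy$vertices, logical(1)))
    if (length(ci) == 1L) {
      # the cycle's component: the unique >=2-member component among the
      # splits the cycle displays (an m-split that doubles as a cut-edge
      # split sits in its own singleton component and is excluded; using the
      # raw nontrivial cycle system would merge the images of a partially
      # resolved vertex and its attachment vertex)
      cy <- cycles[[ci]]
      cyc_idx <- match(system_keys(sm$cycle_systems[[ci]]), keys)
      cands <- unique(comp_of[cyc_idx])
      cands <- cands[lengths(comps$members[cands]) >= 2L]
      if (length(cands) != 1L) stop("cycle does not map to a unique component")
      comp <- comps$members[[cands]]
      x_v <- taxa[reachable_leafset(net, v, cy$edges, taxa)][1L]
    } else {
      e_v <- incident_edges(net, v)[1L]
      blk <- reachable_leafset(net, net$edges[e_v, 1L], e_v, taxa)
      if (!blk[1L]) blk <- !blk
      comp <- match(split_key(blk), keys)
      x_v <- taxa[reachable_leafset(net, v, e_v, taxa)][1L]
    }
    sel <- gate(kuratowski_map(x_v, sigma), g, comp)
    gv <- bg_vertex_index(g, sel)
    if (is.null(gv)) stop("embedded image is not a Buneman vertex")
    vertex_map[v] <- gv
  }
  list(graph = g, vertex_map = vertex_map, sigma = sigma)
}
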