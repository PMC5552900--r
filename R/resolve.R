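## Partial resolution moves (R1)/(R2), their converses, the canonical
## unresolved form, and leaf-label-respecting isomorphism.

# drop unused vertex ids and renumber compactly
compact_network <- function(edges, labels) {
  used <- sort(unique(as.vector(edges)))
  remap <- integer(length(labels))
  remap[used] <- seq_along(used)
  uprooted_network(matrix(remap[edges], ncol = 2L), labels[used],
                   n_vertices = length(used))
}

#' Partially resolve a vertex of a 1-nested network
#'
#' Applies the split-preserving replacement move at `vertex`:
#' \describe{
#'   \item{R1}{a cycle vertex with 2 or more incident non-cycle edges: all of
#'     them are moved to a new vertex joined to the cycle vertex by a new cut
#'     edge;}
#'   \item{R2}{a cut vertex shared by two cycles: one cycle is pulled onto a
#'     new vertex joined to the old one by a new cut edge.}
#' }
#' The displayed split set is unchanged; the split multiset is not.
#'
#' @param net A 1-nested `uprooted_network`.
#' @param vertex Vertex id.
#' @return The resolved `uprooted_network`.
#' @export
partially_resolve <- function(net, vertex) {
  cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
  mine <- which(vapply(cycles, function(cy) vertex %in% cy$vertices, logical(1)))
  edges <- net$edges
  labels <- c(net$labels, NA_character_)
  w <- net$n_vertices + 1L
  if (length(mine) >= 2L) {
    # (R2): move the edges of one cycle (the one listed last) onto w
    move <- intersect(cycles[[mine[length(mine)]]]$edges, incident_edges(net, vertex))
  } else if (length(mine) == 1L) {
    move <- setdiff(incident_edges(net, vertex), cycles[[mine]]$edges)
    if (length(move) < 2L) stop("vertex not eligible for partial resolution")
  } else {
    stop("vertex not eligible for partial resolution")
  }
  for (e in move) {
    edges[e, ] <- sort(c(sum(edges[e, ]) - vertex, w))
  }
  uprooted_network(rbind(edges, sort(c(vertex, w))), labels, n_vertices = w)
}

# is edge row e eligible for contraction by (R1') or (R2')?
unresolve_eligible <- function(net, e, cycles = NULL, degrees = NULL) {
  if (is.null(cycles)) cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
  if (is.null(degrees)) degrees <- net_degrees(net)
  on_cycle_edge <- any(vapply(cycles, function(cy) e %in% cy$edges, logical(1)))
  if (on_cycle_edge) return(FALSE)
  u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
  if (!is.na(net$labels[u]) || !is.na(net$labels[v])) return(FALSE)
  cyc_count <- cycle_membership_count(net, cycles)
  u_cyc <- cyc_count[u] > 0L
  v_cyc <- cyc_count[v] > 0L
  if (u_cyc && v_cyc) return(TRUE)                      # (R2')
  if (u_cyc && !v_cyc && degrees[u] == 3L) return(TRUE) # (R1')
  if (v_cyc && !u_cyc && degrees[v] == 3L) return(TRUE)
  FALSE
}

#' Undo a partial resolution by contracting a cut edge
#'
#' Contracts the internal cut edge `edge` (given as a pair of vertex ids),
#' inverting (R1) or (R2).  The edge must join two cycle vertices (R2'), or
#' a degree-3 cycle vertex to an interior tree vertex (R1'); either way the
#' displayed split set is preserved.
#'
#' @param net A 1-nested `uprooted_network`.
#' @param edge Length-2 integer vector of vertex ids.
#' @return The contracted `uprooted_network`.
#' @export
unresolve <- function(net, edge) {
  edge <- sort(as.integer(edge))
  e <- which(net$edges[, 1L] == edge[1L] & net$edges[, 2L] == edge[2L])
  if (length(e) != 1L) stop("no such edge")
  if (!unresolve_eligible(net, e)) stop("edge not eligible for (R1')/(R2') contraction")
  contract_edge(net, e)
}

contract_edge <- function(net, e) {
  u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
  edges <- net$edges[-e, , drop = FALSE]
  edges[edges == v] <- u
  compact_network(edges, net$labels)
}

#' Canonical unresolved form of a 1-nested network
#'
#' Exhaustively applies the converse resolution moves (R1')/(R2'),
#' contracting pendant-attachment cut edges into their cycle vertices and
#' merging cut edges between two cycles into shared vertices.  All partial
#' resolutions of the same network reach the same fixpoint, which therefore
#' canonicalizes networks up to partial resolution.
#'
#' @param net A 1-nested `uprooted_network`.
#' @return An `uprooted_network`.
#' @export
canonical_unresolved_form <- function(net) {
  repeat {
    cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
    if (length(cycles) == 0L) return(net)
    degrees <- net_degrees(net)
    el <- which(vapply(seq_len(nrow(net$edges)),
                       function(e) unresolve_eligible(net, e, cycles, degrees),
                       logical(1)))
    if (length(el) == 0L) return(net)
    net <- contract_edge(net, el[1L])
  }
}

#' Maximal partial resolution of a 1-nested network
#'
#' Applies (R2) to every vertex shared by two cycles and (R1) to every cycle
#' vertex carrying two or more non-cycle edges until neither applies: the
#' result is level-1-ward maximal, with every cycle vertex of degree 3.
#'
#' @param net A 1-nested `uprooted_network`.
#' @return An `uprooted_network`.
#' @export
maximal_partial_resolution <- function(net) {
  repeat {
    cycles <- Filter(function(cy) cy$is_cycle, net_cycles(net))
    if (length(cycles) == 0L) return(net)
    cnt <- cycle_membership_count(net, cycles)
    shared <- which(cnt >= 2L)
    if (length(shared) > 0L) {
      net <- partially_resolve(net, shared[1L])
      next
    }
    done <- TRUE
    for (ci in seq_along(cycles)) {
      for (v in cycles[[ci]]$vertices) {
        if (length(setdiff(incident_edges(net, v), cycles[[ci]]$edges)) >= 2L) {
          net <- partially_resolve(net, v)
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) return(net)
  }
}

#' Leaf-label-respecting graph isomorphism
#'
#' Tests whether two uprooted networks are isomorphic by a graph isomorphism
#' that is the identity on the taxon set (leaf labels pinned, interior
#' vertex ids ignored).  Uses VF2 with vertex colors.
#'
#' @param n1,n2 `uprooted_network` objects on the same taxon set.
#' @return Logical.
#' @export
networks_isomorphic <- function(n1, n2) {
  taxa <- net_taxa(n1)
  if (!identical(taxa, net_taxa(n2))) return(FALSE)
  if (n1$n_vertices != n2$n_vertices || nrow(n1$edges) != nrow(n2$edges)) return(FALSE)
  color <- function(net) {
    cl <- match(net$labels, taxa)
    cl[is.na(cl)] <- 0L
    cl
  }
  igraph::is_isomorphic_to(as_igraph(n1), as_igraph(n2), method = "vf2",
                           vertex.color1 = color(n1), vertex.color2 = color(n2))
}

#' Isomorphism up to partial resolution
#'
#' Two 1-nested networks display the same split system iff their canonical
#' unresolved forms are leaf-label-respecting isomorphic; this implements
#' the uniqueness notion of the reconstruction theory ("unique up to
#' isomorphism and partial resolution").
#'
#' @param n1,n2 1-nested `uprooted_network` objects.
#' @return Logical.
#' @export
isomorphic_up_to_resolution <- function(n1, n2) {
  networks_isomorphic(canonical_unresolved_form(n1), canonical_unresolved_form(n2))
}
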