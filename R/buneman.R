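## Buneman (median) graph of a split system: vertex enumeration, ladders,
## blocks <-> incompatibility components, gates, marguerites, and the
## embedding of a 1-nested network.
##
## A vertex is a side-selection map phi assigning to every split one of its
## sides so that all chosen sides pairwise intersect; it is stored as a
## logical vector over the canonical split order (TRUE = the canonical side,
## the one containing the minimum taxon).  Two vertices are adjacent when
## they differ in exactly one split, and graph distance equals the number of
## splits on which they differ.

#' Build the Buneman graph of a split system
#'
#' Enumerates all consistent side-selection maps by backtracking over the
#' splits in canonical order (increasing size, then lexicographic), pruning
#' as soon as two chosen sides fail to intersect.  Edges join selections at
#' symmetric difference one and carry the split on which they differ.  When
#' the system contains all trivial splits, the degree-1 vertices are exactly
#' the Kuratowski maps, identified with the taxa.
#'
#' @param sigma A nonempty `split_system`.
#' @param cap Maximum number of splits admitted to the exponential
#'   enumeration (default 25).
#' @return An object of class `buneman_graph`: list with `sigma`,
#'   `selections` (V x m logical matrix), `edges` (2-column matrix of vertex
#'   indices), `edge_split` (row index into `sigma` per edge), `kuratowski`
#'   (named vertex index per taxon, NA when the Kuratowski map of a taxon is
#'   not a vertex -- it always is).
#' @export
buneman_graph <- function(sigma, cap = 25L) {
  m <- n_splits(sigma)
  if (m == 0L) stop("empty split system")
  if (m > cap) stop(sprintf("Buneman enumeration cap exceeded: %d splits > cap %d", m, cap))
  blocks <- sigma$blocks
  # empty[i, j, ci, cj]: is side ci of split i disjoint from side cj of j?
  side <- function(i, c) if (c == 1L) blocks[i, ] else !blocks[i, ]
  empty <- array(FALSE, c(m, m, 2L, 2L))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      for (ci in 1:2) for (cj in 1:2) {
        empty[i, j, ci, cj] <- !any(side(i, ci) & side(j, cj))
      }
    }
  }
  sel <- integer(m)  # 1 = canonical side, 2 = complement
  out <- list()
  recurse <- function(depth) {
    if (depth > m) {
      out[[length(out) + 1L]] <<- sel == 1L
      return(invisible(NULL))
    }
    for (c in 1:2) {
      ok <- TRUE
      for (j in seq_len(depth - 1L)) {
        if (empty[depth, j, c, sel[j]]) { ok <- FALSE; break }
      }
      if (ok) {
        sel[depth] <<- c
        recurse(depth + 1L)
      }
    }
    invisible(NULL)
  }
  recurse(1L)
  selections <- do.call(rbind, out)
  keys <- apply(selections, 1L, function(r) paste(as.integer(r), collapse = ""))
  ord <- order(keys, method = "radix")
  selections <- selections[ord, , drop = FALSE]
  keys <- keys[ord]
  index <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) assign(keys[i], i, envir = index)
  # edges: flip each coordinate, look up
  e_from <- integer(0); e_to <- integer(0); e_split <- integer(0)
  for (v in seq_len(nrow(selections))) {
    r <- selections[v, ]
    for (s in seq_len(m)) {
      r2 <- r
      r2[s] <- !r2[s]
      key2 <- paste(as.integer(r2), collapse = "")
      w <- index[[key2]]
      if (!is.null(w) && w > v) {
        e_from <- c(e_from, v); e_to <- c(e_to, w); e_split <- c(e_split, s)
      }
    }
  }
  kur <- vapply(sigma$taxa, function(x) {
    r <- blocks[, match(x, sigma$taxa)]
    index[[paste(as.integer(r), collapse = "")]]
  }, integer(1))
  structure(list(sigma = sigma, selections = selections,
                 edges = cbind(e_from, e_to), edge_split = e_split,
                 kuratowski = kur, keys = keys),
            class = "buneman_graph")
}

#' @export
print.buneman_graph <- function(x, ...) {
  cat(sprintf("Buneman graph: %d vertices, %d edges over %d splits\n",
              nrow(x$selections), nrow(x$edges), n_splits(x$sigma)))
  invisible(x)
}

bg_igraph <- function(g) {
  gr <- igraph::make_empty_graph(n = nrow(g$selections), directed = FALSE)
  igraph::add_edges(gr, as.vector(t(g$edges)))
}

bg_vertex_index <- function(g, selection) {
  key <- paste(as.integer(selection), collapse = "")
  i <- match(key, g$keys)
  if (is.na(i)) NULL else i
}

bg_degrees <- function(g) tabulate(g$edges, nbins = nrow(g$selections))

#' Kuratowski map of a taxon
#'
#' The selection choosing, for every split, the side containing `x`; always
#' a consistent Buneman vertex, and a degree-1 vertex of the graph when the
#' system contains all trivial splits.
#'
#' @param x A taxon label.
#' @param sigma A `split_system` containing `x` in its ground set.
#' @return Logical selection vector over the splits of `sigma`.
#' @export
kuratowski_map <- function(x, sigma) {
  i <- match(x, sigma$taxa)
  if (is.na(i)) stop("taxon not in ground set")
  sigma$blocks[, i]
}

#' Splits Bu-displayed by a Buneman graph
#'
#' For each split, the "ladder" of parallel edges tagged with it is deleted;
#' the graph falls into exactly two components whose Kuratowski maps are
#' partitioned as the split partitions the taxa.  The Bu-displayed system is
#' exactly the system the graph was built from, which this function asserts
#' before returning it.
#'
#' @param g A `buneman_graph`.
#' @return The `split_system` of Bu-displayed splits.
#' @export
bu_displayed_splits <- function(g) {
  gr <- bg_igraph(g)
  taxa <- g$sigma$taxa
  rows <- list()
  for (s in seq_len(n_splits(g$sigma))) {
    ladder <- which(g$edge_split == s)
    comp <- igraph::components(igraph::delete_edges(gr, ladder))
    if (comp$no != 2L) stop("ladder deletion did not yield two components")
    block <- comp$membership[g$kuratowski] == comp$membership[g$kuratowski[1L]]
    if (!identical(unname(block), unname(g$sigma$blocks[s, ]))) {
      stop("Bu-displayed split differs from the generating split")
    }
    rows[[s]] <- block
  }
  new_split_system(taxa, do.call(rbind, rows))
}

## ---- blocks and gates -----------------------------------------------------

# For a split S (row index s, not in component `comp`), the side of S that
# intersects both sides of every split in the component: max(S | Sigma_0).
# Returns TRUE if that side is the canonical block side.
max_side <- function(sigma, s, comp) {
  a <- sigma$blocks[s, ]
  ok <- c(TRUE, TRUE)
  for (cand in 1:2) {
    sd <- if (cand == 1L) a else !a
    for (j in comp) {
      b <- sigma$blocks[j, ]
      if (!any(sd & b) || !any(sd & !b)) { ok[cand] <- FALSE; break }
    }
  }
  if (sum(ok) != 1L) stop("max(S | Sigma') is not well defined here")
  ok[1L]
}

#' Blocks of the Buneman graph and their incompatibility components
#'
#' Realizes the 1-1 correspondence between the connected components of the
#' incompatibility graph and the blocks (maximal 2-connected subgraphs) of
#' the Buneman graph: component `Sigma_0` maps to the block of all vertices
#' selecting `max(S | Sigma_0)` outside `Sigma_0`.
#'
#' @param g A `buneman_graph`.
#' @return A list with `components` (an `incompatibility_components`) and
#'   `blocks` (list of integer vertex-index vectors, one per component, in
#'   the same order).
#' @export
buneman_blocks <- function(g) {
  sigma <- g$sigma
  comps <- incompatibility_components(sigma)
  m <- n_splits(sigma)
  blocks <- lapply(comps$members, function(comp) {
    outside <- setdiff(seq_len(m), comp)
    want <- vapply(outside, function(s) max_side(sigma, s, comp), logical(1))
    keep <- rep(TRUE, nrow(g$selections))
    for (t in seq_along(outside)) {
      keep <- keep & (g$selections[, outside[t]] == want[t])
    }
    which(keep)
  })
  list(components = comps, blocks = blocks)
}

#' Gate of a vertex in the block of a component
#'
#' The unique block vertex on all shortest paths from `phi` into the block:
#' it agrees with `phi` on the component's splits and selects
#' `max(S | Sigma_0)` elsewhere.
#'
#' @param phi Logical selection vector (a vertex of `g`).
#' @param g A `buneman_graph`.
#' @param comp Integer vector of split row indices forming one
#'   incompatibility component of `g$sigma`.
#' @return Logical selection vector of the gate.
#' @export
gate <- function(phi, g, comp) {
  sigma <- g$sigma
  out <- phi
  for (s in setdiff(seq_len(n_splits(sigma)), comp)) {
    out[s] <- max_side(sigma, s, comp)
  }
  out
}

#' Gates of a Buneman graph
#'
#' The gates of the Kuratowski maps in every block, excluding the Kuratowski
#' maps themselves (a taxon is trivially its own gate in its pendant block).
#' For split systems of 1-nested networks these are in bijection with the
#' non-leaf vertices of the network.
#'
#' @param g A `buneman_graph`.
#' @return Integer vector of vertex indices.
#' @export
buneman_gates <- function(g) {
  bb <- buneman_blocks(g)
  out <- integer(0)
  for (comp in bb$components$members) {
    for (x in g$sigma$taxa) {
      gv <- bg_vertex_index(g, gate(kuratowski_map(x, g$sigma), g, comp))
      if (is.null(gv)) stop("gate is not a vertex of the graph")
      out <- c(out, gv)
    }
  }
  sort(setdiff(unique(out), g$kuratowski))
}
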