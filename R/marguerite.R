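## Marguerites: the distinguished subgraph of the Buneman graph of a maximal
## circular split system (minus trivial splits) whose external vertices carry
## the cycle of the reconstructed network.

# arc [a, b] of 1..k (inclusive, modulo k, representatives 1..k)
arc_1k <- function(a, b, k) {
  a <- ((a - 1L) %% k) + 1L
  b <- ((b - 1L) %% k) + 1L
  if (a <= b) a:b else c(a:k, 1:b)
}

# the split system Sigma_k: maximal circular on taxa 1..k in lexicographic
# cyclic order, with the trivial splits removed
sigma_k_system <- function(k) {
  nontrivial_splits(interval_splits(circular_ordering(as.character(1:k))))
}

#' Construct the k-marguerite
#'
#' Builds the maximal circular split system on k taxa (cyclic order
#' 1,...,k) minus its trivial splits, and the subgraph of its Buneman graph
#' induced by the maps `phi_i^j` (0 <= j < k-3, with `phi_i^(k-3)`
#' identified with `phi_(i+1)^0`) and `psi_i^j` (1 <= j < k-3).  The map
#' `phi_i^j` flips a split away from taxon i exactly when the side of i is
#' contained in the arc `[i-j, i]`; `psi_i^j` further flips the
#' adjacent-pair split `[i, i+1] | rest`.  Every constructed map is checked
#' to be a consistent Buneman vertex.  External vertices are the `phi_i^0`;
#' external edges the `{phi_i^j, phi_i^(j+1)}`.
#'
#' @param k Cycle length, at least 4.
#' @return A list with `sigma` (the system `Sigma_k`), `selections` (vertex
#'   rows), `ids` (data.frame `kind`, `i`, `j` of one representative id per
#'   vertex), `all_ids` (every (kind,i,j) with the vertex row it landed on),
#'   `edges` (induced edges as index pairs), `external_vertices`,
#'   `external_edges` (logical over rows of `edges`).
#' @export
marguerite <- function(k) {
  k <- as.integer(k)
  if (k < 4L) stop("marguerites need k >= 4")
  sigma <- sigma_k_system(k)
  m <- n_splits(sigma)
  taxa <- sigma$taxa
  phi_sel <- function(i, j) {
    arc <- as.character(arc_1k(i - j, i, k))
    vapply(seq_len(m), function(s) {
      blk <- sigma$blocks[s, ]
      side_i <- if (blk[match(as.character(i), taxa)]) blk else !blk
      flip <- all(taxa[side_i] %in% arc)
      chosen <- if (flip) !side_i else side_i
      identical(chosen, blk)
    }, logical(1))
  }
  s_plus_index <- function(i) {
    pair <- as.character(arc_1k(i, i + 1L, k))
    blk <- taxa %in% pair
    if (!blk[1L]) blk <- !blk
    match(split_key(blk), system_keys(sigma))
  }
  consistent <- function(sel) {
    for (a in seq_len(m - 1L)) {
      sa <- if (sel[a]) sigma$blocks[a, ] else !sigma$blocks[a, ]
      for (b in (a + 1L):m) {
        sb <- if (sel[b]) sigma$blocks[b, ] else !sigma$blocks[b, ]
        if (!any(sa & sb)) return(FALSE)
      }
    }
    TRUE
  }
  rows <- list(); ids <- list(); all_ids <- list()
  key_of <- function(sel) paste(as.integer(sel), collapse = "")
  seen <- character(0)
  add_map <- function(kind, i, j, sel) {
    if (!consistent(sel)) {
      stop(sprintf("map %s_%d^%d is not a consistent Buneman vertex", kind, i, j))
    }
    key <- key_of(sel)
    at <- match(key, seen)
    if (is.na(at)) {
      rows[[length(rows) + 1L]] <<- sel
      seen[length(seen) + 1L] <<- key
      ids[[length(ids) + 1L]] <<- data.frame(kind = kind, i = i, j = j)
      at <- length(seen)
    }
    all_ids[[length(all_ids) + 1L]] <<- data.frame(kind = kind, i = i, j = j,
                                                   vertex = at)
    at
  }
  for (i in seq_len(k)) {
    for (j in 0:(k - 4L)) add_map("phi", i, j, phi_sel(i, j))
  }
  if (k >= 5L) {
    for (i in seq_len(k)) {
      sp <- s_plus_index(i)
      for (j in seq_len(k - 4L)) {
        sel <- phi_sel(i, j)
        sel[sp] <- !sel[sp]
        add_map("psi", i, j, sel)
      }
    }
  }
  selections <- do.call(rbind, rows)
  ids <- do.call(rbind, ids)
  all_ids <- do.call(rbind, all_ids)
  nv <- nrow(selections)
  e_from <- integer(0); e_to <- integer(0)
  for (a in seq_len(nv - 1L)) {
    for (b in (a + 1L):nv) {
      if (sum(selections[a, ] != selections[b, ]) == 1L) {
        e_from <- c(e_from, a); e_to <- c(e_to, b)
      }
    }
  }
  vertex_of <- function(kind, i, j) {
    hit <- all_ids$vertex[all_ids$kind == kind & all_ids$i == i & all_ids$j == j]
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  external_vertices <- vapply(seq_len(k), function(i) vertex_of("phi", i, 0L),
                              integer(1))
  ext_pairs <- do.call(rbind, unlist(lapply(seq_len(k), function(i) {
    lapply(0:(k - 4L), function(j) {
      a <- vertex_of("phi", i, j)
      b <- if (j + 1L <= k - 4L) vertex_of("phi", i, j + 1L) else vertex_of("phi", ((i) %% k) + 1L, 0L)
      sort(c(a, b))
    })
  }), recursive = FALSE))
  edge_key <- paste(e_from, e_to)
  external_edges <- edge_key %in% paste(ext_pairs[, 1L], ext_pairs[, 2L])
  list(sigma = sigma, selections = selections, ids = ids, all_ids = all_ids,
       edges = cbind(e_from, e_to), external_vertices = external_vertices,
       external_edges = external_edges, k = k)
}
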