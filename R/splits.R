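## ---- taxon ordering -------------------------------------------------------

# Natural (numeric-aware) sort key: digit runs are zero-padded so that "10"
# sorts after "9".  Labels must be nonempty.
natural_key <- function(x) {
  stopifnot(is.character(x), all(nzchar(x)))
  vapply(x, function(lab) {
    parts <- regmatches(lab, gregexpr("[0-9]+|[^0-9]+", lab))[[1]]
    digits <- grepl("^[0-9]+$", parts)
    parts[digits] <- formatC(sub("^0+(?=.)", "", parts[digits], perl = TRUE),
                             width = 12, flag = "0")
    paste(parts, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

natural_sort <- function(x) x[order(natural_key(x), method = "radix")]

check_ground_set <- function(taxa) {
  if (!is.character(taxa)) taxa <- as.character(taxa)
  if (length(taxa) < 3L) stop("a ground set needs at least 3 taxa")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels in ground set")
  if (!all(nzchar(taxa))) stop("empty taxon label")
  natural_sort(taxa)
}

## ---- splits ---------------------------------------------------------------

#' Create a canonical split of a taxon set
#'
#' A split is an unordered bipartition `{A, X - A}` of the ground set `X`.
#' The canonical representative stores the side containing the minimum taxon
#' (in natural, numeric-aware label order), so `make_split(A, X)` and
#' `make_split(X - A, X)` yield identical objects.
#'
#' @param side Character vector: one side of the bipartition (nonempty,
#'   proper subset of `ground_set`).
#' @param ground_set Character vector of all taxa (at least 3, unique labels).
#' @return An object of class `nsplit`.
#' @examples
#' s <- make_split(c("3", "4", "5"), as.character(1:5))
#' print(s)                      # canonical side is {1,2}
#' split_size(s)                 # 2
#' @export
make_split <- function(side, ground_set) {
  taxa <- check_ground_set(ground_set)
  side <- as.character(side)
  if (anyDuplicated(side)) stop("duplicate taxa in split side")
  if (!all(side %in% taxa)) stop("split side contains taxa outside the ground set")
  if (length(side) == 0L) stop("invalid split: empty side")
  if (length(side) >= length(taxa)) stop("invalid split: side is not a proper subset")
  block <- taxa %in% side
  if (!block[1L]) block <- !block
  structure(list(taxa = taxa, block = block), class = "nsplit")
}

new_split_raw <- function(taxa, block) {
  if (!block[1L]) block <- !block
  structure(list(taxa = taxa, block = block), class = "nsplit")
}

#' @export
format.nsplit <- function(x, ...) {
  paste(paste(x$taxa[x$block], collapse = " "), "|",
        paste(x$taxa[!x$block], collapse = " "))
}

#' @export
print.nsplit <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Split utilities
#'
#' `split_size()` is the size of the smaller side; `is_trivial_split()` tests
#' for size one; `split_sides()` returns both sides as character vectors
#' (canonical side first); `split_side_of()` returns the side containing a
#' given taxon.
#'
#' @param s An `nsplit`.
#' @param x A taxon label.
#' @name split-utils
#' @export
split_size <- function(s) min(sum(s$block), sum(!s$block))

#' @rdname split-utils
#' @export
is_trivial_split <- function(s) split_size(s) == 1L

#' @rdname split-utils
#' @export
split_sides <- function(s) list(s$taxa[s$block], s$taxa[!s$block])

#' @rdname split-utils
#' @export
split_side_of <- function(s, x) {
  stopifnot(x %in% s$taxa)
  if (s$block[match(x, s$taxa)]) s$taxa[s$block] else s$taxa[!s$block]
}

split_key <- function(block) paste(as.integer(block), collapse = "")

#' Test whether two splits are equal
#' @param s1,s2 `nsplit` objects on the same ground set.
#' @export
splits_equal <- function(s1, s2) {
  identical(s1$taxa, s2$taxa) && identical(s1$block, s2$block)
}

## ---- split systems --------------------------------------------------------

#' Construct a split system
#'
#' A split system is a set of splits over one ground set, stored as a
#' canonical logical incidence matrix (rows are splits, columns are taxa in
#' natural order; each row records the side containing the minimum taxon).
#' Duplicates are removed and rows are sorted deterministically (by split
#' size, then lexicographically), so two systems with the same splits are
#' `identical()`.
#'
#' @param sides List of character vectors, one side per split, or a list of
#'   `nsplit` objects.
#' @param taxa Character vector of ground-set taxa; may be omitted when
#'   `sides` holds `nsplit` objects.
#' @param allow_empty Permit a system with no splits (used by a few internal
#'   operations; split systems are assumed nonempty by default).
#' @return An object of class `split_system` with fields `taxa` and `blocks`.
#' @examples
#' ss <- split_system(list(c("1", "2"), c("2", "3")), taxa = as.character(1:5))
#' n_splits(ss)
#' @export
split_system <- function(sides, taxa = NULL, allow_empty = FALSE) {
  if (length(sides) > 0L && inherits(sides[[1L]], "nsplit")) {
    if (is.null(taxa)) taxa <- sides[[1L]]$taxa
    taxa <- check_ground_set(taxa)
    for (s in sides) {
      if (!identical(s$taxa, taxa)) stop("ground-set mismatch between splits")
    }
    blocks <- do.call(rbind, lapply(sides, function(s) s$block))
  } else {
    if (is.null(taxa)) stop("taxa must be given when sides are plain vectors")
    taxa <- check_ground_set(taxa)
    blocks <- do.call(rbind, lapply(sides, function(a) {
      s <- make_split(a, taxa)
      s$block
    }))
  }
  if (is.null(blocks)) blocks <- matrix(logical(0), 0L, length(taxa))
  new_split_system(taxa, blocks, allow_empty = allow_empty)
}

new_split_system <- function(taxa, blocks, allow_empty = FALSE) {
  colnames(blocks) <- taxa
  if (nrow(blocks) > 0L) {
    flip <- !blocks[, 1L]
    blocks[flip, ] <- !blocks[flip, , drop = FALSE]
    keys <- apply(blocks, 1L, split_key)
    keep <- !duplicated(keys)
    blocks <- blocks[keep, , drop = FALSE]
    keys <- keys[keep]
    sizes <- pmin(rowSums(blocks), length(taxa) - rowSums(blocks))
    ord <- order(sizes, keys, method = "radix")
    blocks <- blocks[ord, , drop = FALSE]
  }
  if (nrow(blocks) == 0L && !allow_empty) stop("split system is empty")
  structure(list(taxa = taxa, blocks = blocks), class = "split_system")
}

#' @rdname split_system
#' @param sigma A `split_system`.
#' @export
n_splits <- function(sigma) nrow(sigma$blocks)

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("Split system on %d taxa with %d split(s)\n",
              length(x$taxa), n_splits(x)))
  for (i in seq_len(n_splits(x))) cat("  ", format(get_split(x, i)), "\n", sep = "")
  invisible(x)
}

#' Extract the i-th split of a system as an `nsplit`
#' @param sigma A `split_system`.
#' @param i Row index.
#' @export
get_split <- function(sigma, i) {
  new_split_raw(sigma$taxa, unname(sigma$blocks[i, ]))
}

#' All splits of a system as a list of `nsplit` objects
#' @param sigma A `split_system`.
#' @export
system_splits <- function(sigma) {
  lapply(seq_len(n_splits(sigma)), function(i) get_split(sigma, i))
}

system_keys <- function(sigma) {
  if (n_splits(sigma) == 0L) return(character(0))
  apply(sigma$blocks, 1L, split_key)
}

#' Set operations and predicates on split systems
#'
#' `ss_equal()` tests set equality; `ss_contains()` membership of a split;
#' `ss_union()` merges systems on the same ground set; `ss_subset()` keeps
#' the given row indices; `ss_setdiff()` removes the splits of `s2` from
#' `s1`; `nontrivial_splits()` drops all trivial splits
#' and `all_trivial_splits()` builds the n trivial splits of a ground set.
#'
#' @param s1,s2,sigma `split_system` objects.
#' @param s An `nsplit`.
#' @param idx Integer vector of row indices.
#' @param taxa Ground-set character vector.
#' @name system-ops
#' @export
ss_equal <- function(s1, s2) {
  identical(s1$taxa, s2$taxa) && identical(unname(s1$blocks), unname(s2$blocks))
}

#' @rdname system-ops
#' @export
ss_contains <- function(sigma, s) {
  stopifnot(identical(sigma$taxa, s$taxa))
  split_key(s$block) %in% system_keys(sigma)
}

#' @rdname system-ops
#' @export
ss_union <- function(s1, s2) {
  stopifnot(identical(s1$taxa, s2$taxa))
  new_split_system(s1$taxa, rbind(s1$blocks, s2$blocks))
}

#' @rdname system-ops
#' @export
ss_subset <- function(sigma, idx) {
  new_split_system(sigma$taxa, sigma$blocks[idx, , drop = FALSE],
                   allow_empty = TRUE)
}

#' @rdname system-ops
#' @export
ss_setdiff <- function(s1, s2) {
  stopifnot(identical(s1$taxa, s2$taxa))
  keep <- !(system_keys(s1) %in% system_keys(s2))
  ss_subset(s1, which(keep))
}

#' @rdname system-ops
#' @export
ss_issubset <- function(s1, s2) {
  stopifnot(identical(s1$taxa, s2$taxa))
  all(system_keys(s1) %in% system_keys(s2))
}

#' @rdname system-ops
#' @export
nontrivial_splits <- function(sigma) {
  sz <- pmin(rowSums(sigma$blocks), length(sigma$taxa) - rowSums(sigma$blocks))
  ss_subset(sigma, which(sz > 1L))
}

#' @rdname system-ops
#' @export
all_trivial_splits <- function(taxa) {
  taxa <- check_ground_set(taxa)
  split_system(lapply(taxa, identity), taxa = taxa)
}

#' @rdname system-ops
#' @export
has_all_trivial_splits <- function(sigma) {
  ss_issubset(all_trivial_splits(sigma$taxa), sigma)
}

## ---- compatibility --------------------------------------------------------

compatible_blocks <- function(a, b) {
  # distinct splits are compatible iff one of the four side intersections is
  # empty; equal splits are defined compatible
  !any(a & b) || !any(a & !b) || !any(!a & b) || !any(!a & !b)
}

#' Compatibility of two splits
#'
#' Two distinct splits `{A1, B1}` and `{A2, B2}` are compatible when one of
#' the four side intersections is empty (equivalently, one side strictly
#' contains a side of the other).  Equal splits are defined compatible so
#' that system compatibility reduces to pairwise checks.
#'
#' @param s1,s2 `nsplit` objects on the same ground set.
#' @return Logical.
#' @export
are_compatible <- function(s1, s2) {
  if (!identical(s1$taxa, s2$taxa)) stop("ground-set mismatch")
  compatible_blocks(s1$block, s2$block)
}

# m x m logical matrix of pairwise compatibility (diagonal TRUE)
compatibility_matrix <- function(sigma) {
  m <- n_splits(sigma)
  cm <- matrix(TRUE, m, m)
  if (m < 2L) return(cm)
  for (i in seq_len(m - 1L)) {
    a <- sigma$blocks[i, ]
    for (j in (i + 1L):m) {
      cm[i, j] <- cm[j, i] <- compatible_blocks(a, sigma$blocks[j, ])
    }
  }
  cm
}

#' Is a split system compatible?
#' @param sigma A `split_system`.
#' @export
is_compatible_system <- function(sigma) {
  all(compatibility_matrix(sigma))
}

#' Connected components of the incompatibility graph
#'
#' The incompatibility graph `Incomp(sigma)` has the splits as vertices and
#' joins two splits when they are incompatible.  Its connected components
#' partition the system; splits in different components are pairwise
#' compatible, and the system is compatible exactly when all components are
#' singletons.
#'
#' @param sigma A nonempty `split_system`.
#' @return An object of class `incompatibility_components`: a list with
#'   `members` (list of integer index vectors into the rows of `sigma`),
#'   `systems` (the corresponding sub-systems) and `sigma`.
#' @export
incompatibility_components <- function(sigma) {
  if (n_splits(sigma) == 0L) stop("empty split system")
  cm <- compatibility_matrix(sigma)
  # union-find over incompatible pairs
  parent <- seq_len(nrow(cm))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(nrow(cm))) {
      if (j > i && !cm[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  members <- split(seq_along(roots), roots)
  # deterministic order: by smallest member index
  members <- members[order(vapply(members, min, integer(1)))]
  names(members) <- NULL
  structure(list(members = members,
                 systems = lapply(members, function(ix) ss_subset(sigma, ix)),
                 sigma = sigma),
            class = "incompatibility_components")
}

#' @export
print.incompatibility_components <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("Incomp(Sigma): %d component(s) of sizes %s\n",
              length(sizes), paste(sizes, collapse = ", ")))
  invisible(x)
}
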