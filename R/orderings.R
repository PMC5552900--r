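## Circular orderings of the taxon set and interval (circular) split systems.

#' Create a canonical circular ordering
#'
#' A circular ordering is a cyclic arrangement of all taxa.  The canonical
#' form fixes rotation by starting at the minimum taxon (natural label
#' order) and fixes reflection by requiring the second element to precede
#' the last element.
#'
#' @param sequence Character vector listing every taxon exactly once.
#' @return An object of class `circular_ordering` (a character vector).
#' @examples
#' circular_ordering(c("3", "2", "1", "5", "4"))
#' @export
circular_ordering <- function(sequence) {
  sequence <- as.character(sequence)
  taxa <- check_ground_set(sequence)
  n <- length(sequence)
  i <- match(taxa[1L], sequence)
  seq_rot <- sequence[((i - 1L + 0:(n - 1L)) %% n) + 1L]
  key <- natural_key(seq_rot)
  if (order(key[c(2L, n)])[1L] != 1L) {
    seq_rot <- c(seq_rot[1L], rev(seq_rot[-1L]))
  }
  structure(seq_rot, class = "circular_ordering", taxa = taxa)
}

#' @export
print.circular_ordering <- function(x, ...) {
  cat("Circular ordering:", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

ordering_taxa <- function(ordering) attr(ordering, "taxa")

# indices of arc starting at position i with length len (1-based, modulo n)
arc_positions <- function(i, len, n) ((i - 1L + 0:(len - 1L)) %% n) + 1L

#' All interval splits of a circular ordering
#'
#' Returns every split of the taxon set whose two sides are both arcs
#' (intervals) of the ordering: the unique maximal circular split system for
#' that ordering, of size `n(n-1)/2`.
#'
#' @param ordering A `circular_ordering` (or a vector coercible to one).
#' @return A `split_system`.
#' @examples
#' interval_splits(circular_ordering(as.character(1:4)))  # 6 splits
#' @export
interval_splits <- function(ordering) {
  if (!inherits(ordering, "circular_ordering")) ordering <- circular_ordering(ordering)
  n <- length(ordering)
  taxa <- ordering_taxa(ordering)
  sides <- list()
  k <- 0L
  for (len in seq_len(floor(n / 2))) {
    for (i in seq_len(n)) {
      k <- k + 1L
      sides[[k]] <- unclass(ordering)[arc_positions(i, len, n)]
    }
  }
  split_system(sides, taxa = taxa)
}

#' The adjacent-pair split system of a circular ordering
#'
#' The system of the n splits `{x_i, x_{i+1}} | X - {x_i, x_{i+1}}`
#' separating each pair of neighbours in the ordering.  Its I-intersection
#' closure is the maximal circular split system of the ordering.  For n = 4
#' the listed splits coincide pairwise, so only 2 distinct splits remain
#' after canonical deduplication.
#'
#' @param ordering A `circular_ordering` (or a vector coercible to one).
#' @return A `split_system`.
#' @export
adjacent_pair_system <- function(ordering) {
  if (!inherits(ordering, "circular_ordering")) ordering <- circular_ordering(ordering)
  n <- length(ordering)
  if (n < 4L) stop("adjacent-pair systems need at least 4 taxa")
  sides <- lapply(seq_len(n), function(i) unclass(ordering)[arc_positions(i, 2L, n)])
  split_system(sides, taxa = ordering_taxa(ordering))
}

# is the block side of `block` (logical over taxa) an interval of `ordering`?
block_is_interval <- function(block, ordering, taxa) {
  pos <- sort(match(taxa[block], unclass(ordering)))
  contiguous <- function(p) length(p) == 0L || (p[length(p)] - p[1L] + 1L) == length(p)
  contiguous(pos) || contiguous(sort(match(taxa[!block], unclass(ordering))))
}

#' Does an ordering display a split system?
#'
#' TRUE when every split of `sigma` cuts `ordering` into two arcs.
#'
#' @param sigma A `split_system`.
#' @param ordering A `circular_ordering`.
#' @export
ordering_displays <- function(sigma, ordering) {
  if (!inherits(ordering, "circular_ordering")) ordering <- circular_ordering(ordering)
  stopifnot(identical(sigma$taxa, ordering_taxa(ordering)))
  for (i in seq_len(n_splits(sigma))) {
    if (!block_is_interval(sigma$blocks[i, ], ordering, sigma$taxa)) return(FALSE)
  }
  TRUE
}

# all canonical circular orderings of taxa (first element pinned, reflection
# removed); (n-1)!/2 of them
all_circular_orderings <- function(taxa) {
  taxa <- check_ground_set(taxa)
  n <- length(taxa)
  rest <- taxa[-1L]
  perms <- permutations_of(seq_len(n - 1L))
  out <- list()
  k <- 0L
  for (p in perms) {
    if (n > 3L && p[1L] > p[n - 1L]) next  # reflection representative
    k <- k + 1L
    out[[k]] <- structure(c(taxa[1L], rest[p]), class = "circular_ordering",
                          taxa = taxa)
    if (n == 3L) break  # single ordering up to rotation/reflection
  }
  out
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (tail_perm in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], tail_perm)
    }
  }
  out
}

#' Test circularity of a split system
#'
#' Searches for a circular ordering of the taxa for which every split of
#' `sigma` is an interval split, returning a verified witness ordering or
#' `NULL` when none exists.  For small ground sets the `(n-1)!/2` canonical
#' orderings are searched exhaustively; for larger sets the constructive
#' route (quotient each incompatibility component, grow its I-closure, read
#' the ordering off the reconstructed network) is used, and its result is
#' verified before being returned.
#'
#' @param sigma A nonempty `split_system`.
#' @param method `"auto"` (default), `"brute"` or `"construct"`.
#' @return A `circular_ordering` witness, or `NULL`.
#' @export
is_circular <- function(sigma, method = c("auto", "brute", "construct")) {
  method <- match.arg(method)
  if (n_splits(sigma) == 0L) stop("empty split system")
  n <- length(sigma$taxa)
  if (method == "auto") {
    if (n <= 7L) return(is_circular_brute(sigma))
    witness <- is_circular_construct(sigma)
    if (!is.null(witness)) return(witness)
    if (n <= 10L) return(is_circular_brute(sigma))
    return(NULL)
  }
  if (method == "brute") return(is_circular_brute(sigma))
  is_circular_construct(sigma)
}

is_circular_brute <- function(sigma) {
  for (ordering in all_circular_orderings(sigma$taxa)) {
    if (ordering_displays(sigma, ordering)) return(circular_ordering(ordering))
  }
  NULL
}

is_circular_construct <- function(sigma) {
  net <- tryCatch(build_1nested(sigma), error = function(e) NULL)
  if (is.null(net)) return(NULL)
  ordering <- leaf_ordering(net)
  if (ordering_displays(sigma, ordering)) circular_ordering(ordering) else NULL
}
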