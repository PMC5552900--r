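## File formats: plain-text split lists, NEXUS SPLITS blocks (SplitsTree4
## dialect), GraphML/GML networks, JSON reports.

#' Read and write split systems
#'
#' Plain-text format: one split per line, taxa whitespace-separated, the two
#' sides separated by `|`; lines starting with `#` are comments.  NEXUS
#' format: a TAXA block plus a SPLITS block in the SplitsTree4 dialect
#' (splits listed by the taxon indices of one side; weights are ignored on
#' read and written as 1.0; a CYCLE statement is written when a witness
#' ordering is supplied, and ignored on read).  The format is chosen by file
#' extension (`.nex`/`.nxs` for NEXUS, anything else plain text).
#'
#' @param path File path.
#' @param sigma A `split_system`.
#' @param ordering Optional `circular_ordering` written as the CYCLE
#'   statement of the NEXUS SPLITS block.
#' @return `read_splits()` returns a `split_system`; `write_splits()`
#'   returns `path` invisibly.
#' @name splits-io
#' @export
read_splits <- function(path) {
  if (grepl("\\.(nex|nxs)$", path, ignore.case = TRUE)) {
    read_nexus_splits(path)
  } else {
    read_splits_text(path)
  }
}

#' @rdname splits-io
#' @export
write_splits <- function(sigma, path, ordering = NULL) {
  if (grepl("\\.(nex|nxs)$", path, ignore.case = TRUE)) {
    write_nexus_splits(sigma, path, ordering = ordering)
  } else {
    write_splits_text(sigma, path)
  }
  invisible(path)
}

read_splits_text <- function(path) {
  lines <- readLines(path)
  sides <- list()
  taxa <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    n_pipes <- lengths(regmatches(line, gregexpr("|", line, fixed = TRUE)))
    if (n_pipes != 1L) {
      stop(sprintf("%s:%d: expected exactly one '|'", path, ln))
    }
    parts <- strsplit(line, "|", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- c(parts, "")
    a <- strsplit(trimws(parts[1L]), "[[:space:]]+")[[1]]
    b <- strsplit(trimws(parts[2L]), "[[:space:]]+")[[1]]
    if (length(a) == 0L || length(b) == 0L) {
      stop(sprintf("%s:%d: a split side is empty", path, ln))
    }
    sides[[length(sides) + 1L]] <- a
    taxa <- union(taxa, c(a, b))
  }
  if (length(sides) == 0L) stop(sprintf("%s: no splits found", path))
  split_system(sides, taxa = taxa)
}

write_splits_text <- function(sigma, path) {
  lines <- vapply(system_splits(sigma), format, character(1))
  writeLines(lines, path)
}

read_nexus_splits <- function(path) {
  lines <- readLines(path)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("^\\s*#nexus", txt, ignore.case = TRUE)) {
    stop(sprintf("%s:1: not a NEXUS file (missing #NEXUS header)", path))
  }
  # statements are ;-terminated; strip [] comments
  txt <- gsub("\\[[^]]*\\]", "", txt)
  grab_block <- function(name) {
    m <- regexpr(paste0("(?is)begin\\s+", name, "\\s*;.*?end\\s*;"), txt, perl = TRUE)
    if (m == -1L) stop(sprintf("%s: missing %s block", path, name))
    regmatches(txt, m)
  }
  taxa_block <- grab_block("taxa")
  m <- regexpr("(?is)taxlabels(.*?);", taxa_block, perl = TRUE)
  if (m == -1L) stop(sprintf("%s: TAXA block has no TAXLABELS", path))
  lab_txt <- sub("(?is)taxlabels", "", regmatches(taxa_block, m), perl = TRUE)
  labels <- strsplit(trimws(gsub(";", "", lab_txt)), "[[:space:]]+")[[1]]
  labels <- gsub("^'(.*)'$", "\\1", labels)
  splits_block <- grab_block("splits")
  m <- regexpr("(?is)matrix(.*?);", splits_block, perl = TRUE)
  if (m == -1L) stop(sprintf("%s: SPLITS block has no MATRIX", path))
  mat_txt <- sub("(?is)^matrix", "", regmatches(splits_block, m), perl = TRUE)
  mat_txt <- sub(";\\s*$", "", mat_txt)
  fmt <- regmatches(splits_block,
                    regexpr("(?is)format[^;]*;", splits_block, perl = TRUE))
  labels_left <- length(fmt) == 1L && grepl("labels\\s*=\\s*left", fmt,
                                            ignore.case = TRUE)
  rows <- strsplit(mat_txt, ",")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  saw_weight <- FALSE
  sides <- lapply(rows, function(row) {
    toks <- strsplit(row, "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    # SplitsTree rows carry `id weight taxa...` under labels=left, or
    # `weight taxa...` under labels=no; weights have a decimal point
    if (labels_left) toks <- toks[-1L]
    if (any(grepl("[.]", toks))) saw_weight <<- TRUE
    toks <- toks[!grepl("[.]", toks)]
    idx <- suppressWarnings(as.integer(toks))
    if (anyNA(idx)) stop(sprintf("%s: bad SPLITS matrix row: %s", path, row))
    if (any(idx < 1L) || any(idx > length(labels))) {
      stop(sprintf("%s: taxon index out of range in row: %s", path, row))
    }
    labels[idx]
  })
  if (saw_weight) message("NEXUS SPLITS: weights present; ignored on read")
  split_system(sides, taxa = labels)
}

write_nexus_splits <- function(sigma, path, ordering = NULL) {
  taxa <- sigma$taxa
  n <- length(taxa)
  m <- n_splits(sigma)
  quote_lab <- function(x) ifelse(grepl("[^A-Za-z0-9_.]", x), paste0("'", x, "'"), x)
  lines <- c(
    "#NEXUS",
    "",
    "BEGIN taxa;",
    sprintf("    DIMENSIONS ntax=%d;", n),
    "    TAXLABELS",
    paste0("        ", quote_lab(taxa)),
    "    ;",
    "END;",
    "",
    "BEGIN splits;",
    sprintf("    DIMENSIONS ntax=%d nsplits=%d;", n, m),
    "    FORMAT labels=left weights=yes;")
  if (!is.null(ordering)) {
    lines <- c(lines, sprintf("    CYCLE %s;",
                              paste(match(unclass(ordering), taxa), collapse = " ")))
  }
  lines <- c(lines, "    MATRIX")
  for (i in seq_len(m)) {
    idx <- which(sigma$blocks[i, ])
    # SplitsTree/Spectronet row layout: id <tab> weight <tab> indices,
    lines <- c(lines, sprintf("\t\t%d\t1.0\t%s,", i, paste(idx, collapse = " ")))
  }
  lines <- c(lines, "    ;", "END;")
  writeLines(lines, path)
}

## ---- networks -------------------------------------------------------------

#' Read and write uprooted networks (GraphML/GML)
#'
#' GraphML is the primary format: leaves carry a string attribute `label`;
#' interior vertices carry none (or an empty label).  GML is accepted too;
#' the format is chosen by extension.
#'
#' @param net An `uprooted_network`.
#' @param path File path (`.graphml` or `.gml`).
#' @return `read_network()` returns an `uprooted_network`; `write_network()`
#'   returns `path` invisibly.
#' @name network-io
#' @export
read_network <- function(path) {
  fmt <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "graphml"
  g <- igraph::read_graph(path, format = fmt)
  labels <- igraph::vertex_attr(g, "label")
  if (is.null(labels)) labels <- rep(NA_character_, igraph::vcount(g))
  labels <- as.character(labels)
  labels[!nzchar(labels) | labels == "NA"] <- NA_character_
  edges <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  unlabeled_leaf <- which(deg == 1L & is.na(labels))
  if (length(unlabeled_leaf) > 0L) {
    stop(sprintf("%s: unlabeled leaf vertex (id %s)", path,
                 paste(unlabeled_leaf, collapse = ",")))
  }
  uprooted_network(edges, labels, n_vertices = igraph::vcount(g))
}

#' @rdname network-io
#' @export
write_network <- function(net, path) {
  fmt <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "graphml"
  g <- as_igraph(net)
  lab <- net$labels
  lab[is.na(lab)] <- ""
  g <- igraph::set_vertex_attr(g, "label", value = lab)
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}

#' Multiplicity sidecar table
#'
#' Writes the split multiset of a network as a TSV with columns `split`
#' (canonical string) and `multiplicity`.
#'
#' @param sm A `split_multiset` from [splits_of()].
#' @param path Output TSV path.
#' @export
write_multiplicities <- function(sm, path) {
  df <- data.frame(split = vapply(system_splits(sm$system), format, character(1)),
                   multiplicity = sm$multiplicity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
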