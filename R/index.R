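INDEX_FORMAT_VERSION <- 1L

#' Build the hierarchically labeled suffix index
#'
#' Concatenates all database records, each terminated by a sentinel that
#' sorts before every residue and never matches a query symbol, builds the
#' generalized suffix array of that text, annotates every suffix with the
#' taxonomy node of its source record, and precomputes a sparse table over
#' the suffix-ordered label array (combining operator: tree LCA) so the LCA
#' of any contiguous label range — the lowest taxonomic unit (LTU) of a
#' pattern's match interval — is answerable in constant time.
#'
#' @param db a [sequence_database()].
#' @return Object of class `labeled_index` with fields `text`, `sa`
#'   (0-based suffix positions), `doc` (per-suffix source record, 1-based),
#'   `labels` (per-suffix taxonomy node id), the sparse range-LCA table,
#'   `alphabet`, `tree` and `format_version`.
#' @examples
#' tr <- parse_tree(data.frame(child = c("1", "1.1", "1.1.1", "1.1.1.1"),
#'                             parent = c("R", "1", "1.1", "1.1.1")))
#' db <- sequence_database("S1", "MKVLA", "1.1.1.1", tr)
#' idx <- build_index(db)
#' @export
build_index <- function(db) {
  stopifnot(inherits(db, "sequence_database"))
  if (length(db$seq_id) == 0L) stop("empty database")
  rec_len <- nchar(db$residues) + 1L            # + sentinel
  text <- paste0(paste0(db$residues, SENTINEL, collapse = ""))
  sa <- sa_build(text)
  rec_end <- cumsum(rec_len)                    # 1-based end position of each record
  doc <- findInterval(sa, rec_end) + 1L         # sa is 0-based: pos p in record i
  labels <- db$node_id[doc]
  lca_tab <- lca_sparse_build(labels, int0(db$tree$parent), db$tree$level)
  structure(list(text = text, sa = sa, doc = doc, labels = labels,
                 lca_tab = lca_tab, alphabet = db$alphabet, tree = db$tree,
                 seq_id = db$seq_id, rec_end = rec_end,
                 format_version = INDEX_FORMAT_VERSION),
            class = "labeled_index")
}

# parent vector with 0 (not NA) for the root, as the C++ side expects
int0 <- function(parent) {
  parent[is.na(parent)] <- 0L
  as.integer(parent)
}

#' @export
print.labeled_index <- function(x, ...) {
  cat("labeled_index: ", length(x$seq_id), " records, |text| = ",
      nchar(x$text), " (", x$alphabet, "), tree of ",
      length(x$tree$name), " nodes\n", sep = "")
  invisible(x)
}

#' Suffix-array interval of a pattern
#'
#' Returns the half-open interval `[lo, hi)` of suffix-array ranks of all
#' suffixes prefixed by `pattern` (0-based ranks). An absent pattern gives
#' an empty interval, never an error; wildcard symbols in the pattern match
#' nothing. The empty pattern matches every suffix.
#'
#' @param index a `labeled_index`.
#' @param pattern character scalar over the index alphabet (sanitized as a
#'   query: symbols outside the alphabet become non-matching wildcards).
#' @return Object of class `match_interval`: list with `lo`, `hi`
#'   (0-based, half-open) and `pattern_len`.
#' @export
match_interval <- function(index, pattern) {
  pattern <- sanitize_residues(as.character(pattern)[1L], index$alphabet,
                               "query")
  iv <- sa_match_interval(index$text, index$sa, pattern)
  structure(iv, class = "match_interval")
}

#' @export
print.match_interval <- function(x, ...) {
  cat("match_interval: [", x$lo, ", ", x$hi, ") width ", max(0L, x$hi - x$lo),
      ", pattern_len ", x$pattern_len, "\n", sep = "")
  invisible(x)
}

interval_width <- function(iv) max(0L, iv$hi - iv$lo)

#' Lowest taxonomic unit of a match interval
#'
#' The LCA of the taxonomy labels of every suffix in the interval, i.e. the
#' deepest node annotating all database records that contain the match.
#' Answered from the precomputed sparse table in constant time: two
#' overlapping power-of-two blocks and a single pairwise tree LCA,
#' independent of the interval width and of the pattern length.
#'
#' @param index a `labeled_index`.
#' @param interval a nonempty `match_interval` (or a list with `lo`, `hi`).
#' @return Integer taxonomy node id.
#' @export
ltu <- function(index, interval) {
  if (interval$lo >= interval$hi) stop("empty interval has no LTU")
  lca_sparse_query(index$lca_tab, int0(index$tree$parent),
                   index$tree$level, interval$lo, interval$hi)
}

#' Longest database match of a query prefix
#'
#' The maximum `l` such that `query[start .. start + l)` (0-based, half-open)
#' occurs in the indexed text, together with its suffix-array interval.
#' `l = 0` gives an empty interval.
#'
#' @param index a `labeled_index`.
#' @param query character scalar (sanitized as a query).
#' @param start 0-based offset into `query`.
#' @return list with `length` and `interval` (a `match_interval`).
#' @export
longest_prefix_match <- function(index, query, start = 0L) {
  query <- sanitize_residues(as.character(query)[1L], index$alphabet, "query")
  r <- sa_longest_prefix(index$text, index$sa, query, as.integer(start))
  list(length = r$length,
       interval = structure(list(lo = r$lo, hi = r$hi,
                                 pattern_len = r$length),
                            class = "match_interval"))
}

#' Save / load a labeled index
#'
#' The on-disk format is a directory holding a JSON manifest
#' (`format_version`, alphabet, counts) plus plain-text arrays and the tree
#' node table. The derived range-LCA table is rebuilt on load. Loading
#' checks `format_version` and the presence of every component file;
#' `load_index(save_index(x, d))` answers all queries identically to `x`.
#'
#' @param index a `labeled_index`.
#' @param dir_path directory to write (created if needed) / read.
#' @return `save_index` returns `dir_path` invisibly; `load_index` a
#'   `labeled_index`.
#' @export
save_index <- function(index, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = index$format_version,
                   alphabet = index$alphabet,
                   n_records = length(index$seq_id),
                   text_length = nchar(index$text),
                   n_nodes = length(index$tree$name))
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(index$text, file.path(dir_path, "text.txt"))
  writeLines(as.character(index$sa), file.path(dir_path, "sa.txt"))
  writeLines(index$seq_id, file.path(dir_path, "seq_id.txt"))
  writeLines(as.character(index$rec_end), file.path(dir_path, "rec_end.txt"))
  # per-record labels suffice; per-suffix labels are derived
  rec_label <- index$labels[match(seq_along(index$seq_id), index$doc)]
  writeLines(as.character(rec_label), file.path(dir_path, "rec_label.txt"))
  nodes <- data.frame(id = seq_along(index$tree$name), name = index$tree$name,
                      parent = int0(index$tree$parent),
                      level = index$tree$level)
  utils::write.table(nodes, file.path(dir_path, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}

#' @rdname save_index
#' @export
load_index <- function(dir_path) {
  need <- c("manifest.json", "text.txt", "sa.txt", "seq_id.txt",
            "rec_end.txt", "rec_label.txt", "nodes.tsv")
  missing <- need[!file.exists(file.path(dir_path, need))]
  if (length(missing) > 0L)
    stop("index directory is missing component(s): ",
         paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir_path, "manifest.json"))
  if (!identical(as.integer(manifest$format_version), INDEX_FORMAT_VERSION))
    stop("index format_version ", manifest$format_version,
         " does not match supported version ", INDEX_FORMAT_VERSION)
  text <- readLines(file.path(dir_path, "text.txt"), n = 1L)
  sa <- as.integer(readLines(file.path(dir_path, "sa.txt")))
  seq_id <- readLines(file.path(dir_path, "seq_id.txt"))
  rec_end <- as.integer(readLines(file.path(dir_path, "rec_end.txt")))
  rec_label <- as.integer(readLines(file.path(dir_path, "rec_label.txt")))
  nodes <- utils::read.delim(file.path(dir_path, "nodes.tsv"),
                             colClasses = c("integer", "character",
                                            "integer", "integer"))
  parent <- nodes$parent
  parent[parent == 0L] <- NA_integer_
  tree <- structure(list(name = nodes$name, parent = parent,
                         level = nodes$level, root = which(is.na(parent))),
                    class = "taxonomy_tree")
  if (nchar(text) != length(sa) ||
      !identical(as.integer(manifest$text_length), nchar(text)))
    stop("corrupted index: component sizes disagree")
  doc <- findInterval(sa, rec_end) + 1L
  labels <- rec_label[doc]
  lca_tab <- lca_sparse_build(labels, int0(tree$parent), tree$level)
  structure(list(text = text, sa = sa, doc = doc, labels = labels,
                 lca_tab = lca_tab,
                 alphabet = as.character(manifest$alphabet), tree = tree,
                 seq_id = seq_id, rec_end = rec_end,
                 format_version = as.integer(manifest$format_version)),
            class = "labeled_index")
}
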