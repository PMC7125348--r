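#' Enumerate maximal exact matches of a query against the index
#'
#' A MEM is a query substring that occurs in the database and cannot be
#' extended left or right within the query and still occur. Maximality is
#' query-side against the whole database, not per record. Implementation:
#' one longest-prefix match per query start; the match at start `i` (length
#' `l_i`) is reported iff `l_i >= min_len` and `l_i >= l_{i-1}` (otherwise
#' it is the trailing remainder of the previous start's match and not
#' left-maximal), with `l_{-1} = 0`. Each MEM carries the LTU of its match
#' interval.
#'
#' @param index a `labeled_index`.
#' @param query character scalar (sanitized as a query; wildcards never
#'   match, so ambiguous positions terminate MEMs).
#' @param min_len minimum reported MEM length in residues (default 5 for
#'   amino-acid indexes, 15 for nucleotide).
#' @param frame optional frame tag attached to every hit (used by the
#'   six-frame classifier).
#' @return data.frame of class `mem_hits`, one row per MEM, sorted by
#'   `query_start` (0-based): columns `query_start`, `length`, `lo`, `hi`,
#'   `ltu_node`, `frame`.
#' @examples
#' tr <- parse_tree(data.frame(
#'   child  = c("1", "1.1", "1.1.1", "1.1.1.1", "1.1.1.2"),
#'   parent = c("R", "1", "1.1", "1.1.1", "1.1.1")))
#' db <- sequence_database(c("S1", "S2"), c("MKVLA", "KVLAG"),
#'                         c("1.1.1.1", "1.1.1.2"), tr)
#' idx <- build_index(db)
#' find_mems(idx, "MKVLAG", min_len = 3)
#' @export
find_mems <- function(index, query, min_len = default_min_mem(index$alphabet),
                      frame = NA_integer_) {
  query <- sanitize_residues(as.character(query)[1L], index$alphabet, "query")
  m <- sa_find_mems(index$text, index$sa, query, as.integer(min_len))
  nodes <- if (nrow(m) > 0L)
    lca_sparse_query_many(index$lca_tab, int0(index$tree$parent),
                          index$tree$level, m[, "lo"], m[, "hi"])
  else integer(0)
  structure(data.frame(query_start = m[, "start"], length = m[, "len"],
                       lo = m[, "lo"], hi = m[, "hi"], ltu_node = nodes,
                       frame = rep(as.integer(frame), nrow(m)),
                       row.names = NULL),
            class = c("mem_hits", "data.frame"))
}

#' @rdname find_mems
#' @param alphabet `"AA"` or `"NT"`.
#' @export
default_min_mem <- function(alphabet = c("AA", "NT")) {
  switch(match.arg(alphabet), AA = 5L, NT = 15L)
}

#' Select the classification-determining hit
#'
#' Returns a hit of maximal length; when several MEMs tie for the maximal
#' length, one is chosen uniformly at random (the tie-broken representative
#' that stands in for an explicit LCA computation across all equally long
#' matches). With `strict = TRUE` the LCA across the tied hits' LTU nodes
#' is returned instead (sensitivity-analysis mode, not the default).
#'
#' @param mems a `mem_hits` data.frame.
#' @param seed integer seed for the tie-break draw; the caller derives one
#'   stream per read so results do not depend on processing order.
#' @param tree taxonomy (required for `strict = TRUE`).
#' @param strict logical; collapse ties by LCA instead of random choice.
#' @return A one-row `mem_hits` data.frame (with `n_tied` column added), or
#'   `NULL` when `mems` is empty.
#' @export
best_hit <- function(mems, seed = 1L, tree = NULL, strict = FALSE) {
  if (is.null(mems) || nrow(mems) == 0L) return(NULL)
  tied <- which(mems$length == max(mems$length))
  n_tied <- length(tied)
  if (strict && n_tied > 1L) {
    if (is.null(tree)) stop("strict mode needs the taxonomy tree")
    hit <- mems[tied[1L], , drop = FALSE]
    hit$ltu_node <- lca_fold(tree, mems$ltu_node[tied])
  } else if (n_tied > 1L) {
    pick <- with_local_seed(seed, sample.int(n_tied, 1L))
    hit <- mems[tied[pick], , drop = FALSE]
  } else {
    hit <- mems[tied, , drop = FALSE]
  }
  hit$n_tied <- n_tied
  rownames(hit) <- NULL
  hit
}

#' Number of MEMs tying for the maximal length
#'
#' The per-read multi-matching diagnostic: how many alternative equally
#' long MEMs the read has (0 for no MEM at all).
#'
#' @param mems a `mem_hits` data.frame (or `NULL`).
#' @return Integer count.
#' @export
count_tied_mems <- function(mems) {
  if (is.null(mems) || nrow(mems) == 0L) return(0L)
  sum(mems$length == max(mems$length))
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# per-read tie-break stream: deterministic, independent of scheduling,
# kept inside 32-bit signed range
derive_seed <- function(root_seed, ordinal) {
  as.integer((as.double(root_seed) * 48271 + as.double(ordinal) * 7919) %%
               2147483647)
}
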