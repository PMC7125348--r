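# Shared fixtures: the small worked-example database and its taxonomy,
# plus brute-force oracles that every index query is checked against.
# Oracles operate on raw character vectors and never touch the suffix
# array, the sparse table or the package's LCA code.

example_edges <- function() {
  data.frame(
    child  = c("1", "1.1", "1.1.1", "1.1.1.1", "1.1.1.2",
               "2", "2.1", "2.1.1", "2.1.1.1"),
    parent = c("R", "1", "1.1", "1.1.1", "1.1.1",
               "R", "2", "2.1", "2.1.1"),
    stringsAsFactors = FALSE)
}

example_tree <- function() parse_tree(example_edges())

example_db <- function(tree = example_tree()) {
  sequence_database(c("S1", "S2", "S3"), c("MKVLA", "KVLAG", "GGWWP"),
                    c("1.1.1.1", "1.1.1.2", "2.1.1.1"), tree)
}

example_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) idx <<- build_index(example_db())
    idx
  }
})

nm <- function(tree, id) tax_node_name(tree, id)
id_of <- function(tree, name) tax_node_id(tree, name)

# ---- taxonomy oracles -------------------------------------------------

# root-path of a node as a vector of ids, root first
oracle_root_path <- function(tree, v) {
  path <- v
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    path <- c(v, path)
  }
  path
}

# LCA by path intersection: deepest element common to both root-paths
oracle_lca <- function(tree, a, b) {
  common <- intersect(oracle_root_path(tree, a), oracle_root_path(tree, b))
  common[which.max(tree$level[common])]
}

oracle_lca_fold <- function(tree, ids)
  Reduce(function(a, b) oracle_lca(tree, a, b), ids)

# ---- text-matching oracles (dynamic programming, no suffix array) -----

# L[p, k] = length of the longest common prefix of text[p..] and
# query[k..]; computed right-to-left so column k is max-match length of
# every text position against query start k (1-based).
oracle_lcp_matrix <- function(text, query) {
  tch <- strsplit(text, "")[[1]]
  qch <- strsplit(query, "")[[1]]
  n <- length(tch); q <- length(qch)
  L <- matrix(0L, n, q + 1L)
  for (k in q:1) {
    nxt <- c(L[-1L, k + 1L], 0L)
    L[, k] <- ifelse(tch == qch[k], nxt + 1L, 0L)
  }
  L[, seq_len(q), drop = FALSE]
}

# longest match length for every 0-based query start
oracle_lpm_all <- function(text, query) {
  L <- oracle_lcp_matrix(text, query)
  apply(L, 2L, max)
}

# number of occurrences of pattern in text (overlapping included)
oracle_occurrences <- function(text, pattern) {
  if (nchar(pattern) == 0L) return(nchar(text))
  L <- oracle_lcp_matrix(text, pattern)
  sum(L[, 1L] >= nchar(pattern))
}

# all MEMs (0-based start, length) straight from the definition: the
# substring occurs, cannot be right-extended (longest-prefix length), and
# cannot be left-extended (previous start does not reach over it)
oracle_mems <- function(text, query, min_len) {
  l <- oracle_lpm_all(text, query)
  q <- length(l)
  keep <- which(l >= min_len &
                  l >= c(0L, l[-q]))  # left-maximal: l[i-1] < l[i] + 1
  data.frame(query_start = keep - 1L, length = l[keep])
}

# LTU oracle: records containing the pattern, LCA-folded by path intersection
oracle_ltu <- function(db, pattern) {
  has <- vapply(db$residues, function(r)
    oracle_occurrences(r, pattern) > 0L, logical(1), USE.NAMES = FALSE)
  if (!any(has)) return(NA_integer_)
  oracle_lca_fold(db$tree, db$node_id[has])
}

# naive generalized suffix array: byte-order sort of all suffixes
oracle_suffix_array <- function(text) {
  n <- nchar(text)
  order(substring(text, 1:n, n), method = "radix") - 1L
}

# random query built from a database substring with point mutations, so
# queries share realistic MEM structure with the records
random_query <- function(db, len = 30L, mut = 0.15) {
  rec <- sample(db$residues, 1L)
  if (nchar(rec) < len) len <- nchar(rec)
  at <- sample.int(nchar(rec) - len + 1L, 1L)
  ch <- strsplit(substr(rec, at, at + len - 1L), "")[[1]]
  syms <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hit <- which(runif(len) < mut)
  ch[hit] <- sample(syms, length(hit), replace = TRUE)
  paste0(ch, collapse = "")
}

# small random fixture for oracle tests
random_fixture <- function(seed, max_records = 20L, max_len = 200L) {
  n_rec <- sample.int(max_records - 1L, 1L) + 1L
  lo <- sample(10:max_len, 1L)
  make_fixture(seed = seed, n_records = n_rec,
               record_len_range = c(min(lo, 10L), lo),
               branching = c(2L, 2L, 2L, 2L))
}
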