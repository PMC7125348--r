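#' Parse an annotation tree from a child-parent edge table
#'
#' Builds a rooted functional taxonomy (e.g. a four-level enzyme-code
#' hierarchy under an artificial root) from an edge list. Node names are
#' opaque strings: only the edge table defines the topology, the dotted-code
#' convention is never parsed for structure. Levels are computed from the
#' root (root = 0); by convention leaves of a full enzyme-code tree sit at
#' level 4.
#'
#' @param edges data.frame (or matrix) with two character columns,
#'   child name and parent name, one row per edge.
#' @param max_height maximum allowed height below the root (default 4,
#'   the enzyme-code convention). Use `Inf` to disable the check.
#' @return An object of class `taxonomy_tree`: a list with `name`
#'   (character, indexed by node id), `parent` (integer, `NA` for the root),
#'   `level` (integer, root = 0), and `root` (integer node id).
#' @examples
#' edges <- data.frame(child = c("1", "1.1"), parent = c("R", "1"))
#' tr <- parse_tree(edges)
#' tax_level(tr, tax_node_id(tr, "1.1"))
#' @export
parse_tree <- function(edges, max_height = 4) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) stop("edge list is empty")
  child <- as.character(edges[[1L]])
  parent <- as.character(edges[[2L]])
  if (anyNA(child) || anyNA(parent) || any(child == "") || any(parent == ""))
    stop("edge table contains missing names")
  if (anyDuplicated(child)) {
    dup <- child[duplicated(child)][1L]
    stop("duplicate child '", dup, "' (conflicting parents or repeated edge)")
  }
  if (any(child == parent)) stop("cycle detected: self-loop at '",
                                 child[child == parent][1L], "'")
  roots <- setdiff(parent, child)
  if (length(roots) == 0L) stop("cycle detected: no root")
  if (length(roots) > 1L)
    stop("multiple roots: ", paste(sort(roots), collapse = ", "))

  name <- c(roots, child)                      # root gets id 1
  n <- length(name)
  pid <- c(NA_integer_, match(parent, name))
  # levels by climbing; > n steps means a cycle
  level <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; v <- i
    while (!is.na(pid[v])) {
      v <- pid[v]; d <- d + 1L
      if (d > n) stop("cycle detected")
    }
    level[i] <- d
  }
  if (max(level) > max_height)
    stop("tree height ", max(level), " exceeds max_height ", max_height)
  structure(list(name = name, parent = pid, level = level, root = 1L),
            class = "taxonomy_tree")
}

#' Read / write the two-column tree TSV
#'
#' Format: `child_name TAB parent_name`, UTF-8, no header (a header row is
#' tolerated if its first field is `"child"`).
#'
#' @param path file path.
#' @param ... passed on to [parse_tree()].
#' @return `read_tree_tsv` returns a `taxonomy_tree`; `write_tree_tsv`
#'   returns `path` invisibly.
#' @export
read_tree_tsv <- function(path, ...) {
  ed <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("child", "parent"), quote = "",
                          fileEncoding = "UTF-8")
  if (nrow(ed) > 0L && identical(tolower(ed$child[1L]), "child"))
    ed <- ed[-1L, , drop = FALSE]
  parse_tree(ed, ...)
}

#' @param tree a `taxonomy_tree`.
#' @rdname read_tree_tsv
#' @export
write_tree_tsv <- function(tree, path) {
  nonroot <- which(!is.na(tree$parent))
  utils::write.table(
    data.frame(child = tree$name[nonroot],
               parent = tree$name[tree$parent[nonroot]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree: ", length(x$name), " nodes, height ", max(x$level),
      ", root '", x$name[x$root], "'\n", sep = "")
  invisible(x)
}

check_node <- function(tree, a) {
  if (anyNA(a) || any(a < 1L) || any(a > length(tree$name)))
    stop("unknown node id")
  as.integer(a)
}

#' Node handles and attributes
#'
#' @param tree a `taxonomy_tree`.
#' @param name,id node name(s) / integer id(s).
#' @return `tax_node_id` the integer id(s) (error on unknown names);
#'   `tax_node_name` the name(s); `tax_level` the level(s); `tax_leaves`
#'   the ids of all leaf nodes; `tree_height` the maximum level.
#' @export
tax_node_id <- function(tree, name) {
  id <- match(name, tree$name)
  if (anyNA(id)) stop("unknown node name: ", name[is.na(id)][1L])
  id
}

#' @rdname tax_node_id
#' @export
tax_node_name <- function(tree, id) tree$name[check_node(tree, id)]

#' @rdname tax_node_id
#' @export
tax_level <- function(tree, id) tree$level[check_node(tree, id)]

#' @rdname tax_node_id
#' @export
tax_leaves <- function(tree) {
  setdiff(seq_along(tree$name), tree$parent[!is.na(tree$parent)])
}

#' @rdname tax_node_id
#' @export
tree_height <- function(tree) max(tree$level)

#' Lowest common ancestor of tree nodes
#'
#' Parent-pointer climbing with depth equalization, O(height) per pair
#' (height is at most the configured maximum, 4 in the enzyme-code
#' application). `lca` is idempotent, commutative and associative, so
#' `lca_fold` reduces any node set.
#'
#' @param tree a `taxonomy_tree`.
#' @param a,b integer node ids.
#' @param ids integer vector of node ids (nonempty).
#' @return Integer node id of the LCA.
#' @export
lca <- function(tree, a, b) {
  a <- check_node(tree, a); b <- check_node(tree, b)
  lv <- tree$level; par <- tree$parent
  while (lv[a] > lv[b]) a <- par[a]
  while (lv[b] > lv[a]) b <- par[b]
  while (a != b) { a <- par[a]; b <- par[b] }
  a
}

#' @rdname lca
#' @export
lca_fold <- function(tree, ids) {
  ids <- check_node(tree, ids)
  if (length(ids) == 0L) stop("empty node set")
  Reduce(function(a, b) lca(tree, a, b), ids)
}

#' Ancestor queries
#'
#' `is_ancestor(tree, a, b)` is `TRUE` iff `a` lies on the root-path of `b`
#' (`a == b` counts as `TRUE`). `level_ancestor` returns the ancestor of `a`
#' at exactly the requested level, or `NA` if `a` sits above that level.
#'
#' @param tree a `taxonomy_tree`.
#' @param a,b integer node ids.
#' @param level requested level, `0 <= level <= tree_height(tree)`.
#' @export
is_ancestor <- function(tree, a, b) {
  a <- check_node(tree, a); b <- check_node(tree, b)
  while (tree$level[b] > tree$level[a]) b <- tree$parent[b]
  a == b
}

#' @rdname is_ancestor
#' @export
level_ancestor <- function(tree, a, level) {
  a <- check_node(tree, a)
  stopifnot(level >= 0L, level <= tree_height(tree))
  if (tree$level[a] < level) return(NA_integer_)
  while (tree$level[a] > level) a <- tree$parent[a]
  a
}
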