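#' Generate a synthetic annotated database with its taxonomy
#'
#' Builds a complete rooted tree with the given branching factors (default
#' four levels below the root, the enzyme-code shape), names nodes by
#' dotted codes (`"1"`, `"1.1"`, ...) under root `"R"`, and draws records of
#' uniform-random residues, each labeled with a uniformly chosen leaf
#' (optionally a small fraction relabeled to uniformly chosen internal
#' non-root nodes, mirroring databases that place some sequences above the
#' leaf level). Reproducible from `seed`.
#'
#' @param seed integer seed.
#' @param n_records number of reference records.
#' @param record_len_range length range (min, max) in residues; records
#'   drawn uniformly within it.
#' @param branching integer vector of per-level branching factors (all
#'   `>= 1`).
#' @param alphabet `"AA"` or `"NT"`.
#' @param internal_frac fraction of records labeled at internal non-root
#'   nodes instead of leaves.
#' @return list with elements `tree` (a `taxonomy_tree`) and `db`
#'   (a `sequence_database`).
#' @examples
#' fx <- make_fixture(seed = 1, n_records = 10, record_len_range = c(100, 100))
#' fx$db
#' @export
make_fixture <- function(seed = 1L, n_records = 10L,
                         record_len_range = c(100L, 100L),
                         branching = c(2L, 2L, 2L, 2L),
                         alphabet = c("AA", "NT"), internal_frac = 0) {
  alphabet <- match.arg(alphabet)
  if (any(branching < 1L)) stop("infeasible tree shape: zero branching")
  with_local_seed(seed, {
    edges <- branching_edges(branching)
    tree <- parse_tree(edges, max_height = length(branching))
    leaves <- tax_leaves(tree)
    lab <- leaves[sample.int(length(leaves), n_records, replace = TRUE)]
    if (internal_frac > 0) {
      internal <- setdiff(which(tree$level > 0L), leaves)
      flip <- which(stats::runif(n_records) < internal_frac)
      if (length(flip) > 0L && length(internal) > 0L)
        lab[flip] <- internal[sample.int(length(internal), length(flip),
                                         replace = TRUE)]
    }
    len <- record_len_range[1L] - 1L +
      sample.int(record_len_range[2L] - record_len_range[1L] + 1L,
                 n_records, replace = TRUE)
    syms <- canonical_alphabet(alphabet)
    residues <- vapply(len, function(l)
      paste0(sample(syms, l, replace = TRUE), collapse = ""), character(1))
    db <- sequence_database(sprintf("S%04d", seq_len(n_records)), residues,
                            tree = tree, alphabet = alphabet, node_id = lab)
    list(tree = tree, db = db)
  })
}

# complete-tree edge table for per-level branching factors, dotted names
branching_edges <- function(branching) {
  parents <- "R"
  child <- character(0); parent <- character(0)
  for (b in branching) {
    nxt <- character(0)
    for (p in parents) {
      stem <- if (p == "R") "" else paste0(p, ".")
      kids <- paste0(stem, seq_len(b))
      child <- c(child, kids); parent <- c(parent, rep(p, b))
      nxt <- c(nxt, kids)
    }
    parents <- nxt
  }
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

#' Simulate reads with substitution errors and ground truth
#'
#' Draws each read from a source record chosen with probability
#' proportional to record length, at a uniform offset, then substitutes
#' each position independently with probability `error_rate` by a uniformly
#' chosen *different* canonical symbol (substitution-only error model: no
#' indels, so truth offsets stay exact). Reproducible from `seed`.
#'
#' @param db a `sequence_database`.
#' @param n_reads number of reads.
#' @param read_len read length in residues; must not exceed the shortest
#'   record.
#' @param error_rate per-position substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame of class `simulated_reads`: `read_id`, `residues`,
#'   `truth_node` (taxonomy node id of the source record), `source_seq`,
#'   `source_offset` (0-based).
#' @export
simulate_reads <- function(db, n_reads, read_len = 60L, error_rate = 0.05,
                           seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1, n_reads >= 1L)
  rec_len <- nchar(db$residues)
  if (read_len > max(rec_len)) stop("read_len exceeds every record length")
  if (read_len > min(rec_len))
    stop("read_len exceeds the shortest record (fragment sampling)")
  syms <- canonical_alphabet(db$alphabet)
  with_local_seed(seed, {
    src <- sample.int(length(rec_len), n_reads, replace = TRUE,
                      prob = rec_len)
    off <- vapply(src, function(i)
      sample.int(rec_len[i] - read_len + 1L, 1L), integer(1)) - 1L
    frag <- substring(db$residues[src], off + 1L, off + read_len)
    residues <- frag
    if (error_rate > 0) {
      residues <- vapply(seq_len(n_reads), function(i) {
        ch <- strsplit(frag[i], "")[[1]]
        hit <- which(stats::runif(read_len) < error_rate)
        for (j in hit) {
          alt <- setdiff(syms, ch[j])
          ch[j] <- alt[sample.int(length(alt), 1L)]
        }
        paste0(ch, collapse = "")
      }, character(1))
    }
    structure(data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
                         residues = residues, truth_node = db$node_id[src],
                         source_seq = db$seq_id[src], source_offset = off,
                         stringsAsFactors = FALSE),
              class = c("simulated_reads", "data.frame"))
  })
}

#' Four-way classification category of an assignment
#'
#' `"correct"` when the assigned node equals the truth; `"root"` when it is
#' the root; `"ancestor"` when it is a non-root proper ancestor of the
#' truth; `"unassigned"` when there is no assignment (only reachable when
#' unassigned reads are not merged into the root); `"incorrect"` otherwise
#' (siblings, cousins, or descendants of the truth).
#'
#' @param tree a `taxonomy_tree`.
#' @param assigned node id or `NA` (unassigned).
#' @param truth node id of the source record.
#' @return character scalar category.
#' @export
categorize <- function(tree, assigned, truth) {
  truth <- check_node(tree, truth)
  if (is.na(assigned)) return("unassigned")
  assigned <- check_node(tree, assigned)
  if (assigned == truth) return("correct")
  if (assigned == tree$root) return("root")
  if (is_ancestor(tree, assigned, truth)) return("ancestor")
  "incorrect"
}

#' Evaluate classifications against simulation ground truth
#'
#' Matches assignments to truths by read id and summarizes: the five
#' category fractions (summing to 1), mean MEM length over assigned reads,
#' mean tied-MEM count, and the per-level histogram of assignments.
#'
#' @param assignments a `read_assignments` data.frame.
#' @param truth a `simulated_reads` data.frame (or any with `read_id`,
#'   `truth_node`).
#' @param tree a `taxonomy_tree`.
#' @param merge_unassigned_into_root count unassigned reads as root
#'   assignments (the default accounting).
#' @return list of class `eval_summary`: `fractions` (named: correct,
#'   ancestor, root, incorrect, unassigned), `n_reads`, `mean_mem_length`,
#'   `mean_tied_mems`, `level_histogram` (fraction of assigned reads per
#'   level).
#' @export
evaluate <- function(assignments, truth, tree,
                     merge_unassigned_into_root = TRUE) {
  m <- match(assignments$read_id, truth$read_id)
  if (anyNA(m) || length(unique(m)) != nrow(assignments) ||
      nrow(assignments) != nrow(truth))
    stop("assignment and truth read ids do not match")
  node <- assignments$node_id
  if (merge_unassigned_into_root) node[is.na(node)] <- tree$root
  cat_i <- vapply(seq_len(nrow(assignments)), function(i)
    categorize(tree, node[i], truth$truth_node[m[i]]), character(1))
  lev <- c("correct", "ancestor", "root", "incorrect", "unassigned")
  fr <- table(factor(cat_i, levels = lev)) / nrow(assignments)
  assigned <- !is.na(node)
  lv <- table(factor(tree$level[node[assigned]],
                     levels = 0:tree_height(tree)))
  structure(list(fractions = stats::setNames(as.numeric(fr), lev),
                 n_reads = nrow(assignments),
                 mean_mem_length = mean(assignments$mem_length[
                   assignments$status == "assigned"]),
                 mean_tied_mems = mean(assignments$n_tied[
                   assignments$status == "assigned"]),
                 level_histogram = stats::setNames(
                   as.numeric(lv) / max(1L, sum(assigned)), names(lv))),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("eval_summary over ", x$n_reads, " reads\n", sep = "")
  cat(sprintf("  %-10s %6.1f%%\n", names(x$fractions),
              100 * x$fractions), sep = "")
  cat(sprintf("  mean MEM length %.1f, mean tied MEMs %.1f\n",
              x$mean_mem_length, x$mean_tied_mems))
  invisible(x)
}

#' Per-level composition of database labels
#'
#' The fraction of database records labeled at each tree level; the
#' comparison background for the assignment level histogram (leaf-heavy
#' databases whose reads land above the leaf level indicate shared
#' sequence content within subtrees).
#'
#' @param db a `sequence_database`.
#' @return named numeric vector, one fraction per level 0..height.
#' @export
db_level_histogram <- function(db) {
  lv <- table(factor(db$tree$level[db$node_id],
                     levels = 0:tree_height(db$tree)))
  stats::setNames(as.numeric(lv) / length(db$node_id), names(lv))
}

#' Write / read simulated reads as FASTA + truth TSV
#'
#' @param reads a `simulated_reads` data.frame.
#' @param fasta_path,truth_path output paths.
#' @param path truth TSV path to read back.
#' @export
write_simulated_reads <- function(reads, fasta_path, truth_path) {
  writeLines(paste0(">", reads$read_id, "\n", reads$residues), fasta_path)
  utils::write.table(reads[, c("read_id", "truth_node", "source_seq",
                               "source_offset")],
                     truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(reads)
}

#' @rdname write_simulated_reads
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, colClasses = c("character", "integer",
                                         "character", "integer"))
}
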