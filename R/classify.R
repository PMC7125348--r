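#' Classification parameters
#'
#' @param min_mem minimum MEM length in residues (amino acids when
#'   `translate = TRUE` or the index is amino acid; nucleotides otherwise).
#' @param translate six-frame-translate nucleotide reads before searching
#'   an amino-acid index.
#' @param seed root seed for tie-break randomness; per-read streams are
#'   derived from it by read ordinal.
#' @param merge_unassigned_into_root count reads with no qualifying MEM as
#'   root assignments in profiles and evaluation summaries (the classifier
#'   output always keeps the two distinguishable).
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(min_mem = 5L, translate = FALSE, seed = 1L,
                            merge_unassigned_into_root = TRUE) {
  stopifnot(min_mem >= 1L)
  structure(list(min_mem = as.integer(min_mem), translate = isTRUE(translate),
                 seed = as.integer(seed),
                 merge_unassigned_into_root = isTRUE(merge_unassigned_into_root)),
            class = "classify_params")
}

#' Classify a single read by its longest maximal exact match
#'
#' Finds all MEMs of the read against the labeled index (pooling
#' fragment-local MEMs across all six translation frames when
#' `params$translate` is on; lengths then in amino acids), selects the
#' longest with uniform random tie-breaking, and assigns the read to the
#' lowest taxonomic unit of that hit. A read with no MEM of length
#' `>= min_mem` is unassigned.
#'
#' @param index a `labeled_index`.
#' @param read character scalar of residues.
#' @param params a [classify_params()].
#' @param read_id id string recorded in the output.
#' @param ordinal 1-based position of the read in its run; keys the
#'   per-read tie-break stream.
#' @return One-row data.frame: `read_id`, `status`
#'   (`"assigned"`/`"unassigned"`), `node_id`, `node_name`, `node_level`,
#'   `mem_length`, `n_tied`, `frame`.
#' @export
classify_read <- function(index, read, params = classify_params(),
                          read_id = "read", ordinal = 1L) {
  if (params$translate && index$alphabet != "AA")
    stop("translate = TRUE requires an amino-acid index")
  if (params$translate) {
    frags <- six_frame_translate(read)
    mems <- NULL
    if (nrow(frags) > 0L) {
      per <- lapply(seq_len(nrow(frags)), function(i)
        find_mems(index, frags$aa[i], params$min_mem, frame = frags$frame[i]))
      mems <- do.call(rbind, per)
    }
  } else {
    mems <- find_mems(index, read, params$min_mem)
  }
  hit <- best_hit(mems, seed = derive_seed(params$seed, ordinal))
  if (is.null(hit)) {
    data.frame(read_id = read_id, status = "unassigned",
               node_id = NA_integer_, node_name = NA_character_,
               node_level = NA_integer_, mem_length = 0L, n_tied = 0L,
               frame = NA_integer_, stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = read_id, status = "assigned",
               node_id = hit$ltu_node,
               node_name = tax_node_name(index$tree, hit$ltu_node),
               node_level = tax_level(index$tree, hit$ltu_node),
               mem_length = hit$length, n_tied = hit$n_tied,
               frame = hit$frame, stringsAsFactors = FALSE)
  }
}

#' Classify a set of reads
#'
#' @param index a `labeled_index`.
#' @param reads named character vector of reads (names are read ids).
#' @param params a [classify_params()].
#' @return data.frame of class `read_assignments`, one row per read, in
#'   input order, with the [classify_read()] columns.
#' @export
classify_reads <- function(index, reads, params = classify_params()) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  if (length(reads) == 0L) {
    out <- data.frame(read_id = character(), status = character(),
                      node_id = integer(), node_name = character(),
                      node_level = integer(), mem_length = integer(),
                      n_tied = integer(), frame = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("read_assignments", "data.frame")
    return(out)
  }
  rows <- vector("list", length(reads))
  for (i in seq_along(reads))
    rows[[i]] <- classify_read(index, reads[[i]], params, ids[i], i)
  out <- do.call(rbind, rows)
  class(out) <- c("read_assignments", "data.frame")
  out
}

#' Classify a FASTA/FASTQ file of reads
#'
#' Reads the file (FASTQ qualities are ignored; mates of a pair are
#' independent reads), classifies every record, writes one TSV row per read
#' (columns `read_id`, `status`, `node_name`, `node_level`, `mem_length`,
#' `n_tied`, `frame`) and returns a run summary. Records with empty
#' sequences are skipped with a warning and counted. Deterministic for a
#' fixed `params$seed`.
#'
#' @param index a `labeled_index`.
#' @param reads_path FASTA or FASTQ file (auto-detected).
#' @param params a [classify_params()].
#' @param out_path output TSV path, or `NULL` to skip writing.
#' @return list with `assignments` (the `read_assignments` data.frame),
#'   `n_reads`, `n_assigned`, `n_unassigned`, `n_skipped`, and
#'   `level_counts` (assigned reads per tree level).
#' @export
classify_file <- function(index, reads_path, params = classify_params(),
                          out_path = NULL) {
  reads <- read_reads(reads_path)
  bad <- !nzchar(reads)
  if (any(bad)) {
    warning(sum(bad), " empty record(s) skipped")
    reads <- reads[!bad]
  }
  asg <- classify_reads(index, reads, params)
  if (!is.null(out_path)) {
    cols <- c("read_id", "status", "node_name", "node_level",
              "mem_length", "n_tied", "frame")
    utils::write.table(asg[, cols], out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  lv <- table(factor(asg$node_level[asg$status == "assigned"],
                     levels = 0:tree_height(index$tree)))
  list(assignments = asg,
       n_reads = nrow(asg),
       n_assigned = sum(asg$status == "assigned"),
       n_unassigned = sum(asg$status == "unassigned"),
       n_skipped = sum(bad),
       level_counts = stats::setNames(as.integer(lv), names(lv)))
}

#' Aggregate assignments into a fixed-level profile
#'
#' Each read assigned at level >= the requested level contributes one count
#' to its ancestor at exactly that level; reads assigned strictly above the
#' level are tallied as `n_above_level`; unassigned reads as
#' `n_unassigned` (or, when `merge_unassigned_into_root`, as root
#' assignments, i.e. above any level >= 1). Counts + above + unassigned
#' always sum to the number of reads processed.
#'
#' @param assignments a `read_assignments` data.frame.
#' @param tree a `taxonomy_tree`.
#' @param level target level (0 = root .. `tree_height(tree)`).
#' @param merge_unassigned_into_root see [classify_params()].
#' @return list of class `level_profile`: `level`, `counts` (named integer
#'   vector, node names at the level), `n_above_level`, `n_unassigned`.
#' @export
aggregate_profile <- function(assignments, tree, level,
                              merge_unassigned_into_root = FALSE) {
  stopifnot(level >= 0L, level <= tree_height(tree))
  node <- assignments$node_id
  unassigned <- is.na(node)
  if (merge_unassigned_into_root) {
    node[unassigned] <- tree$root
    unassigned <- rep(FALSE, length(node))
  }
  node_lv <- ifelse(is.na(node), NA_integer_, tree$level[node])
  at_or_below <- !is.na(node) & node_lv >= level
  anc <- vapply(node[at_or_below], function(v) level_ancestor(tree, v, level),
                integer(1))
  tab <- table(tax_node_name(tree, anc))
  structure(list(level = as.integer(level),
                 counts = stats::setNames(as.integer(tab), names(tab)),
                 n_above_level = sum(!is.na(node) & node_lv < level),
                 n_unassigned = sum(unassigned)),
            class = "level_profile")
}

#' @export
print.level_profile <- function(x, ...) {
  cat("level_profile at level ", x$level, ": ", length(x$counts),
      " nodes, ", sum(x$counts), " reads (+", x$n_above_level,
      " above level, +", x$n_unassigned, " unassigned)\n", sep = "")
  invisible(x)
}
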