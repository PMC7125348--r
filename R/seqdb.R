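# Alphabet handling. Ambiguous residues are mapped to a wildcard that never
# matches: '*' in database text, '#' in queries. The two bytes differ, so
# plain byte equality gives exact-match semantics in which an ambiguous
# position on either side terminates a match. '$' is reserved as the record
# sentinel; it sorts before all residue letters.

SENTINEL <- "$"
DB_WILDCARD <- "*"
QUERY_WILDCARD <- "#"
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_CANONICAL <- strsplit("ACGT", "")[[1]]

canonical_alphabet <- function(alphabet = c("AA", "NT")) {
  switch(match.arg(alphabet), AA = AA_CANONICAL, NT = NT_CANONICAL)
}

#' Map residues onto the index alphabet
#'
#' Uppercases and replaces every symbol outside the canonical alphabet
#' (20 amino acids or ACGT) with a wildcard that never matches: ambiguity
#' codes such as `N`, `X`, `B`, `Z`, `J`, `U`, `O` terminate exact matches
#' rather than matching loosely. Database text and queries use distinct
#' wildcard bytes so the two sides never match each other.
#'
#' @param x character vector of sequences.
#' @param alphabet `"AA"` or `"NT"`.
#' @param role `"db"` for reference records, `"query"` for reads/patterns.
#' @return Character vector of sanitized sequences.
#' @export
sanitize_residues <- function(x, alphabet = c("AA", "NT"),
                              role = c("db", "query")) {
  alphabet <- match.arg(alphabet)
  role <- match.arg(role)
  wc <- if (role == "db") DB_WILDCARD else QUERY_WILDCARD
  x <- toupper(x)
  if (role == "db" && any(grepl(SENTINEL, x, fixed = TRUE)))
    stop("sequence contains the reserved sentinel symbol '", SENTINEL, "'")
  keep <- paste0(canonical_alphabet(alphabet), collapse = "")
  gsub(sprintf("[^%s]", keep), wc, x)
}

#' Construct an annotated sequence database
#'
#' A `sequence_database` couples reference records with their taxonomy
#' labels: each record carries exactly one node of the companion
#' `taxonomy_tree`. Residues are sanitized with [sanitize_residues()].
#'
#' @param seq_id character vector of unique record ids.
#' @param residues character vector of sequences.
#' @param node_name character vector of taxonomy node names (or
#'   `node_id` integer ids via the `node_id` argument).
#' @param tree a `taxonomy_tree`.
#' @param alphabet `"AA"` or `"NT"`.
#' @param node_id integer node ids; alternative to `node_name`.
#' @return Object of class `sequence_database`.
#' @export
sequence_database <- function(seq_id, residues, node_name = NULL, tree,
                              alphabet = c("AA", "NT"), node_id = NULL) {
  alphabet <- match.arg(alphabet)
  seq_id <- as.character(seq_id)
  if (anyDuplicated(seq_id))
    stop("duplicate seq_id: ", seq_id[duplicated(seq_id)][1L])
  if (is.null(node_id)) node_id <- tax_node_id(tree, node_name)
  node_id <- check_node(tree, node_id)
  if (length(node_id) != length(seq_id) || length(residues) != length(seq_id))
    stop("seq_id, residues and labels must have equal length")
  if (any(!nzchar(residues)))
    stop("empty sequence: ", seq_id[!nzchar(residues)][1L])
  structure(list(seq_id = seq_id,
                 residues = sanitize_residues(residues, alphabet, "db"),
                 node_id = node_id, alphabet = alphabet, tree = tree),
            class = "sequence_database")
}

#' @export
print.sequence_database <- function(x, ...) {
  cat("sequence_database: ", length(x$seq_id), " records (",
      x$alphabet, "), ", sum(nchar(x$residues)), " residues, ",
      length(unique(x$node_id)), " distinct labels\n", sep = "")
  invisible(x)
}

read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  x <- Biostrings::readBStringSet(path, format = format)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Load an annotated reference database from FASTA + labels TSV
#'
#' Every FASTA record id must appear in the labels table and every label
#' must name a node of `tree`. Records preserve input order.
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param labels labels TSV path (`seq_id TAB node_name`, no header) or an
#'   equivalent two-column data.frame.
#' @param tree a `taxonomy_tree`.
#' @param alphabet `"AA"` or `"NT"`.
#' @return A `sequence_database`.
#' @export
load_database <- function(fasta_path, labels, tree, alphabet = c("AA", "NT")) {
  seqs <- read_fasta(fasta_path)
  if (!is.data.frame(labels))
    labels <- utils::read.delim(labels, header = FALSE,
                                colClasses = "character",
                                col.names = c("seq_id", "node_name"),
                                quote = "")
  lab <- stats::setNames(as.character(labels[[2L]]),
                         as.character(labels[[1L]]))
  missing <- setdiff(names(seqs), names(lab))
  if (length(missing) > 0L)
    stop("missing label for record(s): ", paste(missing[1:min(3, length(missing))],
                                                collapse = ", "))
  sequence_database(names(seqs), unname(seqs), unname(lab[names(seqs)]),
                    tree, alphabet)
}

#' Write a database back to FASTA + labels TSV
#'
#' @param db a `sequence_database`.
#' @param fasta_path,labels_path output paths.
#' @export
write_database <- function(db, fasta_path, labels_path) {
  writeLines(paste0(">", db$seq_id, "\n", db$residues), fasta_path)
  utils::write.table(data.frame(db$seq_id, tax_node_name(db$tree, db$node_id)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(db)
}

#' Six-frame translation of a nucleotide read
#'
#' Translates the read in all three offsets of both strands under the
#' standard genetic code and splits each frame's translation at stop codons
#' into maximal stop-free fragments. Codons containing an ambiguous base
#' translate to the query wildcard (terminating any exact match) so that
#' offsets are preserved. Frames `-1,-2,-3` translate the reverse
#' complement; their `nt_offset` is 0-based in the reverse-complemented
#' orientation.
#'
#' @param nt_read a nucleotide sequence (character scalar).
#' @return data.frame with columns `frame` (`+1,+2,+3,-1,-2,-3` as integer),
#'   `nt_offset` (0-based offset of the fragment's first codon in the
#'   frame's strand), and `aa` (amino-acid fragment, wildcards as `#`).
#'   Reads shorter than one codon give zero rows.
#' @examples
#' six_frame_translate("ATGAAAGTT")
#' @export
six_frame_translate <- function(nt_read) {
  empty <- data.frame(frame = integer(), nt_offset = integer(),
                      aa = character(), stringsAsFactors = FALSE)
  x <- toupper(as.character(nt_read)[1L])
  n <- nchar(x)
  if (n < 3L) return(empty)
  rc <- rev_comp(x)
  out <- vector("list", 6L)
  k <- 0L
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) x else rc
    for (off in 0:2) {
      n_codons <- (n - off) %/% 3L
      if (n_codons < 1L) next
      starts <- off + 3L * (seq_len(n_codons) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      aa <- unname(Biostrings::GENETIC_CODE[codons])
      aa[is.na(aa)] <- QUERY_WILDCARD  # ambiguous codon: wildcard, keep offset
      frags <- split_at_stops(aa)
      if (nrow(frags) > 0L) {
        k <- k + 1L
        out[[k]] <- data.frame(
          frame = strand * (off + 1L),
          nt_offset = off + 3L * (frags$aa_start - 1L),
          aa = frags$aa, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, out[seq_len(k)])
}

# maximal stop-free runs of a per-codon AA vector; aa_start is 1-based codon
split_at_stops <- function(aa) {
  is_stop <- aa == "*"
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(aa_start = starts[keep],
             aa = vapply(which(keep), function(i)
               paste0(aa[starts[i]:ends[i]], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

rev_comp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}
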