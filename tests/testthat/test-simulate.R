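test_that("fixtures are reproducible with the forced shape and counts", {
  fx <- make_fixture(seed = 1L, n_records = 10L,
                     record_len_range = c(100L, 100L),
                     branching = c(2L, 2L, 2L, 2L))
  expect_length(fx$tree$name, 31L)                  # 1 + 2 + 4 + 8 + 16
  expect_length(fx$db$seq_id, 10L)
  expect_true(all(nchar(fx$db$residues) == 100L))
  expect_true(all(fx$db$node_id %in% tax_leaves(fx$tree)))

  fx2 <- make_fixture(seed = 1L, n_records = 10L,
                      record_len_range = c(100L, 100L),
                      branching = c(2L, 2L, 2L, 2L))
  expect_identical(fx2$db$residues, fx$db$residues)
  expect_identical(fx2$db$node_id, fx$db$node_id)

  expect_error(make_fixture(branching = c(2L, 0L, 2L, 2L)), "branching")

  fx3 <- make_fixture(seed = 2L, n_records = 200L,
                      record_len_range = c(20L, 20L), internal_frac = 0.3)
  expect_gt(sum(!(fx3$db$node_id %in% tax_leaves(fx3$tree))), 0L)
  expect_false(any(fx3$db$node_id == fx3$tree$root))
})

test_that("record labels are uniform over the leaves", {
  fx <- make_fixture(seed = 9L, n_records = 8000L,
                     record_len_range = c(5L, 5L),
                     branching = c(2L, 2L, 2L, 2L))
  counts <- table(factor(fx$db$node_id, levels = tax_leaves(fx$tree)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("simulated reads carry exact truth and calibrated substitutions", {
  fx <- make_fixture(seed = 3L, n_records = 20L,
                     record_len_range = c(80L, 120L))
  reads0 <- simulate_reads(fx$db, n_reads = 200L, read_len = 50L,
                           error_rate = 0, seed = 21L)
  src <- substring(fx$db$residues[match(reads0$source_seq, fx$db$seq_id)],
                   reads0$source_offset + 1L, reads0$source_offset + 50L)
  expect_identical(reads0$residues, src)            # error 0: exact fragments
  expect_identical(reads0$truth_node,
                   fx$db$node_id[match(reads0$source_seq, fx$db$seq_id)])

  # per-read mismatch count is Binomial(read_len, error_rate): the mean
  # must sit within 3 standard errors of read_len * error_rate
  n <- 10000L
  reads <- simulate_reads(fx$db, n_reads = n, read_len = 50L,
                          error_rate = 0.05, seed = 22L)
  src <- substring(fx$db$residues[match(reads$source_seq, fx$db$seq_id)],
                   reads$source_offset + 1L, reads$source_offset + 50L)
  mm <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    reads$residues, src, USE.NAMES = FALSE)
  se <- sqrt(50 * 0.05 * 0.95 / n)
  expect_lt(abs(mean(mm) - 50 * 0.05), 3 * se)

  expect_identical(simulate_reads(fx$db, 50L, 40L, 0.1, seed = 7L),
                   simulate_reads(fx$db, 50L, 40L, 0.1, seed = 7L))
  expect_error(simulate_reads(fx$db, 10L, 1000L, 0, seed = 1L), "read_len")
})

test_that("assignments fall into the four categories plus unassigned", {
  tr <- example_tree()
  t111 <- id_of(tr, "1.1.1.1")
  expect_identical(categorize(tr, id_of(tr, "1.1.1.1"), t111), "correct")
  expect_identical(categorize(tr, id_of(tr, "1.1.1"), t111), "ancestor")
  expect_identical(categorize(tr, id_of(tr, "2.1.1.1"), t111), "incorrect")
  expect_identical(categorize(tr, tr$root, t111), "root")
  expect_identical(categorize(tr, NA, t111), "unassigned")
  # a descendant of the truth is incorrect, not an ancestor
  expect_identical(categorize(tr, t111, id_of(tr, "1.1.1")), "incorrect")
  expect_error(categorize(tr, 1L, 99L), "unknown node")
})

test_that("evaluation fractions are conserved and perfect runs score 1", {
  tr <- example_tree()
  n <- 30L
  truth <- data.frame(read_id = paste0("r", 1:n),
                      truth_node = sample(tax_leaves(tr), n, replace = TRUE))
  asg <- data.frame(read_id = truth$read_id, status = "assigned",
                    node_id = truth$truth_node,
                    node_level = tr$level[truth$truth_node],
                    mem_length = 12L, n_tied = 1L)
  ev <- evaluate(asg, truth, tr)
  expect_identical(unname(ev$fractions["correct"]), 1)
  expect_identical(sum(ev$fractions), 1)
  expect_identical(ev$mean_mem_length, 12)

  # randomized inputs: fractions always sum to 1, with or without merging
  set.seed(31)
  for (k in 1:15) {
    node <- sample(c(NA_integer_, seq_along(tr$name)), n, replace = TRUE)
    r <- data.frame(read_id = truth$read_id,
                    status = ifelse(is.na(node), "unassigned", "assigned"),
                    node_id = node, mem_length = 5L, n_tied = 1L)
    for (merge in c(TRUE, FALSE)) {
      ev <- evaluate(r, truth, tr, merge_unassigned_into_root = merge)
      expect_equal(sum(ev$fractions), 1)
      if (merge) expect_identical(unname(ev$fractions["unassigned"]), 0)
      expect_equal(sum(ev$level_histogram),
                   as.numeric(any(!is.na(node)) || merge))
    }
  }
  expect_error(evaluate(asg[1:10, ], truth, tr), "ids do not match")
})

test_that("simulated reads round-trip through FASTA + truth TSV", {
  fx <- make_fixture(seed = 13L, n_records = 5L,
                     record_len_range = c(40L, 60L))
  reads <- simulate_reads(fx$db, 20L, 30L, 0.1, seed = 2L)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_simulated_reads(reads, fa, tsv)
  back <- read_truth_tsv(tsv)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$truth_node, reads$truth_node)
  expect_identical(unname(memtax:::read_fasta(fa)), reads$residues)
})
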