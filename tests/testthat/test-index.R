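test_that("index construction satisfies its structural invariants", {
  idx <- example_index()
  expect_identical(nchar(idx$text), 18L)            # 3 x 5 residues + 3 sentinels
  expect_setequal(idx$sa, 0:17)                     # permutation of positions
  # strict lexicographic order of suffixes (byte order, sentinel smallest)
  sufs <- substring(idx$text, idx$sa + 1L, 18L)
  expect_identical(sufs, sort(sufs, method = "radix"))
  # labels[k] is the node of the suffix's source record
  expect_identical(idx$labels, example_db()$node_id[idx$doc])

  one <- build_index(sequence_database("S1", "AAA", "1", example_tree()))
  expect_identical(one$sa, c(3L, 2L, 1L, 0L))       # "AAA$": $, A$, AA$, AAA$
  expect_identical(unique(one$labels), id_of(example_tree(), "1"))

  expect_error(build_index(structure(list(seq_id = character()),
                                     class = "sequence_database")),
               "empty database")
  expect_error(sequence_database("S1", "MK$V", "1", example_tree()),
               "sentinel")
})

test_that("suffix order equals a naive sort of all suffixes on random databases", {
  set.seed(3)
  for (s in 1:15) {
    fx <- random_fixture(seed = s)
    idx <- build_index(fx$db)
    expect_identical(idx$sa, oracle_suffix_array(idx$text))
  }
})

test_that("pattern intervals, LTU and longest-prefix match the worked example", {
  idx <- example_index()
  tr <- idx$tree

  iv <- match_interval(idx, "KVLA")
  expect_identical(iv$hi - iv$lo, 2L)                         # S1 and S2
  expect_identical(nm(tr, ltu(idx, iv)), "1.1.1")

  expect_identical(match_interval(idx, "VLAGG")$hi,           # would cross
                   match_interval(idx, "VLAGG")$lo)           # a boundary
  full <- match_interval(idx, "")
  expect_identical(c(full$lo, full$hi), c(0L, 18L))
  # wildcard symbols in the pattern never match
  mx <- match_interval(idx, "MXVLA")
  expect_identical(mx$hi - mx$lo, 0L)

  expect_identical(nm(tr, ltu(idx, match_interval(idx, "MKV"))), "1.1.1.1")
  expect_identical(nm(tr, ltu(idx, match_interval(idx, "G"))), "R")
  expect_error(ltu(idx, match_interval(idx, "QQ")), "empty interval")

  expect_identical(longest_prefix_match(idx, "KVLAGGW", 0L)$length, 5L)
  lp0 <- longest_prefix_match(idx, "QQQQ", 0L)
  expect_identical(lp0$length, 0L)
  expect_identical(lp0$interval$lo, lp0$interval$hi)
})

test_that("interval, LTU and longest-prefix queries agree with brute force", {
  set.seed(19)
  for (s in 1:30) {
    fx <- random_fixture(seed = s, max_records = 12L, max_len = 80L)
    idx <- build_index(fx$db)
    for (k in 1:3) {
      q <- random_query(fx$db, len = sample(8:30, 1L), mut = 0.2)
      # match_interval: width equals overlapping occurrence count; every
      # suffix in the interval starts with the pattern
      p <- substr(q, 1L, sample(3:8, 1L))
      iv <- match_interval(idx, p)
      expect_identical(iv$hi - iv$lo, oracle_occurrences(idx$text, p))
      if (iv$lo < iv$hi) {
        sufs <- substring(idx$text, idx$sa[(iv$lo + 1L):iv$hi] + 1L)
        expect_true(all(startsWith(sufs, p)))
        expect_identical(ltu(idx, iv), oracle_ltu(fx$db, p))
      }
      # longest_prefix_match at every start
      lens <- oracle_lpm_all(idx$text, q)
      for (st in seq_len(nchar(q)) - 1L)
        expect_identical(longest_prefix_match(idx, q, st)$length,
                         lens[st + 1L])
    }
  }
})

test_that("no match interval ever spans a record boundary", {
  set.seed(23)
  for (s in 1:10) {
    fx <- random_fixture(seed = s, max_records = 10L, max_len = 60L)
    idx <- build_index(fx$db)
    q <- random_query(fx$db, len = 20L, mut = 0.1)
    m <- find_mems(idx, q, min_len = 3L)
    for (i in seq_len(nrow(m))) {
      pos <- idx$sa[(m$lo[i] + 1L):m$hi[i]]             # 0-based text starts
      doc_start <- findInterval(pos, idx$rec_end) + 1L
      doc_end <- findInterval(pos + m$length[i] - 1L, idx$rec_end) + 1L
      expect_identical(doc_start, doc_end)
    }
  }
})

test_that("a saved index answers queries identically after loading", {
  idx <- example_index()
  dir <- withr::local_tempdir()
  save_index(idx, dir)
  idx2 <- load_index(dir)
  syms <- c("M", "K", "V", "L", "A", "G", "W", "P", "Q")
  pats <- as.vector(outer(as.vector(outer(syms, syms, paste0)), syms, paste0))
  pats <- c(syms, as.vector(outer(syms, syms, paste0)), pats,
            "MKVLA", "KVLAG", "GGWWP", "VLAGG", "MKVLAG")
  for (p in pats) {
    a <- match_interval(idx, p); b <- match_interval(idx2, p)
    expect_identical(unclass(b), unclass(a))
    if (a$lo < a$hi) expect_identical(ltu(idx2, b), ltu(idx, a))
  }
  expect_identical(idx2$sa, idx$sa)
  expect_identical(idx2$labels, idx$labels)
  expect_identical(idx2$tree$name, idx$tree$name)

  # missing components and version mismatches are explicit errors
  expect_error(load_index(withr::local_tempdir()), "missing component")
  mf <- file.path(dir, "manifest.json")
  m <- jsonlite::read_json(mf)
  m$format_version <- 99L
  jsonlite::write_json(m, mf, auto_unbox = TRUE)
  expect_error(load_index(dir), "format_version")
})
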