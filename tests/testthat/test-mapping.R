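test_that("assoc_map collapses duplicates and strips whitespace", {
  m <- assoc_map(tibble::tibble(source = c("m1", "m1", "m1"),
                                target = c("g1", "g2", "g1")))
  expect_equal(as.data.frame(m),
               data.frame(source = c("m1", "m1"), target = c("g1", "g2")))

  m2 <- assoc_map(tibble::tibble(source = " m1 ", target = "g1\n"))
  expect_equal(m2$source, "m1")
  expect_equal(m2$target, "g1")

  m3 <- assoc_map(tibble::tibble(source = c("m1", "", "m2"),
                                 target = c("g1", "g2", "")))
  expect_equal(nrow(m3), 1)
  expect_equal(attr(m3, "n_skipped"), 2L)
})

test_that("read_mapping handles dialects, column selection and errors", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tscore\tgene", "m1\t0.9\tg1", "m1\t0.8\tg2", " m1 \t0.7\tg1"), tsv)
  m <- read_mapping(tsv, source_col = "miRNA", target_col = "gene")
  expect_equal(pair_set(m), pair_set(tibble::tibble(source = "m1", target = c("g1", "g2"))))

  # 0-based index selection picks the same columns
  m_idx <- read_mapping(tsv, source_col = 0, target_col = 2)
  expect_equal(as.data.frame(m_idx), as.data.frame(m))

  # comma fallback when the header has no tabs
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,disease", "g1,d1", "g2,d1"), csv)
  expect_equal(nrow(read_mapping(csv)), 2)

  expect_error(read_mapping(tsv, source_col = "absent"), "absent")
  expect_error(read_mapping(tsv, source_col = 9), "out of range")
  expect_error(read_mapping(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("read_mapping equals a nested-loop dedup oracle on random input", {
  set.seed(101)
  pairs <- random_pairs(1000, sprintf("s%02d", 1:50), sprintf("t%02d", 1:50))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(pairs, f)
  m <- read_mapping(f)
  # oracle: brute-force pairwise dedup
  seen <- character()
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$source[i], pairs$target[i], sep = "\x01")
    if (!key %in% seen) seen <- c(seen, key)
  }
  expect_setequal(pair_set(m), seen)
})

test_that("merge_on_key composes relations and accounts for dropped sources", {
  a <- assoc_map(tibble::tibble(source = c("m1", "m1", "m2"),
                                target = c("g1", "g2", "g3")))
  b <- assoc_map(tibble::tibble(source = c("g1", "g2", "g2"),
                                target = c("d1", "d1", "d2")))
  res <- suppressMessages(merge_on_key(a, b))
  expect_equal(as.data.frame(res),
               data.frame(source = c("m1", "m1"), target = c("d1", "d2")))
  expect_equal(attr(res, "dropped"), "m2")
  expect_equal(attr(res, "n_dropped"), 1L)

  # empty right side drops every source
  empty <- assoc_map(tibble::tibble(source = character(), target = character()))
  res2 <- suppressMessages(merge_on_key(a, empty))
  expect_equal(nrow(res2), 0)
  expect_setequal(attr(res2, "dropped"), c("m1", "m2"))
})

test_that("merge_on_key equals a triple-loop join oracle on random maps", {
  set.seed(202)
  for (i in 1:5) {
    a <- assoc_map(random_pairs(600, sprintf("m%03d", 1:200), sprintf("g%03d", 1:300)))
    b <- assoc_map(random_pairs(500, sprintf("g%03d", 1:300), sprintf("d%03d", 1:150)))
    res <- suppressMessages(merge_on_key(a, b))
    expect_equal(pair_set(res), pair_set(join_oracle(a, b)))
  }
})

test_that("invert_map is the transpose and an involution", {
  m <- assoc_map(tibble::tibble(source = "m1", target = c("d1", "d2")))
  inv <- invert_map(m)
  expect_equal(as.data.frame(inv),
               data.frame(source = c("d1", "d2"), target = c("m1", "m1")))

  set.seed(303)
  r <- assoc_map(random_pairs(400, sprintf("a%02d", 1:100), sprintf("b%02d", 1:100)))
  expect_equal(pair_set(invert_map(r)), pair_set(transpose_oracle(r)))
  expect_equal(as.data.frame(invert_map(invert_map(r))), as.data.frame(r))
  # count conservation: edges are preserved under transposition
  expect_equal(nrow(invert_map(r)), nrow(r))
})

test_that("build_db populates both directions with consistent universes", {
  db <- toy_db(list(c("m1", "m1", "m2"), c("d1", "d2", "d2")))
  expect_equal(db$M_N, 2)
  expect_equal(db$D_N, 2)
  expect_equal(pair_set(db$inverse), pair_set(transpose_oracle(db$forward)))

  db1 <- toy_db(list("m1", "d1"))
  expect_equal(c(db1$M_N, db1$D_N), c(1, 1))

  expect_error(build_db(tibble::tibble(source = character(), target = character())),
               "empty")

  set.seed(404)
  dbr <- random_db(40, 60, 500)
  expect_equal(pair_set(dbr$inverse), pair_set(transpose_oracle(dbr$forward)))
  expect_equal(sum(table(dbr$forward$source)), sum(table(dbr$inverse$source)))
})

test_that("query is a case-insensitive unanchored regex filter", {
  db <- toy_db(list(c("hsa-miR-335-5p", "hsa-miR-21-5p"),
                    c("Colorectal Neoplasms", "Stomach Neoplasms")))
  hit <- query_db(db, "neoplasm", by = "disease")
  expect_equal(hit$name, c("Colorectal Neoplasms", "Stomach Neoplasms"))
  expect_equal(query_db(db, "NEOPLASM", by = "disease")$name, hit$name)

  expect_equal(query_db(db, "mir-33[0-9]", by = "miRNA")$name, "hsa-miR-335-5p")
  expect_equal(nrow(query_db(db, "^$", by = "miRNA")), 0)
  expect_error(query_db(db, "([", by = "miRNA"), "regex")

  # pure filter: results are a subset of keys, sorted
  res <- query_db(db, ".", by = "miRNA")
  expect_true(all(res$name %in% db$forward$source))
  expect_equal(res$name, sort(res$name))
})

test_that("database TSV round trip is byte-stable and order independent", {
  set.seed(505)
  db <- random_db(30, 40, 300)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_db(db, d1)
  # rebuild from shuffled input rows: same files byte for byte
  shuffled <- db$forward[sample(nrow(db$forward)), ]
  write_db(build_db(shuffled), d2)
  expect_equal(readLines(file.path(d1, "mirna2disease.tsv")),
               readLines(file.path(d2, "mirna2disease.tsv")))
  expect_equal(readLines(file.path(d1, "disease2mirna.tsv")),
               readLines(file.path(d2, "disease2mirna.tsv")))

  back <- suppressMessages(read_db(d1))
  expect_equal(as.data.frame(back$forward), as.data.frame(db$forward))
  expect_equal(c(back$M_N, back$D_N), c(db$M_N, db$D_N))
})
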