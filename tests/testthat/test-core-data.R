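test_that("compound_table enforces its invariants", {
  tab <- toy_table()
  expect_equal(n_compounds(tab), 3)
  expect_equal(feature_names(tab), c("b1", "b2", "b3", "b4", "hbd", "logp"))
  expect_equal(unname(feature_types(tab)),
               c(rep("binary", 4), "discrete", "continuous"))

  expect_error(
    compound_table(c("A", "A"), matrix(0L, 2, 2)),
    "duplicate compound id: A")
  expect_error(
    compound_table(c("A", "B"), matrix(c(0, 2, 1, 0), 2, 2)),
    "non-binary fingerprint value at row 2, column 1")
  expect_error(
    compound_table("A", matrix(1L, 1, 1),
                   descriptors = matrix(NA_real_, 1, 1),
                   descriptor_types = "discrete"),
    "missing descriptor value")
  expect_error(
    compound_table("A", matrix(1L, 1, 1), labels = "Maybe"),
    "invalid label")
})

test_that("read/write round-trips a table exactly", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(tab, path)
  back <- read_compound_table(path)
  expect_identical(back$ids, tab$ids)
  expect_identical(back$bits, tab$bits)
  expect_identical(back$descriptors, tab$descriptors)
  expect_identical(back$labels, tab$labels)

  # awkward doubles survive the round trip bit-for-bit
  gen <- generate_dataset(synthetic_spec(n_active = 15, n_inactive = 15,
                                         n_bits = 12, n_informative_bits = 4,
                                         seed = 5))$table
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(gen, p2)
  b2 <- read_compound_table(p2)
  expect_identical(b2$descriptors, gen$descriptors)
  expect_identical(b2$bits, gen$bits)
})

test_that("reader handles toy files, duplicates and missing class columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tb1\tb2\tb3\tb4\td1\td2\tclass",
               "K1\t1\t0\t0\t1\t3\t0.5\tActive",
               "K2\t0\t1\t0\t1\t7\t-1.5\tInactive",
               "K3\t1\t1\t0\t0\t5\t2.25\tActive"), path)
  schema <- table_schema(bits = paste0("b", 1:4), discrete = "d1",
                         continuous = "d2", class = "class")
  tab <- read_compound_table(path, schema)
  expect_equal(n_compounds(tab), 3)
  expect_equal(ncol(tab$bits), 4)
  expect_equal(tab$labels, c("Active", "Inactive", "Active"))

  # duplicate InChIKey named in the error
  writeLines(c("id\tb1", "KEYX\t1", "KEYX\t0"), path)
  expect_error(read_compound_table(path, table_schema(bits = "b1")),
               "duplicate compound id: KEYX")

  # non-binary bit value named by row and column
  writeLines(c("id\tb1", "K1\t1", "K2\t3"), path)
  expect_error(read_compound_table(path, table_schema(bits = "b1")),
               "non-binary value '3' in bit column 'b1', row 2")

  # no class column -> Unknown labels
  writeLines(c("id\tb1", "K1\t1", "K2\t0"), path)
  tab <- read_compound_table(path, table_schema(bits = "b1",
                                                class = "class"))
  expect_equal(tab$labels, c("Unknown", "Unknown"))
})

test_that("writer handles empty tables and the class-column flag", {
  empty <- compound_table(character(0),
                          matrix(0L, 0, 3,
                                 dimnames = list(NULL, c("b1", "b2", "b3"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(empty, path)
  expect_equal(readLines(path), "id\tb1\tb2\tb3")
  expect_equal(n_compounds(read_compound_table(path)), 0)

  # Unknown labels: class column omitted by default, empty when forced
  tab <- toy_table(labels = rep("Unknown", 3))
  write_compound_table(tab, path)
  expect_false(grepl("class", readLines(path)[1]))
  write_compound_table(tab, path, write_class = TRUE)
  expect_true(grepl("class$", readLines(path)[1]))
  expect_equal(read_compound_table(path)$labels, rep("Unknown", 3))
})

test_that("a full-width table has 2132 feature columns plus the class", {
  spec <- synthetic_spec(n_active = 3, n_inactive = 3, paper_shape = TRUE,
                         seed = 2)
  tab <- generate_dataset(spec)$table
  expect_equal(length(feature_names(tab)), 2132)   # 2048 + 50 + 34
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(tab, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(length(header), 1 + 2132 + 1)       # id + features + class
})

test_that("partition_rows yields evenly sized, stratified, deterministic groups", {
  spec <- synthetic_spec(n_active = 1977, n_inactive = 1948, n_bits = 4,
                         n_informative_bits = 0, n_discrete = 0,
                         n_continuous = 0, seed = 9)
  tab <- generate_dataset(spec)$table
  pa <- partition_rows(tab, 4, seed = 123)
  expect_equal(sort(as.integer(table(pa$groups)), decreasing = TRUE),
               c(982, 981, 981, 981))
  # stratification: per-group class counts within 1 of proportionality
  for (g in 1:4) {
    ids <- group_ids(pa, g)
    n_g <- length(ids)
    act <- sum(compound_labels(tab)[ids] == "Active")
    expect_lte(abs(act - n_g * 1977 / 3925), 1)
  }
  expect_identical(partition_rows(tab, 4, seed = 123)$groups, pa$groups)
  expect_false(identical(partition_rows(tab, 4, seed = 124)$groups,
                         pa$groups))

  small <- subset_rows(tab, 1:8)
  expect_equal(unname(as.integer(table(partition_rows(small, 4, seed = 1)$groups))),
               rep(2L, 4))
  expect_error(partition_rows(small, 0, seed = 1), "positive integer")
  expect_error(partition_rows(small, 9, seed = 1), "exceeds")
})

test_that("partition invariants hold across group counts and seeds", {
  tab <- generate_dataset(synthetic_spec(n_active = 37, n_inactive = 23,
                                         n_bits = 4, seed = 3,
                                         n_informative_bits = 2,
                                         n_discrete = 0,
                                         n_continuous = 0))$table
  for (g in c(2, 3, 4, 7)) {
    for (seed in c(1, 99)) {
      pa <- partition_rows(tab, g, seed = seed, stratify = (seed == 1))
      expect_setequal(names(pa$groups), tab$ids)
      sizes <- as.integer(table(factor(pa$groups, levels = 1:g)))
      expect_lte(max(sizes) - min(sizes), 1)
    }
  }
})

test_that("select_bits_by_frequency ranks by closeness with index ties", {
  freqs <- c(0.50, 0.10, 0.90, 0.49, 0.02)
  m <- vapply(freqs, function(f) {
    c(rep(1L, round(f * 100)), rep(0L, 100 - round(f * 100)))
  }, integer(100))
  expect_equal(select_bits_by_frequency(m, 2), c(1, 4))
  expect_equal(select_bits_by_frequency(m, 5), c(1, 4, 2, 3, 5))

  # all-equal frequencies: first n column indices
  same <- matrix(rep(c(1L, 0L), 50), 100, 6)
  expect_equal(select_bits_by_frequency(same, 3), 1:3)

  # equidistant frequencies keep column order
  two <- cbind(c(rep(1L, 45), rep(0L, 55)), c(rep(1L, 55), rep(0L, 45)))
  expect_equal(select_bits_by_frequency(two, 2), c(1, 2))

  expect_error(select_bits_by_frequency(matrix(0L, 0, 0), 1), "non-empty")
  expect_error(select_bits_by_frequency(same, 7), "exceeds")
})

test_that("select_bits_by_frequency is permutation-equivariant", {
  # frequencies j/40 for j = 1..19: closeness to 0.5 is unique per column
  m <- vapply(1:19, function(j) c(rep(1L, j), rep(0L, 40 - j)), integer(40))
  sel <- select_bits_by_frequency(m, 6)
  set.seed(42)
  perm <- sample(ncol(m))
  sel_p <- select_bits_by_frequency(m[, perm], 6)
  expect_setequal(perm[sel_p], sel)
})
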