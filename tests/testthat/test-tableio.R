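test_that("the toy STAR fixture parses with correct types, quotes, missing", {
  tf <- withr::local_tempfile(fileext = ".star")
  expected <- make_toy_star(tf)
  doc <- read_star(tf)
  expect_named(doc, "micrographs")
  t <- doc$micrographs
  expect_identical(nrow(t), 4L)
  expect_identical(unname(table_ctypes(t)),
                   c("int", "float", "string", "string"))
  expect_identical(t$name[3], "mic c")        # quoted token keeps the space
  expect_true(is.na(t$group[4]))              # "." is missing
  expect_table_values_equal(t, expected)
  expect_identical(table_filter(t, "defocus < 2.0")$id, c(1L, 3L))
})

test_that("STAR loops handle empties, ordinals and malformed input", {
  tf <- withr::local_tempfile(fileext = ".star")
  writeLines(c("data_block", "loop_", "_a #1", "_b #2"), tf)
  t <- read_star(tf)$block
  expect_identical(nrow(t), 0L)
  expect_identical(names(t), c("a", "b"))

  # ordinals override file order of the label lines
  writeLines(c("data_block", "loop_", "_b #2", "_a #1", "1 x", "2 y"), tf)
  t2 <- read_star(tf)$block
  expect_identical(names(t2), c("a", "b"))
  expect_identical(t2$a, 1:2)
  expect_identical(t2$b, c("x", "y"))

  writeLines(c("data_block", "loop_", "_a #1", "_b #2", "_c #3", "1 2"), tf)
  expect_error(read_star(tf), "3 columns")

  writeLines(c("data_block", "loop_", "_a #1", '"unterminated'), tf)
  expect_error(read_star(tf), "unterminated")

  writeLines(c("data_block", "loop_", "_a #1", "_a #2", "1 2"), tf)
  expect_error(read_star(tf), "duplicate")
})

test_that("key-value blocks become single-row tables", {
  tf <- withr::local_tempfile(fileext = ".star")
  writeLines(c("data_general", "_voltage 300", "_cs 2.7",
               "_microscope \"Krios G4\""), tf)
  t <- read_star(tf)$general
  expect_identical(nrow(t), 1L)
  expect_identical(t$voltage, 300L)
  expect_identical(t$cs, 2.7)
  expect_identical(t$microscope, "Krios G4")
})

test_that("semicolon-delimited text fields are read as single values", {
  tf <- withr::local_tempfile(fileext = ".star")
  writeLines(c("data_b", "loop_", "_id #1", "_note #2",
               "1", ";", "line one", "line two", ";"), tf)
  t <- read_star(tf)$b
  expect_identical(t$note[1], "line one\nline two")
})

test_that("write_star round-trips documents and quotes what needs quoting", {
  tf <- withr::local_tempfile(fileext = ".star")
  doc <- list(parts = em_table(tibble::tibble(
    id = c(1L, 2L, NA),
    score = c(0.1, NA, 1 / 3),
    label = c("plain", "needs quote", NA))))
  write_star(doc, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("\"needs quote\"", lines)))
  expect_true(any(grepl("^_id #1$", lines)))   # RELION ordinal labels
  back <- read_star(tf)
  expect_named(back, "parts")
  expect_table_values_equal(back$parts, doc$parts)
  # shortest round-trip float serialization is exact
  expect_identical(back$parts$score[3], 1 / 3)
})

test_that("STAR round-trip is an involution on randomized documents", {
  for (seed in c(1:30)) {
    doc <- rand_star_doc(seed)
    tf <- withr::local_tempfile(fileext = ".star")
    write_star(doc, tf)
    back <- read_star(tf)
    expect_identical(names(back), names(doc), info = paste("seed", seed))
    for (bn in names(doc)) {
      expect_table_values_equal(back[[bn]], doc[[bn]])
    }
  }
})

test_that("written STAR parses identically under the independent parser", {
  doc <- rand_star_doc(99)
  tf <- withr::local_tempfile(fileext = ".star")
  write_star(doc, tf)
  ref <- ref_parse_star_loop(tf)
  expect_identical(names(ref), names(doc))
  for (bn in names(doc)) {
    expect_identical(ref[[bn]]$labels, names(doc[[bn]]))
    expect_identical(nrow(ref[[bn]]$rows), nrow(doc[[bn]]))
  }
})

test_that("TSV round-trips losslessly and rejects ragged rows", {
  tf <- withr::local_tempfile(fileext = ".star")
  expected <- make_toy_star(tf)
  t <- read_star(tf)$micrographs

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(t, tsv)
  back <- read_tsv_table(tsv)
  expect_table_values_equal(back, t)

  # empty table: header-only file, zero rows back
  t0 <- em_table(tibble::tibble(a = integer(), b = character()))
  tsv0 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(t0, tsv0)
  expect_identical(length(readLines(tsv0)), 1L)
  b0 <- read_tsv_table(tsv0)
  expect_identical(nrow(b0), 0L)
  expect_identical(names(b0), c("a", "b"))

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2", "3"), ragged)
  expect_error(read_tsv_table(ragged), "ragged")

  # csv delimiter
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tsv_table(t, csv, delimiter = ",")
  expect_error(write_tsv_table(t, csv, delimiter = "c"),
               "delimiter")  # values contain the letter c
  expect_table_values_equal(read_tsv_table(csv, delimiter = ","), t)
})
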