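test_that("NEXUS matrices read back their declared content", {
  tf <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;",
               "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
               "MATRIX", "taxA 01?", "taxB 1-0", ";", "END;"), tf)
  m <- readCharacterMatrix(tf)
  expect_s3_class(m, "characterMatrix")
  expect_equal(m$taxa, c("taxA", "taxB"))
  expect_equal(m$n_characters, 3L)
  expect_equal(countMissing(m), 1L)
  expect_equal(m$missing, "?")
  expect_equal(m$gap, "-")
  expect_equal(unname(m$cells["taxB", ]), c("1", "-", "0"))
})

test_that("missing-cell count matches a hand count of the fixture", {
  tf <- nexus_fixture_5x10(tempfile(fileext = ".nex"))
  m <- readCharacterMatrix(tf)
  expect_equal(length(m$taxa), 5L)
  expect_equal(m$n_characters, 10L)
  expect_equal(countMissing(m), 7L)
})

test_that("write/read round-trip preserves taxa, dimensions and cells", {
  tf <- nexus_fixture_5x10(tempfile(fileext = ".nex"))
  m <- readCharacterMatrix(tf)
  tf2 <- tempfile(fileext = ".nex")
  writeCharacterMatrix(m, tf2)
  m2 <- readCharacterMatrix(tf2)
  expect_equal(m2$taxa, m$taxa)
  expect_equal(m2$n_characters, m$n_characters)
  expect_equal(m2$cells, m$cells)
})

test_that("malformed or inconsistent NEXUS blocks raise structural errors", {
  tf <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TREES;", "END;"), tf)
  expect_error(readCharacterMatrix(tf), "no DATA/CHARACTERS block")

  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=3;",
               "FORMAT DATATYPE=STANDARD MISSING=? GAP=-;",
               "MATRIX", "taxA 01?", "taxB 1-0", ";", "END;"), tf)
  expect_error(readCharacterMatrix(tf), "ntax", ignore.case = TRUE)

  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2;",
               "FORMAT MISSING=? GAP=-;",
               "MATRIX", "taxA 01?", "taxB 1-0", ";", "END;"), tf)
  expect_error(readCharacterMatrix(tf), "NTAX and NCHAR")
})

test_that("merging character sets is size-exact with overlap removal", {
  a <- characterRegionMap(rep(list("frontal"), 5), source = "A")
  b <- characterRegionMap(rep(list("femur"), 5), source = "B")
  expect_equal(nCharacters(mergeCharacterSets(a, b)), 10L)

  ov <- data.frame(id_a = c(1L, 2L), id_b = c(3L, 5L))
  merged <- mergeCharacterSets(a, b, ov)
  expect_equal(nCharacters(merged), 8L)
  prov <- attr(merged, "provenance")
  expect_equal(prov$character_id, 1:8)
  expect_equal(sum(prov$source_map == "b"), 3L)
  expect_false(any(prov$original_id[prov$source_map == "b"] %in% ov$id_b))

  # self-merge under a full overlap list collapses to the original size
  full <- data.frame(id_a = 1:5, id_b = 1:5)
  expect_equal(nCharacters(mergeCharacterSets(a, a, full)), 5L)
})

test_that("overlap validation rejects bad pairs", {
  a <- characterRegionMap(rep(list("frontal"), 5))
  b <- characterRegionMap(rep(list("femur"), 5))
  expect_error(mergeCharacterSets(a, b, data.frame(id_a = c(1, 1), id_b = c(1, 2))),
               "duplicate")
  expect_error(mergeCharacterSets(a, b, data.frame(id_a = 9, id_b = 1)),
               "outside")
})

test_that("merge size identity holds on random maps", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_map(sample(3:12, 1))
    b <- random_map(sample(3:12, 1))
    k <- sample(0:min(nCharacters(a), nCharacters(b)), 1)
    ov <- data.frame(id_a = sample(nCharacters(a), k),
                     id_b = sample(nCharacters(b), k))
    expect_equal(nCharacters(mergeCharacterSets(a, b, ov)),
                 nCharacters(a) + nCharacters(b) - k)
  }
})

test_that("charactersForElements returns exactly the fully-covered characters", {
  map <- fixture_map10()
  expect_equal(charactersForElements(map, character(0)), integer(0))
  expect_equal(charactersForElements(map, VOCAB$element), 1:10)
  expect_equal(charactersForElements(map, "frontal"), 1:6)
  expect_equal(charactersForElements(map, "femur"), 7:9)
  expect_equal(charactersForElements(map, c("frontal", "femur")), 1:10)
  expect_error(charactersForElements(map, "wishbone"), "unknown element")
})

test_that("charactersForElements is monotone in the element set", {
  set.seed(7)
  for (i in 1:25) {
    map <- random_map(15)
    e2 <- sample(VOCAB$element, sample(5:30, 1))
    e1 <- sample(e2, sample(seq_along(e2), 1))
    expect_true(all(charactersForElements(map, e1) %in%
                      charactersForElements(map, e2)))
  }
})

test_that("region map CSV round-trips and validates its vocabulary", {
  map <- fixture_map10()
  tf <- tempfile(fileext = ".csv")
  writeRegionMap(map, tf)
  map2 <- readRegionMap(tf)
  expect_equal(map2$characters$elements, map$characters$elements)
  expect_error(characterRegionMap(list("frontal", "not_a_bone")),
               "unknown element")
  expect_error(characterRegionMap(list()), "non-empty")
})
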