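test_that("applicable-character denominators follow the limbless rule", {
  map <- fixture_map10()
  expect_equal(applicableCount(map, limbless = FALSE), 10L)
  # 3 femur characters + 1 frontal+femur character leave 6
  expect_equal(applicableCount(map, limbless = TRUE), 6L)
  expect_equal(applicableCharacters(map, TRUE), 1:6)

  no_limbs <- characterRegionMap(rep(list("frontal"), 4))
  expect_equal(applicableCount(no_limbs, TRUE), applicableCount(no_limbs, FALSE))
})

test_that("CCM2 spans its range and matches the worked fixture", {
  map <- fixture_map10()
  all_el <- preservationRecord("full", VOCAB$element, n_specimens = 1)
  expect_equal(scoreSpeciesCCM2(map, all_el)$ccm2, 100)

  none <- preservationRecord("none", character(0))
  expect_equal(scoreSpeciesCCM2(map, none)$ccm2, 0)

  skull_only <- preservationRecord("sk", "frontal")
  s <- scoreSpeciesCCM2(map, skull_only)
  expect_equal(s$scorable, 6L)
  expect_equal(s$applicable, 10L)
  expect_equal(s$ccm2, 60)
})

test_that("a fully preserved limbless species reaches 100% true completeness", {
  map <- squamateCharacterMap()
  non_limb <- VOCAB$element[!VOCAB$partition %in% limbPartitions()]
  rec <- preservationRecord("snake", non_limb, limbless = TRUE)
  s <- scoreSpeciesCCM2(map, rec)
  expect_equal(s$applicable, 710L)
  expect_equal(s$scorable, 710L)
  expect_equal(s$ccm2, 100)
  # the same elements on a limbed species score below 100
  limbed <- scoreSpeciesCCM2(map, preservationRecord("lizard", non_limb))
  expect_equal(limbed$applicable, 860L)
  expect_lt(limbed$ccm2, 100)
})

test_that("limbless records may not carry limb elements", {
  expect_error(preservationRecord("bad", c("frontal", "femur"), limbless = TRUE),
               "limb/girdle")
})

test_that("union preservation pools specimens and never lowers the score", {
  r <- unionPreservation(list(c("frontal")), "one")
  expect_equal(r$elements, "frontal")
  expect_equal(r$n_specimens, 1L)

  r2 <- unionPreservation(list("frontal", "femur"), "two")
  expect_setequal(r2$elements, c("frontal", "femur"))
  expect_equal(r2$n_specimens, 2L)
  expect_error(unionPreservation(list(), "none"), "non-empty")

  set.seed(21)
  map <- random_map(20)
  for (i in 1:10) {
    specimens <- replicate(sample(2:4, 1),
                           sample(VOCAB$element, sample(1:10, 1)),
                           simplify = FALSE)
    pooled <- scoreSpeciesCCM2(map, unionPreservation(specimens, "sp"))
    per_spec <- vapply(specimens, function(e) {
      scoreSpeciesCCM2(map, preservationRecord("sp", e))$ccm2
    }, numeric(1))
    expect_gte(pooled$ccm2, max(per_spec))
  }
})

test_that("CCM2 equals the brute-force per-character oracle", {
  set.seed(42)
  for (i in 1:100) {
    map <- random_map(sample(5:50, 1))
    rec <- random_record(p = stats::runif(1, 0.1, 0.9),
                         limbless = stats::runif(1) < 0.3)
    got <- scoreSpeciesCCM2(map, rec)
    want <- oracle_ccm2(map, rec)
    expect_equal(got$scorable, want$scorable)
    expect_equal(got$applicable, want$applicable)
    expect_equal(got$ccm2, want$ccm2)
  }
})

test_that("CCM2 is monotone in the preserved-element set", {
  set.seed(5)
  for (i in 1:20) {
    map <- random_map(25)
    e2 <- sample(VOCAB$element, sample(10:40, 1))
    e1 <- sample(e2, sample(seq_along(e2), 1))
    s1 <- scoreSpeciesCCM2(map, preservationRecord("a", e1))
    s2 <- scoreSpeciesCCM2(map, preservationRecord("a", e2))
    expect_lte(s1$ccm2, s2$ccm2)
  }
})

test_that("limbless denominator never exceeds the limbed one and lifts limb-free scores", {
  set.seed(6)
  for (i in 1:15) {
    map <- random_map(30)
    expect_lte(applicableCount(map, TRUE), applicableCount(map, FALSE))
    non_limb <- VOCAB$element[!VOCAB$partition %in% limbPartitions()]
    els <- sample(non_limb, sample(5:20, 1))
    s_limbless <- scoreSpeciesCCM2(map, preservationRecord("a", els, TRUE))
    s_limbed <- scoreSpeciesCCM2(map, preservationRecord("a", els, FALSE))
    expect_gte(s_limbless$ccm2, s_limbed$ccm2)
  }
})

test_that("SCM2 conversion is the character-density-weighted mean", {
  expect_equal(convertSCM2toCCM2(c(1, 1, 1), c(5, 5, 5)), 100)
  # uniform counts reduce to the arithmetic mean of the proportions
  expect_equal(convertSCM2toCCM2(c(0.2, 0.4, 0.9), c(7, 7, 7)),
               100 * mean(c(0.2, 0.4, 0.9)))
  expect_equal(convertSCM2toCCM2(c(1, 0.5, 0), c(10, 20, 70)), 20)
  expect_warning(out <- convertSCM2toCCM2(0.5, c(10, 20)), "broadcast")
  expect_equal(out, 50)
  expect_error(convertSCM2toCCM2(c(0.5), c(0)), "sum > 0")
  expect_error(convertSCM2toCCM2(c(1.2, 0), c(1, 1)), "\\[0, 1\\]")
})

test_that("binary SCM2 conversion agrees with direct scoring when characters stay within partitions", {
  set.seed(9)
  for (i in 1:10) {
    map <- random_map(30, max_req = 1L)  # single-element: never spans partitions
    dens <- regionDensity(map)
    present <- sample(ccmPartitions(), sample(1:8, 1))
    p <- as.numeric(ccmPartitions() %in% present)
    els <- VOCAB$element[VOCAB$partition %in% present]
    direct <- scoreSpeciesCCM2(map, preservationRecord("a", els))$ccm2
    expect_equal(convertSCM2toCCM2(p, dens), direct)
  }
})

test_that("per-specimen CSV records pool into species records", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    species_id = c("sp1", "sp1", "sp2"),
    specimen_id = c("a", "b", "c"),
    elements = c("frontal;maxilla", "femur", "dentary"),
    limbless = c(FALSE, FALSE, TRUE)), tf, row.names = FALSE)
  recs <- readPreservationRecords(tf)
  expect_length(recs, 2L)
  expect_setequal(recs[[1]]$elements, c("frontal", "maxilla", "femur"))
  expect_equal(recs[[1]]$n_specimens, 2L)
  expect_true(recs[[2]]$limbless)
})
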