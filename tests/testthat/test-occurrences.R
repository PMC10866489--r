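toy_table <- function() {
  rbind(
    occ_row("Genus_indet", rank = "genus"),
    occ_row("Lacerta_viva", extant = TRUE),
    occ_row("Saichangurvel_davidsoni", n_spec = 2, n_loc = 1),
    occ_row("Saichangurvel_davidsoni", n_spec = 3, n_loc = 2),
    occ_row("Gobiderma_pulchrum"),
    occ_row("Dalinghosaurus_longidigitus", formation = "Yixian",
            environment = "lacustrine", lager = "konservat",
            max_ma = 125, min_ma = 122)
  )
}

test_that("vetting applies the rank, extant and de-duplication rules", {
  ds <- loadAndVet(toy_table())
  expect_s3_class(ds, "occurrenceDataset")
  expect_equal(nrow(ds), 3L)
  expect_setequal(ds$species_id,
                  c("Saichangurvel_davidsoni", "Gobiderma_pulchrum",
                    "Dalinghosaurus_longidigitus"))
  log <- vettingLog(ds)
  expect_equal(sum(log$rule == "rank"), 1L)
  expect_equal(sum(log$rule == "extant"), 1L)
  expect_equal(sum(log$rule == "merge"), 1L)
  # duplicate collapsed with summed counts
  merged <- ds[ds$species_id == "Saichangurvel_davidsoni", ]
  expect_equal(merged$n_specimens, 5)
  expect_equal(merged$n_localities, 3)
})

test_that("clean and empty tables pass through vetting unchanged", {
  clean <- rbind(occ_row("A_a"), occ_row("B_b"), occ_row("C_c"))
  ds <- loadAndVet(clean)
  expect_equal(nrow(ds), 3L)
  expect_equal(nrow(vettingLog(ds)), 0L)

  empty <- clean[0, ]
  ds0 <- loadAndVet(empty)
  expect_equal(nrow(ds0), 0L)
  expect_equal(nrow(vettingLog(ds0)), 0L)
})

test_that("vetting is idempotent at the dataset level", {
  ds <- loadAndVet(toy_table())
  back <- as.data.frame(ds)
  names(back)[names(back) == "species_id"] <- "accepted_name"
  ds2 <- loadAndVet(back)
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "vetting_log") <- NULL
    d
  }
  expect_equal(strip(ds2), strip(ds))
  # and an already-vetted table produces an empty log
  expect_equal(nrow(vettingLog(ds2)), 0L)
})

test_that("conflicting duplicate labels keep the first-seen value and are logged", {
  tab <- rbind(occ_row("X_y", landmass = "Asia"),
               occ_row("X_y", landmass = "Europe"))
  ds <- loadAndVet(tab)
  expect_equal(ds$landmass, "Asia")
  expect_true(any(vettingLog(ds)$rule == "merge_conflict"))
})

test_that("schema and vocabulary violations are hard errors", {
  tab <- toy_table()
  expect_error(loadAndVet(tab[, -3]), "missing column")
  bad <- occ_row("Z_z", landmass = "Atlantis")
  expect_error(loadAndVet(bad), "unknown landmass")
  flipped <- occ_row("Z_z", max_ma = 10, min_ma = 20)
  expect_error(loadAndVet(flipped), "max_ma < min_ma")
})

test_that("partitions are exhaustive and sized like a hand tally", {
  tab <- rbind(occ_row("s1"), occ_row("s2"), occ_row("s3", landmass = "Europe",
                                                     formation = "Quercy",
                                                     environment = "cave_karst"),
               occ_row("s4", landmass = "Europe", formation = "Quercy",
                       environment = "cave_karst"),
               occ_row("s5"))
  ds <- loadAndVet(tab)
  part <- partitionBy(ds, "landmass")
  expect_equal(lengths(part$groups), c(Asia = 3L, Europe = 2L))
  expect_equal(sum(lengths(part$groups)), nrow(ds))

  one <- partitionBy(ds[ds$landmass == "Asia", ], "unit")
  expect_length(one$groups, 1L)

  envs <- rbind(
    do.call(rbind, lapply(1:4, function(i) occ_row(paste0("a", i)))),
    do.call(rbind, lapply(1:3, function(i)
      occ_row(paste0("b", i), environment = "lacustrine"))),
    occ_row("c1", environment = "marine"))
  pe <- partitionBy(loadAndVet(envs), "environment")
  expect_equal(sort(unname(lengths(pe$groups)), decreasing = TRUE),
               c(4L, 3L, 1L))
  expect_error(partitionBy(ds, "continent"), "unknown grouping key")
})

test_that("minimum-sample filtering retains and logs the right groups", {
  groups <- list(A = as.character(1:8), B = as.character(1:6),
                 C = as.character(1:3))
  part <- structure(list(key = "landmass", groups = groups,
                         exclusion_log = data.frame(group = character(0),
                                                    size = integer(0))),
                    class = "groupPartition")
  kept <- applyMinSample(part, 6)
  expect_named(kept$groups, c("A", "B"))
  expect_equal(kept$exclusion_log$group, "C")
  expect_equal(kept$exclusion_log$size, 3L)
  # threshold 1 is the identity
  expect_equal(applyMinSample(part, 1)$groups, groups)
})

test_that("unit removal subtracts exactly the units' species", {
  tab <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      occ_row(paste0("jehol", i), formation = "Yixian",
              environment = "lacustrine", lager = "konservat",
              max_ma = 125, min_ma = 122))),
    do.call(rbind, lapply(1:4, function(i)
      occ_row(paste0("gobi", i), formation = "Djadokhta"))),
    do.call(rbind, lapply(1:11, function(i)
      occ_row(paste0("other", i), formation = "NA_channel",
              landmass = "North America", environment = "fluvial"))))
  ds <- loadAndVet(tab)
  expect_equal(nrow(ds), 20L)
  out <- subsetWithoutUnits(ds, c("Yixian", "Djadokhta"))
  expect_equal(nrow(out), 11L)
  expect_false(any(out$formation %in% c("Yixian", "Djadokhta")))

  expect_warning(same <- subsetWithoutUnits(ds, "Baruungoyot"),
                 "not present")
  expect_equal(as.data.frame(same), as.data.frame(ds))

  # removing U1 then U2 equals removing their union
  seq_removal <- subsetWithoutUnits(subsetWithoutUnits(ds, "Yixian"),
                                    "Djadokhta")
  both <- subsetWithoutUnits(ds, c("Yixian", "Djadokhta"))
  expect_equal(as.data.frame(seq_removal), as.data.frame(both))
})
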