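#' Analysis configuration
#'
#' Bundles the paths, thresholds and seeds shared by the pipeline commands.
#' The minimum-sample defaults follow the analysis design: landmass panels
#' require at least 6 species per landmass, depositional-environment panels
#' at least 17 species per environment. Named unit-set aliases resolve
#' composite assemblages (Jehol, Gobi) to their formation pairs.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed used by [cmdSimulate()].
#' @param alpha base significance level in (0, 1).
#' @param min_n_landmass,min_n_environment minimum group sizes (>= 1).
#' @param aliases named list of formation-label vectors.
#' @param occurrences,specimens,scores file paths used by the commands
#'   (defaults are inside `outdir`).
#' @param map a `characterRegionMap`; defaults to the packaged squamate
#'   map.
#' @return An `analysisConfig`.
#' @export
analysisConfig <- function(outdir = tempfile("fossilccm_run_"),
                           seed = 1L, alpha = 0.05,
                           min_n_landmass = 6L, min_n_environment = 17L,
                           aliases = unitAliases(),
                           occurrences = file.path(outdir, "occurrences.csv"),
                           specimens = file.path(outdir, "specimens.csv"),
                           scores = file.path(outdir, "scores.csv"),
                           map = squamateCharacterMap()) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (min_n_landmass < 1L || min_n_environment < 1L) {
    stop("minimum sample thresholds must be >= 1", call. = FALSE)
  }
  structure(list(outdir = outdir, seed = as.integer(seed), alpha = alpha,
                 min_n_landmass = as.integer(min_n_landmass),
                 min_n_environment = as.integer(min_n_environment),
                 aliases = aliases, occurrences = occurrences,
                 specimens = specimens, scores = scores, map = map),
            class = "analysisConfig")
}

# write a machine-readable run manifest next to a command's outputs
write_manifest <- function(config, command, inputs, outputs, extra = list()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- c(list(
    command = command,
    package_version = as.character(utils::packageVersion("fossilccm")),
    seed = config$seed,
    alpha = config$alpha,
    min_n_landmass = config$min_n_landmass,
    min_n_environment = config$min_n_environment,
    aliases = config$aliases,
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)),
    outputs = outputs
  ), extra)
  path <- file.path(config$outdir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# md5 of a region map via its canonical CSV serialization
map_checksum <- function(map) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  writeRegionMap(map, tf)
  unname(tools::md5sum(tf))
}

#' Generate synthetic inputs on disk
#'
#' Runs [generateFossilRecord()] under the config's seed and writes the
#' occurrence table, the per-specimen-free preservation records (one row
#' per species with its pooled element set) and the ground truth, in the
#' schemas the other commands consume.
#'
#' @param config an `analysisConfig`.
#' @param sim a `simulationConfig`; defaults to
#'   `defaultSimulationConfig(config$seed, config$map)`.
#' @param verbose print progress messages.
#' @return Invisibly, the list from [generateFossilRecord()].
#' @export
cmdSimulate <- function(config,
                        sim = defaultSimulationConfig(config$seed, config$map),
                        verbose = FALSE) {
  stopifnot(inherits(config, "analysisConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generateFossilRecord(sim)
  occ <- as.data.frame(gen$occurrences)
  names(occ)[names(occ) == "species_id"] <- "accepted_name"
  utils::write.csv(occ, config$occurrences, row.names = FALSE)
  spec <- do.call(rbind, lapply(gen$records, function(r) {
    data.frame(species_id = r$species_id,
               specimen_id = paste0(r$species_id, "_pooled"),
               elements = paste(r$elements, collapse = ";"),
               limbless = r$limbless, n_specimens = r$n_specimens,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(spec, config$specimens, row.names = FALSE)
  truth_path <- file.path(config$outdir, "ground_truth.csv")
  utils::write.csv(gen$truth$species, truth_path, row.names = FALSE)
  expected_path <- file.path(config$outdir, "expected_ccm2.csv")
  utils::write.csv(data.frame(unit = names(gen$truth$expected_ccm2),
                              expected_ccm2 = unname(gen$truth$expected_ccm2)),
                   expected_path, row.names = FALSE)
  if (verbose) message("simulated ", nrow(occ), " species into ", config$outdir)
  write_manifest(config, "simulate", character(0),
                 c(config$occurrences, config$specimens, truth_path,
                   expected_path),
                 list(n_species = nrow(occ)))
  invisible(gen)
}

#' Score species completeness from files
#'
#' Reads the occurrence and specimen tables named in the config, vets the
#' occurrences, pools specimens per species, scores CCM2 against the
#' config's character map and writes the score table plus a run manifest
#' recording the map checksum and both denominators.
#'
#' @inheritParams cmdSimulate
#' @return Invisibly, the score data.frame (one row per vetted species).
#' @export
cmdScore <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "analysisConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  occ <- loadAndVet(config$occurrences)
  records <- readPreservationRecords(config$specimens,
                                     vocabulary = config$map$vocabulary)
  rec_ids <- vapply(records, `[[`, character(1), "species_id")
  keep <- rec_ids %in% occ$species_id
  scores <- scoreCCM2(config$map, records[keep])
  scores <- scores[match(occ$species_id, scores$species_id), ]
  utils::write.csv(scores, config$scores, row.names = FALSE)
  log_path <- file.path(config$outdir, "vetting_log.csv")
  utils::write.csv(vettingLog(occ), log_path, row.names = FALSE)
  if (verbose) {
    message("scored ", nrow(scores), " species (",
            nrow(vettingLog(occ)), " vetting log entries)")
  }
  write_manifest(config, "score",
                 c(config$occurrences, config$specimens),
                 c(config$scores, log_path),
                 list(map_checksum = map_checksum(config$map),
                      n_characters = nCharacters(config$map),
                      denominator_limbed = applicableCount(config$map, FALSE),
                      denominator_limbless = applicableCount(config$map, TRUE)))
  invisible(scores)
}

#' Summaries and pairwise test battery for one grouping key
#'
#' Partitions the vetted dataset by `key` within each taxon group, applies
#' the key's minimum-sample threshold, and writes per-group distribution
#' summaries plus the Bonferroni-corrected pairwise comparison family (one
#' family per taxon-group panel; families are never pooled across panels).
#'
#' @inheritParams cmdSimulate
#' @param key grouping key (see [partitionBy()]).
#' @param group optional single taxon group; default runs every group with
#'   at least two retained subgroups.
#' @return Invisibly, a named list (per taxon group) with `summaries`
#'   (data.frame) and `family` (a `comparisonFamily`, or `NULL` if fewer
#'   than two groups survive the threshold).
#' @export
cmdCompare <- function(config, key = "landmass", group = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "analysisConfig"))
  occ <- loadAndVet(config$occurrences)
  scores <- utils::read.csv(config$scores, stringsAsFactors = FALSE)
  sc <- stats::setNames(scores$ccm2, scores$species_id)
  threshold <- switch(key, landmass = config$min_n_landmass,
                      environment = config$min_n_environment, 1L)
  groups_to_run <- if (is.null(group)) unique(occ$taxon_group) else group
  out <- list()
  written <- character(0)
  for (g in groups_to_run) {
    sub <- occ[occ$taxon_group == g, , drop = FALSE]
    if (!nrow(sub)) next
    part <- applyMinSample(partitionBy(sub, key), threshold)
    samples <- lapply(part$groups, function(ids) unname(sc[ids]))
    summaries <- do.call(rbind, lapply(names(samples), function(lab) {
      s <- summarizeDistribution(samples[[lab]], lab)
      data.frame(group = lab, n = s$n, median = s$median, q1 = s$q1,
                 q3 = s$q3, lo95 = s$lo95, hi95 = s$hi95,
                 interval_type = s$interval_type, stringsAsFactors = FALSE)
    }))
    fam <- NULL
    if (length(samples) >= 2L) {
      fam <- runFamily(samples, alpha = config$alpha)
      stem <- file.path(config$outdir, paste0("compare_", key, "_", g))
      written <- c(written, writeComparisonFamily(fam, stem))
    } else if (verbose) {
      message("panel ", g, "/", key,
              ": fewer than two groups above threshold, skipped")
    }
    if (!is.null(summaries)) {
      spath <- file.path(config$outdir,
                         paste0("summary_", key, "_", g, ".csv"))
      utils::write.csv(summaries, spath, row.names = FALSE)
      written <- c(written, spath)
    }
    out[[g]] <- list(summaries = summaries, family = fam,
                     excluded = part$exclusion_log)
  }
  write_manifest(config, paste0("compare_", key),
                 c(config$occurrences, config$scores), written,
                 list(key = key, threshold = threshold))
  invisible(out)
}

#' Leave-unit-out analysis from files
#'
#' @inheritParams cmdSimulate
#' @param alias name of a unit-set alias in the config (e.g. `"jehol"`), or
#'   a character vector of formation labels.
#' @param scope optional landmass label (e.g. `"Asia"`).
#' @param group optional taxon-group label.
#' @param m Bonferroni family size for the comparison.
#' @return Invisibly, the `leaveOutResult`.
#' @export
cmdLeaveout <- function(config, alias, scope = NULL, group = NULL, m = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(config, "analysisConfig"))
  units <- if (length(alias) == 1L && alias %in% names(config$aliases)) {
    config$aliases[[alias]]
  } else {
    as.character(alias)
  }
  occ <- loadAndVet(config$occurrences)
  scores <- utils::read.csv(config$scores, stringsAsFactors = FALSE)
  res <- leaveUnitOut(scores, occ, units, scope = scope, group = group,
                      alpha = config$alpha, m = m)
  out_path <- file.path(config$outdir,
                        paste0("leaveout_", paste(alias, collapse = "_"),
                               if (!is.null(group)) paste0("_", group) else "",
                               ".json"))
  jsonlite::write_json(
    list(units = res$units, scope = res$scope, group = res$group,
         n_full = res$n_full, n_reduced = res$n_reduced,
         n_removed = res$n_removed, median_full = res$median_full,
         median_reduced = res$median_reduced,
         p_mw = if (is.null(res$comparison)) NULL else res$comparison$p_mw,
         p_ks = if (is.null(res$comparison)) NULL else res$comparison$p_ks,
         alpha_adjusted = res$alpha_adjusted,
         sig_mw = res$sig_mw, sig_ks = res$sig_ks),
    out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (verbose) print(res)
  write_manifest(config, "leaveout",
                 c(config$occurrences, config$scores), out_path,
                 list(alias = alias, units = units))
  invisible(res)
}

#' Matrix-representation analysis from files
#'
#' @inheritParams cmdLeaveout
#' @param matrix_taxa path to a CSV with columns `taxon`, `is_fossil`,
#'   `family`, `unit` (the unit each fossil terminal derives from; empty
#'   for none), or a data.frame of the same shape.
#' @param name matrix name used in outputs.
#' @return Invisibly, the `matrixRepresentation`.
#' @export
cmdRepresent <- function(config, matrix_taxa, alias, name = "matrix",
                         verbose = FALSE) {
  stopifnot(inherits(config, "analysisConfig"))
  if (is.character(matrix_taxa)) {
    matrix_taxa <- utils::read.csv(matrix_taxa, stringsAsFactors = FALSE)
  }
  units <- if (length(alias) == 1L && alias %in% names(config$aliases)) {
    config$aliases[[alias]]
  } else {
    as.character(alias)
  }
  members <- matrix_taxa$taxon[matrix_taxa$unit %in% units]
  res <- matrixRepresentation(matrix_taxa[, c("taxon", "is_fossil", "family")],
                              members, name = name)
  out_path <- file.path(config$outdir,
                        paste0("represent_", name, "_",
                               paste(alias, collapse = "_"), ".json"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    res[c("name", "n_taxa", "n_fossil", "n_from_unit", "percent_fossil",
          "percent_all", "n_families", "families")],
    out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (verbose) print(res)
  write_manifest(config, "represent", character(0), out_path,
                 list(alias = alias, units = units))
  invisible(res)
}

#' Group medians and counts from a deposited score table
#'
#' Ingestion path for an externally supplied per-species score table (e.g.
#' a study's deposited completeness scores): given `species_id`, `ccm2` and
#' any grouping column, returns each group's n and median CCM2. Useful for
#' reproducing printed summary tables from deposited data.
#'
#' @param scores data.frame (or CSV path) with `species_id`, `ccm2` and the
#'   grouping column.
#' @param by name of the grouping column.
#' @return data.frame with `group`, `n`, `median_ccm2`.
#' @export
groupMedians <- function(scores, by) {
  if (is.character(scores)) scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  if (!all(c("species_id", "ccm2", by) %in% names(scores))) {
    stop("score table needs columns species_id, ccm2 and '", by, "'",
         call. = FALSE)
  }
  groups <- split(scores$ccm2, scores[[by]])
  data.frame(group = names(groups), n = lengths(groups),
             median_ccm2 = vapply(groups, stats::median, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
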