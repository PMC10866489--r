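#' Load and vet a species occurrence table
#'
#' Applies the dataset vetting rules used throughout the pipeline:
#'
#' 1. only species-level occurrences are retained (`accepted_rank ==
#'    "species"`) — the phylogenetic matrices use species as terminals;
#' 2. material assigned to extant species is dropped (`is_extant`), since an
#'    extant taxon's morphology is fully observable regardless of its
#'    fossils;
#' 3. duplicate rows for one species are collapsed: specimen and locality
#'    counts are summed, categorical labels are reconciled to the first-seen
#'    value (conflicts are logged, not errors).
#'
#' Every drop and merge is recorded in the vetting log attached to the
#' result.
#'
#' @param table a data.frame, or path to a CSV, with columns
#'   `accepted_name`, `accepted_rank`, `is_extant`, `taxon_group`,
#'   `landmass`, `formation`, `environment`, `lagerstatte_class`, `max_ma`,
#'   `min_ma`, `n_specimens`, `n_localities`, `limbless`.
#' @param landmasses,environments,classes,groups controlled vocabularies
#'   used to validate labels.
#' @return An `occurrenceDataset`: data.frame with one row per vetted
#'   species (first column `species_id`), carrying a `vetting_log` attribute
#'   (data.frame: `species`, `rule`, `detail`).
#' @export
loadAndVet <- function(table,
                       landmasses = landmassVocabulary(),
                       environments = environmentVocabulary(),
                       classes = lagerstatteClasses(),
                       groups = taxonGroups()) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  need <- c("accepted_name", "accepted_rank", "is_extant", "taxon_group",
            "landmass", "formation", "environment", "lagerstatte_class",
            "max_ma", "min_ma", "n_specimens", "n_localities", "limbless")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("occurrence table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  log <- data.frame(species = character(0), rule = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  add_log <- function(sp, rule, detail) {
    rbind(log, data.frame(species = sp, rule = rule, detail = detail,
                          stringsAsFactors = FALSE))
  }

  drop_rank <- table$accepted_rank != "species"
  for (sp in table$accepted_name[drop_rank]) {
    log <- add_log(sp, "rank", "not species-level")
  }
  table <- table[!drop_rank, , drop = FALSE]

  drop_extant <- as.logical(table$is_extant)
  for (sp in table$accepted_name[drop_extant]) {
    log <- add_log(sp, "extant", "assigned to extant species")
  }
  table <- table[!drop_extant, , drop = FALSE]

  out <- NULL
  if (nrow(table)) {
    label_cols <- c("taxon_group", "landmass", "formation", "environment",
                    "lagerstatte_class", "limbless")
    pieces <- split(table, factor(table$accepted_name,
                                  levels = unique(table$accepted_name)))
    rows <- lapply(pieces, function(sub) {
      first <- sub[1, , drop = FALSE]
      if (nrow(sub) > 1L) {
        for (col in label_cols) {
          if (length(unique(sub[[col]])) > 1L) {
            log <<- add_log(first$accepted_name, "merge_conflict",
                            paste0(col, ": kept '", first[[col]], "'"))
          }
        }
        log <<- add_log(first$accepted_name, "merge",
                        paste0("collapsed ", nrow(sub), " rows"))
        first$n_specimens <- sum(sub$n_specimens)
        first$n_localities <- sum(sub$n_localities)
        first$max_ma <- max(sub$max_ma)
        first$min_ma <- min(sub$min_ma)
      }
      first
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  } else {
    out <- table
  }

  if (nrow(out)) {
    check_labels(out$landmass, landmasses, "landmass")
    check_labels(out$environment, environments, "environment")
    check_labels(out$lagerstatte_class, classes, "lagerstatte class")
    check_labels(out$taxon_group, groups, "taxon group")
    if (any(out$max_ma < out$min_ma)) {
      stop("max_ma < min_ma for species: ",
           paste(out$accepted_name[out$max_ma < out$min_ma], collapse = ", "),
           call. = FALSE)
    }
    out$is_extant <- as.logical(out$is_extant)
    out$limbless <- as.logical(out$limbless)
  }
  names(out)[names(out) == "accepted_name"] <- "species_id"
  structure(out, vetting_log = log,
            class = c("occurrenceDataset", "data.frame"))
}

#' Vetting log of an occurrence dataset
#' @param dataset an `occurrenceDataset`.
#' @return data.frame of drop/merge decisions (`species`, `rule`, `detail`).
#' @export
vettingLog <- function(dataset) {
  attr(dataset, "vetting_log")
}

#' @export
print.occurrenceDataset <- function(x, ...) {
  cat("occurrenceDataset:", nrow(x), "species,",
      sum(x$n_specimens), "specimens,", nrow(vettingLog(x)),
      "vetting log entries\n")
  if (nrow(x)) {
    cat("taxon groups:",
        paste(names(table(x$taxon_group)), table(x$taxon_group),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partition an occurrence dataset by a grouping key
#'
#' @param dataset an `occurrenceDataset`.
#' @param key one of `"landmass"`, `"environment"`, `"unit"`,
#'   `"lagerstatte_class"`, `"taxon_group"`.
#' @return A `groupPartition`: list with `key` and `groups` (named list of
#'   member species-id vectors). Group sizes sum to the dataset size.
#' @export
partitionBy <- function(dataset, key) {
  stopifnot(inherits(dataset, "occurrenceDataset"))
  cols <- c(landmass = "landmass", environment = "environment",
            unit = "formation", lagerstatte_class = "lagerstatte_class",
            taxon_group = "taxon_group")
  if (!key %in% names(cols)) {
    stop("unknown grouping key '", key, "'; use one of: ",
         paste(names(cols), collapse = ", "), call. = FALSE)
  }
  values <- dataset[[cols[[key]]]]
  groups <- split(dataset$species_id, factor(values, levels = unique(values)))
  structure(list(key = key, groups = groups,
                 exclusion_log = data.frame(group = character(0),
                                            size = integer(0),
                                            stringsAsFactors = FALSE)),
            class = "groupPartition")
}

#' @export
print.groupPartition <- function(x, ...) {
  cat("groupPartition by", x$key, "-", length(x$groups), "group(s):\n")
  sizes <- lengths(x$groups)
  print(sizes)
  if (nrow(x$exclusion_log)) {
    cat("excluded below threshold:",
        paste(x$exclusion_log$group, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Drop groups below a minimum sample size
#'
#' Small groups carry too little information for distribution comparison;
#' the pipeline's defaults follow the analysis configuration (6 species per
#' landmass, 17 per depositional environment).
#'
#' @param partition a `groupPartition`.
#' @param threshold minimum group size (>= 1).
#' @return A `groupPartition` retaining only groups with `>= threshold`
#'   members; dropped groups are appended to the `exclusion_log`.
#' @export
applyMinSample <- function(partition, threshold) {
  stopifnot(inherits(partition, "groupPartition"), threshold >= 1)
  sizes <- lengths(partition$groups)
  drop <- sizes < threshold
  excl <- rbind(partition$exclusion_log,
                data.frame(group = names(partition$groups)[drop],
                           size = unname(sizes[drop]),
                           stringsAsFactors = FALSE))
  structure(list(key = partition$key, groups = partition$groups[!drop],
                 exclusion_log = excl),
            class = "groupPartition")
}

#' Remove all species from given geologic units
#'
#' The leave-unit-out primitive: returns the dataset minus every species
#' whose formation is in `units`. The original dataset is untouched. A unit
#' label absent from the dataset is a logged warning, not an error.
#'
#' @param dataset an `occurrenceDataset`.
#' @param units non-empty character vector of formation labels (unit-set
#'   aliases such as Jehol resolve to formation pairs; see [unitAliases()]).
#' @return An `occurrenceDataset` without the units' species.
#' @export
subsetWithoutUnits <- function(dataset, units) {
  stopifnot(inherits(dataset, "occurrenceDataset"))
  units <- unique(as.character(units))
  if (!length(units)) stop("'units' must be non-empty", call. = FALSE)
  absent <- setdiff(units, dataset$formation)
  if (length(absent)) {
    warning("unit label(s) not present in dataset: ",
            paste(absent, collapse = ", "))
  }
  keep <- !(dataset$formation %in% units)
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, vetting_log = vettingLog(dataset),
            class = c("occurrenceDataset", "data.frame"))
}
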