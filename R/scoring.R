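#' Per-species preservation record
#'
#' The union of skeletal elements preserved across every specimen referred to
#' a fossil species. CCM2 is a species-level metric: a character counts as
#' scorable if any combination of the species' specimens exposes all of its
#' required elements, so the element union is the scoring input. Limbless
#' species (snakes, amphisbaenians, dibamids and kin) may not carry
#' limb/girdle elements.
#'
#' @param species_id species label.
#' @param elements character vector of preserved element labels (may be
#'   empty: a species known only from unscorable material).
#' @param limbless logical; `TRUE` for limbless lineages, which are scored
#'   against the reduced "true completeness" denominator.
#' @param n_specimens number of referred specimens (>= 1).
#' @param vocabulary element vocabulary used for validation.
#' @return An object of class `preservationRecord`.
#' @export
preservationRecord <- function(species_id, elements, limbless = FALSE,
                               n_specimens = 1L,
                               vocabulary = elementVocabulary()) {
  elements <- unique(as.character(elements))
  check_labels(elements, vocabulary$element, "element")
  if (!is.logical(limbless) || length(limbless) != 1L || is.na(limbless)) {
    stop("'limbless' must be TRUE or FALSE", call. = FALSE)
  }
  n_specimens <- as.integer(n_specimens)
  if (is.na(n_specimens) || n_specimens < 1L) {
    stop("'n_specimens' must be >= 1", call. = FALSE)
  }
  if (limbless) {
    part <- stats::setNames(vocabulary$partition, vocabulary$element)
    limb <- elements[part[elements] %in% limbPartitions()]
    if (length(limb)) {
      stop("limbless species '", species_id,
           "' records limb/girdle element(s): ",
           paste(limb, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(species_id = as.character(species_id), elements = elements,
                 limbless = limbless, n_specimens = n_specimens),
            class = "preservationRecord")
}

#' @export
print.preservationRecord <- function(x, ...) {
  cat("preservationRecord:", x$species_id, "-", length(x$elements),
      "elements over", x$n_specimens, "specimen(s)",
      if (x$limbless) "(limbless)" else "", "\n")
  invisible(x)
}

#' Pool per-specimen element sets into a species record
#'
#' @param specimens list (one entry per specimen) of preserved-element
#'   character vectors; at least one specimen.
#' @inheritParams preservationRecord
#' @return A `preservationRecord` whose elements are the union over
#'   specimens and whose `n_specimens` is `length(specimens)`.
#' @export
unionPreservation <- function(specimens, species_id, limbless = FALSE,
                              vocabulary = elementVocabulary()) {
  if (!is.list(specimens) || length(specimens) < 1L) {
    stop("'specimens' must be a non-empty list of element sets", call. = FALSE)
  }
  preservationRecord(species_id,
                     unique(unlist(specimens, use.names = FALSE)),
                     limbless = limbless, n_specimens = length(specimens),
                     vocabulary = vocabulary)
}

#' Applicable characters for a limbed or limbless species
#'
#' The denominator of CCM2. Limbed species are scored against all characters
#' in the map. Limbless species can never exhibit limb or girdle anatomy, so
#' every character requiring ANY element from the four limb/girdle partitions
#' is removed from their denominator ("true completeness"); a character
#' spanning a limb and a non-limb element can never be fully scored and is
#' also removed. With the shipped squamate map this yields 860 (limbed) and
#' 710 (limbless).
#'
#' @param map a `characterRegionMap`.
#' @param limbless logical scalar.
#' @return `applicableCharacters()`: integer vector of character ids;
#'   `applicableCount()`: its length.
#' @export
applicableCharacters <- function(map, limbless = FALSE) {
  stopifnot(inherits(map, "characterRegionMap"))
  ids <- map$characters$character_id
  if (!limbless) return(ids)
  parts <- characterPartitions(map)
  keep <- !vapply(parts, function(p) any(p %in% limbPartitions()), logical(1))
  ids[keep]
}

#' @rdname applicableCharacters
#' @export
applicableCount <- function(map, limbless = FALSE) {
  length(applicableCharacters(map, limbless))
}

#' Score one species' character completeness (CCM2)
#'
#' CCM2 is the percentage of applicable phylogenetic characters scorable
#' from the elements preserved across all specimens of the species:
#' `100 * scorable / applicable`, where a character is scorable iff all its
#' required elements are in the species' preserved-element union, and the
#' applicable set is the full map (limbed) or the limb-free subset
#' (limbless; see [applicableCharacters()]).
#'
#' @param map a `characterRegionMap`.
#' @param record a `preservationRecord`.
#' @return An object of class `ccm2Score`: list with `species_id`,
#'   `scorable`, `applicable`, `ccm2` (percentage, full precision),
#'   `limbless`, `n_specimens`.
#' @export
scoreSpeciesCCM2 <- function(map, record) {
  stopifnot(inherits(map, "characterRegionMap"),
            inherits(record, "preservationRecord"))
  if (nrow(map$vocabulary) == 0L) {
    stop("configuration error: empty element vocabulary", call. = FALSE)
  }
  check_labels(record$elements, map$vocabulary$element, "element")
  applicable <- applicableCharacters(map, record$limbless)
  scorable <- intersect(charactersForElements(map, record$elements),
                        applicable)
  if (length(applicable) == 0L) {
    stop("no applicable characters for species '", record$species_id, "'",
         call. = FALSE)
  }
  structure(list(species_id = record$species_id,
                 scorable = length(scorable),
                 applicable = length(applicable),
                 ccm2 = 100 * length(scorable) / length(applicable),
                 limbless = record$limbless,
                 n_specimens = record$n_specimens),
            class = "ccm2Score")
}

#' @export
print.ccm2Score <- function(x, ...) {
  cat(sprintf("ccm2Score: %s  %d/%d characters = %.2f%%%s\n", x$species_id,
              x$scorable, x$applicable, x$ccm2,
              if (x$limbless) " (true completeness, limbless)" else ""))
  invisible(x)
}

#' Score many species at once
#'
#' @param map a `characterRegionMap`.
#' @param records list of `preservationRecord`s.
#' @return data.frame with one row per species: `species_id`, `scorable`,
#'   `applicable`, `ccm2`, `limbless`, `n_specimens`.
#' @export
scoreCCM2 <- function(map, records) {
  stopifnot(is.list(records))
  rows <- lapply(records, function(r) {
    s <- scoreSpeciesCCM2(map, r)
    data.frame(species_id = s$species_id, scorable = s$scorable,
               applicable = s$applicable, ccm2 = s$ccm2,
               limbless = s$limbless, n_specimens = s$n_specimens,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read per-specimen element records from CSV
#'
#' Expected columns: `species_id`, `specimen_id`, `elements`
#' (semicolon-separated), `limbless` (logical, constant within species).
#' Specimens are pooled per species via [unionPreservation()].
#'
#' @param path CSV path.
#' @inheritParams preservationRecord
#' @return List of `preservationRecord`s, one per species, in first-seen
#'   species order.
#' @export
readPreservationRecords <- function(path, vocabulary = elementVocabulary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "specimen_id", "elements", "limbless")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("specimen table ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sp <- unique(df$species_id)
  lapply(sp, function(s) {
    sub <- df[df$species_id == s, ]
    if (length(unique(sub$limbless)) != 1L) {
      stop("species '", s, "' has inconsistent limbless flags", call. = FALSE)
    }
    sets <- lapply(strsplit(sub$elements, ";", fixed = TRUE), function(e) {
      e <- trimws(e)
      e[nzchar(e)]
    })
    unionPreservation(sets, s, limbless = as.logical(sub$limbless[1]),
                      vocabulary = vocabulary)
  })
}

#' Convert skeletal completeness (SCM2) to character completeness (CCM2)
#'
#' Skeletal completeness assessments report, per body partition, the
#' proportion of the skeleton preserved. Weighting those proportions by the
#' number of phylogenetic characters each partition carries converts them to
#' the character scale:
#' `100 * sum(p_r * c_r) / sum(c_r)`.
#' A scalar proportion is broadcast to all partitions with a warning (no
#' partition-level resolution was available).
#'
#' @param proportions numeric vector of per-partition preserved proportions
#'   in `[0, 1]` (or a single scalar to broadcast).
#' @param counts integer vector of per-partition character counts; must sum
#'   to the map's character total when derived from a map (see
#'   [regionDensity()]).
#' @return CCM2 percentage.
#' @export
convertSCM2toCCM2 <- function(proportions, counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("partition character counts must be non-negative and sum > 0",
         call. = FALSE)
  }
  if (length(proportions) == 1L && length(counts) > 1L) {
    warning("scalar SCM2 broadcast to all ", length(counts), " partitions")
    proportions <- rep(proportions, length(counts))
  }
  if (length(proportions) != length(counts)) {
    stop("'proportions' and 'counts' lengths differ", call. = FALSE)
  }
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  100 * sum(proportions * counts) / sum(counts)
}

#' Character counts per body partition
#'
#' Tallies how many characters each partition carries, assigning a character
#' to the partition of its first required element (characters spanning
#' partitions are rare and the counts must sum to the character total).
#'
#' @param map a `characterRegionMap`.
#' @return Named integer vector over [ccmPartitions()] (zero-count
#'   partitions included).
#' @export
regionDensity <- function(map) {
  stopifnot(inherits(map, "characterRegionMap"))
  first <- vapply(characterPartitions(map), `[`, character(1), 1L)
  counts <- table(factor(first, levels = ccmPartitions()))
  stats::setNames(as.integer(counts), names(counts))
}
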