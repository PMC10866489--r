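#' Construct a character-to-region map
#'
#' A character region map ties each discrete morphological character of a
#' phylogenetic matrix to the skeletal element(s) that must be preserved for
#' the character to be scorable. A character is scorable if and only if ALL
#' of its required elements are preserved: ratio and articulation characters
#' reference several elements and cannot be scored from a subset. Elements
#' carry a body-partition label (skull, mandible, axial, the four limb/girdle
#' partitions, integument) through the controlled element vocabulary.
#'
#' @param elements list of character vectors, one per character (1-based ids
#'   in list order, following NEXUS conventions), or a character vector of
#'   semicolon-separated element labels.
#' @param source character scalar or vector tagging the parent matrix of each
#'   character (e.g. which of two combined datasets it came from).
#' @param vocabulary element vocabulary data.frame (`element`, `partition`).
#' @return An object of class `characterRegionMap`: a list with
#'   `characters` (data.frame: `character_id`, `source`, plus a list column
#'   `elements`) and `vocabulary`.
#' @examples
#' m <- characterRegionMap(list("frontal", "femur", c("frontal", "femur")))
#' nCharacters(m)
#' @export
characterRegionMap <- function(elements, source = "A",
                               vocabulary = elementVocabulary()) {
  if (is.character(elements)) {
    elements <- strsplit(elements, ";", fixed = TRUE)
    elements <- lapply(elements, trimws)
  }
  if (!is.list(elements) || length(elements) < 1L) {
    stop("'elements' must be a non-empty list of element sets", call. = FALSE)
  }
  elements <- lapply(elements, function(e) unique(as.character(e)))
  if (any(lengths(elements) == 0L)) {
    stop("every character must require at least one element", call. = FALSE)
  }
  check_labels(unlist(elements), vocabulary$element, "element")
  n <- length(elements)
  source <- rep_len(as.character(source), n)
  chars <- data.frame(character_id = seq_len(n), source = source,
                      stringsAsFactors = FALSE)
  chars$elements <- elements
  structure(list(characters = chars, vocabulary = vocabulary),
            class = "characterRegionMap")
}

#' @export
print.characterRegionMap <- function(x, ...) {
  parts <- characterPartitions(x)
  tab <- table(vapply(parts, `[`, character(1), 1L))
  cat("characterRegionMap:", nCharacters(x), "characters,",
      nrow(x$vocabulary), "elements in vocabulary\n")
  cat("characters per partition (by first required element):\n")
  print(tab)
  invisible(x)
}

#' Number of characters in a region map
#' @param map a `characterRegionMap`.
#' @return Integer character count.
#' @export
nCharacters <- function(map) {
  stopifnot(inherits(map, "characterRegionMap"))
  nrow(map$characters)
}

#' Partitions touched by each character
#'
#' @param map a `characterRegionMap`.
#' @return List (one entry per character) of the partition labels of the
#'   character's required elements.
#' @export
characterPartitions <- function(map) {
  stopifnot(inherits(map, "characterRegionMap"))
  part <- stats::setNames(map$vocabulary$partition, map$vocabulary$element)
  lapply(map$characters$elements, function(e) unname(part[e]))
}

#' Read a character-region map from CSV
#'
#' Expected columns: `character_id`, `source`, `required_elements`
#' (semicolon-separated element labels) and `partition` (the partition of the
#' character's leading element; checked for consistency with the vocabulary).
#'
#' @param path CSV path.
#' @inheritParams characterRegionMap
#' @return A `characterRegionMap`.
#' @export
readRegionMap <- function(path, vocabulary = elementVocabulary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("character_id", "source", "required_elements", "partition")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("region map ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$character_id), ]
  if (!identical(as.integer(df$character_id), seq_len(nrow(df)))) {
    stop("character_id must run 1..C without gaps in ", path, call. = FALSE)
  }
  map <- characterRegionMap(df$required_elements, source = df$source,
                            vocabulary = vocabulary)
  parts <- characterPartitions(map)
  bad <- which(!mapply(function(p, declared) declared %in% p,
                       parts, df$partition))
  if (length(bad)) {
    stop("declared partition inconsistent with required elements for character(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  map
}

#' Write a character-region map to CSV
#' @param map a `characterRegionMap`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRegionMap <- function(map, path) {
  stopifnot(inherits(map, "characterRegionMap"))
  parts <- characterPartitions(map)
  df <- data.frame(
    character_id = map$characters$character_id,
    source = map$characters$source,
    required_elements = vapply(map$characters$elements, paste,
                               character(1), collapse = ";"),
    partition = vapply(parts, `[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an overlap list
#'
#' Pairs of character ids judged equivalent between two matrices being
#' combined. Overlap removal is expert judgement, so the list is an explicit
#' input, never computed.
#'
#' @param path CSV with columns `id_a`, `id_b`.
#' @return data.frame with integer columns `id_a`, `id_b`.
#' @export
readOverlapList <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b") %in% names(df))) {
    stop("overlap list must have columns 'id_a' and 'id_b'", call. = FALSE)
  }
  data.frame(id_a = as.integer(df$id_a), id_b = as.integer(df$id_b))
}

#' Merge two character sets with an explicit overlap list
#'
#' Combines two character-region maps the way competing morphological
#' datasets are combined into one scoring set: characters judged equivalent
#' (the overlap list) are kept once, from the first map. The merged map is
#' renumbered 1..C and carries a provenance table mapping each merged id back
#' to (source map, original id).
#'
#' @param a,b `characterRegionMap` objects sharing a compatible vocabulary.
#' @param overlap data.frame with columns `id_a`, `id_b` (may be `NULL` or
#'   empty for disjoint sets). Each id may appear in at most one pair.
#' @return A `characterRegionMap` with `nCharacters(a) + nCharacters(b) -
#'   nrow(overlap)` characters and a `provenance` attribute
#'   (data.frame: `character_id`, `source_map`, `original_id`).
#' @export
mergeCharacterSets <- function(a, b, overlap = NULL) {
  stopifnot(inherits(a, "characterRegionMap"), inherits(b, "characterRegionMap"))
  if (is.null(overlap)) {
    overlap <- data.frame(id_a = integer(0), id_b = integer(0))
  }
  if (nrow(overlap)) {
    if (anyDuplicated(overlap$id_a) || anyDuplicated(overlap$id_b)) {
      stop("duplicate id in overlap list", call. = FALSE)
    }
    if (any(overlap$id_a < 1L | overlap$id_a > nCharacters(a)) ||
        any(overlap$id_b < 1L | overlap$id_b > nCharacters(b))) {
      stop("overlap pair references an id outside its matrix", call. = FALSE)
    }
  }
  vocab <- unique(rbind(a$vocabulary, b$vocabulary))
  if (anyDuplicated(vocab$element)) {
    stop("vocabularies disagree on a partition assignment", call. = FALSE)
  }
  keep_b <- setdiff(seq_len(nCharacters(b)), overlap$id_b)
  elements <- c(a$characters$elements, b$characters$elements[keep_b])
  source <- c(a$characters$source, b$characters$source[keep_b])
  merged <- characterRegionMap(elements, source = source, vocabulary = vocab)
  attr(merged, "provenance") <- data.frame(
    character_id = seq_along(elements),
    source_map = c(rep("a", nCharacters(a)), rep("b", length(keep_b))),
    original_id = c(seq_len(nCharacters(a)), keep_b)
  )
  merged
}

#' Characters scorable from a set of preserved elements
#'
#' Returns the ids of the characters whose full required element set is
#' contained in `elements`. Monotone: a larger preserved set can only add
#' characters.
#'
#' @param map a `characterRegionMap`.
#' @param elements character vector of preserved element labels (may be
#'   empty).
#' @return Integer vector of character ids.
#' @export
charactersForElements <- function(map, elements) {
  stopifnot(inherits(map, "characterRegionMap"))
  elements <- unique(as.character(elements))
  check_labels(elements, map$vocabulary$element, "element")
  ok <- vapply(map$characters$elements,
               function(req) all(req %in% elements), logical(1))
  map$characters$character_id[ok]
}
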