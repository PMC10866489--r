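#' Synthetic squamate character-region map (860 characters)
#'
#' A deterministic, synthetic reconstruction of the combined squamate scoring
#' set formed by merging two competing squamate morphological matrices and
#' removing overlapping characters. The character-by-character element
#' assignments of that combined set were never published; this map is built
#' to honour its published structural totals exactly:
#'
#' * 860 scorable characters in total;
#' * 150 characters on the limbs and limb girdles, so the limbless
#'   "true completeness" denominator is 710;
#' * over two-thirds of characters concentrated on the skull and mandibles
#'   (here 430 skull + 160 mandible = 590 of 860).
#'
#' Within each partition, characters cycle through the partition's elements
#' and each character requires a single element. Use it wherever the real
#' per-character assignments are not required, e.g. denominator logic and
#' simulation.
#'
#' @param vocabulary element vocabulary (`element`, `partition`).
#' @return A `characterRegionMap` with 860 characters.
#' @examples
#' m <- squamateCharacterMap()
#' nCharacters(m)                 # 860
#' applicableCount(m, limbless = TRUE)   # 710
#' @export
squamateCharacterMap <- function(vocabulary = elementVocabulary()) {
  counts <- c(skull = 430L, mandible = 160L, axial = 90L,
              pectoral_girdle = 30L, forelimb = 45L,
              pelvic_girdle = 30L, hindlimb = 45L, integument = 30L)
  stopifnot(sum(counts) == 860L)
  elements <- unlist(lapply(names(counts), function(p) {
    pool <- vocabulary$element[vocabulary$partition == p]
    if (!length(pool)) stop("vocabulary has no elements for partition ", p,
                            call. = FALSE)
    rep_len(pool, counts[[p]])
  }), use.names = FALSE)
  source <- rep_len(c("GEA", "SEA"), length(elements))
  characterRegionMap(as.list(elements), source = source,
                     vocabulary = vocabulary)
}
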