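#' Controlled vocabularies
#'
#' Body partitions, skeletal elements, landmasses, depositional environments,
#' lagerstaette classes and taxon groups are controlled vocabularies: every
#' label entering the pipeline is validated against them at load time, and an
#' unknown label is a hard error rather than a warning. Silent vocabulary
#' drift would corrupt the completeness denominators.
#'
#' @return `ccmPartitions()` returns the eight body-partition labels;
#'   `limbPartitions()` the four limb/girdle partitions excluded from the
#'   limbless ("true completeness") denominator; the other helpers return
#'   their label sets.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
ccmPartitions <- function() {
  c("skull", "mandible", "axial", "pectoral_girdle", "forelimb",
    "pelvic_girdle", "hindlimb", "integument")
}

#' @rdname vocabularies
#' @export
limbPartitions <- function() {
  c("pectoral_girdle", "forelimb", "pelvic_girdle", "hindlimb")
}

#' @rdname vocabularies
#' @export
landmassVocabulary <- function() {
  c("Asia", "North America", "Europe", "Africa", "South America",
    "Australasia", "India", "Madagascar", "Antarctica", "Caribbean")
}

#' @rdname vocabularies
#' @export
environmentVocabulary <- function() {
  c("aeolian", "lacustrine", "fluvial", "marine", "lagoonal",
    "cave_karst", "other")
}

#' @rdname vocabularies
#' @export
lagerstatteClasses <- function() {
  c("konservat", "konzentrat", "none")
}

#' @rdname vocabularies
#' @export
taxonGroups <- function() {
  c("non_avian_theropod", "mesozoic_bird", "squamate")
}

#' Skeletal element vocabulary
#'
#' Reads the element -> body-partition table shipped with the package (or a
#' user-supplied replacement with the same two columns). Every preserved
#' element in a specimen record and every required element in a character map
#' must appear here.
#'
#' @param path CSV with columns `element` and `partition`. Defaults to the
#'   packaged vocabulary.
#' @return A data.frame with columns `element`, `partition`.
#' @export
elementVocabulary <- function(path = system.file("extdata", "element_vocabulary.csv",
                                                 package = "fossilccm")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("element vocabulary file not found: ", path, call. = FALSE)
  }
  vocab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "partition")
  if (!all(need %in% names(vocab))) {
    stop("element vocabulary must have columns 'element' and 'partition'",
         call. = FALSE)
  }
  if (anyDuplicated(vocab$element)) {
    stop("duplicated element labels in vocabulary: ",
         paste(unique(vocab$element[duplicated(vocab$element)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(vocab$partition), ccmPartitions())
  if (length(bad)) {
    stop("unknown partition label(s) in vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vocab[, need]
}

#' Named geologic-unit aliases
#'
#' The Jehol Biota (Yixian + Jiufotang formations) and the Campanian Gobi
#' assemblage (Djadokhta + Baruungoyot formations) are treated as single
#' analytical units, so "remove Jehol" resolves to a formation set.
#'
#' @return Named list of character vectors of formation labels.
#' @export
unitAliases <- function() {
  list(jehol = c("Yixian", "Jiufotang"),
       gobi  = c("Djadokhta", "Baruungoyot"))
}

# internal: validate a label vector against a vocabulary
check_labels <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad)) {
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
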