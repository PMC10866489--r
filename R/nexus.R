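#' Read a NEXUS morphological character matrix
#'
#' Parses a CHARACTERS or DATA block of discrete character states. The file's
#' own declarations are authoritative and enforced: the returned matrix must
#' match the declared NTAX/NCHAR, and the MISSING / GAP symbols are taken
#' from the FORMAT line (defaulting to `?` and `-`). Matrix content is read
#' with \code{\link[ape]{read.nexus.data}}; the surrounding structural
#' validation (and line-numbered parse errors) is done here.
#'
#' @param path path to a NEXUS file.
#' @return An object of class `characterMatrix`: list with `taxa`,
#'   `n_characters`, `cells` (taxa x characters character matrix of state
#'   symbols), `missing` and `gap` symbols.
#' @export
readCharacterMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  up <- toupper(lines)
  begin <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(begin)) {
    stop("parse error: no DATA/CHARACTERS block found in ", path, call. = FALSE)
  }
  dim_line <- grep("DIMENSIONS", up)
  dim_line <- dim_line[dim_line > begin[1]][1]
  if (is.na(dim_line)) {
    stop("parse error at line ", begin[1], ": block has no DIMENSIONS line",
         call. = FALSE)
  }
  ntax <- regmatches(up[dim_line], regexpr("NTAX\\s*=\\s*[0-9]+", up[dim_line]))
  nchar_ <- regmatches(up[dim_line], regexpr("NCHAR\\s*=\\s*[0-9]+", up[dim_line]))
  if (!length(ntax) || !length(nchar_)) {
    stop("parse error at line ", dim_line,
         ": DIMENSIONS must declare NTAX and NCHAR", call. = FALSE)
  }
  ntax <- as.integer(sub(".*=\\s*", "", ntax))
  nchar_ <- as.integer(sub(".*=\\s*", "", nchar_))

  missing_sym <- "?"
  gap_sym <- "-"
  fmt_line <- grep("FORMAT", up)
  fmt_line <- fmt_line[fmt_line > begin[1]]
  if (length(fmt_line)) {
    fmt <- lines[fmt_line[1]]
    m <- regmatches(fmt, regexpr("[Mm][Ii][Ss][Ss][Ii][Nn][Gg]\\s*=\\s*\\S", fmt))
    if (length(m)) missing_sym <- substr(m, nchar(m), nchar(m))
    g <- regmatches(fmt, regexpr("[Gg][Aa][Pp]\\s*=\\s*\\S", fmt))
    if (length(g)) gap_sym <- substr(g, nchar(g), nchar(g))
  }

  dat <- tryCatch(ape::read.nexus.data(path), error = function(e) {
    stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (length(dat) != ntax) {
    stop("structural error: matrix has ", length(dat),
         " taxa but DIMENSIONS declares NTAX=", ntax, call. = FALSE)
  }
  bad <- which(lengths(dat) != nchar_)
  if (length(bad)) {
    stop("structural error: taxon '", names(dat)[bad[1]], "' has ",
         lengths(dat)[bad[1]], " characters but DIMENSIONS declares NCHAR=",
         nchar_, call. = FALSE)
  }
  if (anyDuplicated(names(dat))) {
    stop("structural error: duplicated taxon labels", call. = FALSE)
  }
  cells <- do.call(rbind, dat)
  rownames(cells) <- names(dat)
  structure(list(taxa = names(dat), n_characters = nchar_, cells = cells,
                 missing = missing_sym, gap = gap_sym),
            class = "characterMatrix")
}

#' @export
print.characterMatrix <- function(x, ...) {
  cat("characterMatrix:", length(x$taxa), "taxa x", x$n_characters,
      "characters\n")
  cat("missing symbol '", x$missing, "', gap symbol '", x$gap, "'; ",
      countMissing(x), " missing cells\n", sep = "")
  invisible(x)
}

#' Count missing cells in a character matrix
#' @param x a `characterMatrix`.
#' @return Number of cells equal to the matrix's MISSING symbol.
#' @export
countMissing <- function(x) {
  stopifnot(inherits(x, "characterMatrix"))
  sum(x$cells == x$missing)
}

#' Write a character matrix to NEXUS
#'
#' Writes a standard-datatype DATA block via
#' \code{\link[ape]{write.nexus.data}}; re-reading reproduces taxa,
#' dimensions and cell content exactly.
#'
#' @param x a `characterMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCharacterMatrix <- function(x, path) {
  stopifnot(inherits(x, "characterMatrix"))
  dat <- stats::setNames(lapply(seq_along(x$taxa), function(i) x$cells[i, ]),
                         x$taxa)
  ape::write.nexus.data(dat, path, format = "standard",
                        missing = x$missing, gap = x$gap)
  invisible(path)
}
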