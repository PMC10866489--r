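#' Leave-unit-out comparison of completeness distributions
#'
#' Quantifies the lagerstaetten effect of a geologic unit (or unit set, e.g.
#' the Jehol formation pair) on the completeness distribution of a scope:
#' the full sample of CCM2 scores for the scope (optionally restricted to a
#' landmass and/or taxon group) is compared against the same sample with the
#' unit's species removed. By default the test is full-vs-reduced, mirroring
#' the with/without panels of the analysis; `compare = "unit_vs_rest"`
#' contrasts the unit's species against everything else instead.
#'
#' @param scores data.frame of species scores (`species_id`, `ccm2`), as
#'   returned by [scoreCCM2()].
#' @param dataset an `occurrenceDataset` providing unit / landmass / group
#'   labels.
#' @param units character vector of formation labels to remove.
#' @param scope optional landmass label restricting the sample (e.g.
#'   `"Asia"`); `NULL` for global.
#' @param group optional taxon-group label restricting the sample.
#' @param alpha base significance level.
#' @param m family size the comparison belongs to (for Bonferroni
#'   adjustment; default 1 = standalone).
#' @param compare `"full_vs_reduced"` (default) or `"unit_vs_rest"`.
#' @return A `leaveOutResult`: list with `units`, `scope`, `group`,
#'   `n_full`, `n_reduced`, `n_removed`, `median_full`, `median_reduced`,
#'   `comparison` (a `comparisonResult`), `alpha_adjusted`, `sig_mw`,
#'   `sig_ks`, `compare`.
#' @export
leaveUnitOut <- function(scores, dataset, units, scope = NULL, group = NULL,
                         alpha = 0.05, m = 1L,
                         compare = c("full_vs_reduced", "unit_vs_rest")) {
  compare <- match.arg(compare)
  stopifnot(inherits(dataset, "occurrenceDataset"),
            all(c("species_id", "ccm2") %in% names(scores)))
  sel <- rep(TRUE, nrow(dataset))
  if (!is.null(scope)) sel <- sel & dataset$landmass == scope
  if (!is.null(group)) sel <- sel & dataset$taxon_group == group
  pool <- dataset[sel, , drop = FALSE]
  if (!nrow(pool)) {
    stop("scope/group selection matches no species", call. = FALSE)
  }
  sc <- stats::setNames(scores$ccm2, scores$species_id)
  miss <- setdiff(pool$species_id, names(sc))
  if (length(miss)) {
    stop("no CCM2 score for species: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  in_unit <- pool$formation %in% units
  full <- unname(sc[pool$species_id])
  reduced <- unname(sc[pool$species_id[!in_unit]])
  removed <- sum(in_unit)
  if (!length(reduced)) {
    stop("removing the unit(s) empties the sample", call. = FALSE)
  }
  alpha_adj <- alpha / m
  cmp <- if (removed == 0L) {
    NULL  # nothing removed: distributions identical, no test to run
  } else if (compare == "full_vs_reduced") {
    comparePair(full, reduced, c("full", "reduced"))
  } else {
    comparePair(unname(sc[pool$species_id[in_unit]]), reduced,
                c("unit", "rest"))
  }
  structure(list(units = units, scope = scope, group = group,
                 n_full = length(full), n_reduced = length(reduced),
                 n_removed = removed,
                 median_full = stats::median(full),
                 median_reduced = stats::median(reduced),
                 comparison = cmp, alpha = alpha, alpha_adjusted = alpha_adj,
                 sig_mw = if (is.null(cmp)) FALSE else cmp$p_mw < alpha_adj,
                 sig_ks = if (is.null(cmp)) FALSE else cmp$p_ks < alpha_adj,
                 compare = compare),
            class = "leaveOutResult")
}

#' @export
print.leaveOutResult <- function(x, ...) {
  cat(sprintf(
    "leaveOutResult: remove {%s}%s%s\n",
    paste(x$units, collapse = ", "),
    if (!is.null(x$scope)) paste0(" within ", x$scope) else " (global)",
    if (!is.null(x$group)) paste0(", ", x$group) else ""))
  cat(sprintf("  n %d -> %d (removed %d); median %.2f -> %.2f\n",
              x$n_full, x$n_reduced, x$n_removed,
              x$median_full, x$median_reduced))
  if (!is.null(x$comparison)) {
    cat(sprintf("  MW p=%.4g%s  KS p=%.4g%s  (adjusted alpha %.3g)\n",
                x$comparison$p_mw, if (x$sig_mw) "*" else "",
                x$comparison$p_ks, if (x$sig_ks) "*" else "",
                x$alpha_adjusted))
  }
  invisible(x)
}

#' Representation of a unit's taxa in a phylogenetic matrix
#'
#' How much of a phylogenetic analysis' taxon sample derives from one
#' exceptionally preserving unit: the percentage of the matrix's fossil
#' terminals drawn from the unit, the number of distinct families those
#' terminals represent, and (since some panels may count all terminals) the
#' percentage over all terminals as well.
#'
#' @param matrix_taxa data.frame with columns `taxon`, `is_fossil`
#'   (logical), `family`; taxa must be unique.
#' @param unit_members character vector of taxa derived from the unit. A
#'   member absent from the matrix contributes nothing and is logged in the
#'   result.
#' @param name matrix name (e.g. `"TWiG"`).
#' @return A `matrixRepresentation`: list with `name`, `n_taxa`,
#'   `n_fossil`, `n_from_unit`, `percent_fossil`, `percent_all`,
#'   `n_families`, `families`, `absent_members`.
#' @export
matrixRepresentation <- function(matrix_taxa, unit_members, name = "matrix") {
  need <- c("taxon", "is_fossil", "family")
  miss <- setdiff(need, names(matrix_taxa))
  if (length(miss)) {
    stop("matrix taxon table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(matrix_taxa$taxon)) {
    stop("matrix taxa must be unique", call. = FALSE)
  }
  unit_members <- unique(as.character(unit_members))
  absent <- setdiff(unit_members, matrix_taxa$taxon)
  fossil <- matrix_taxa[as.logical(matrix_taxa$is_fossil), , drop = FALSE]
  hit <- fossil[fossil$taxon %in% unit_members, , drop = FALSE]
  n_fossil <- nrow(fossil)
  fams <- sort(unique(hit$family))
  structure(list(name = name,
                 n_taxa = nrow(matrix_taxa),
                 n_fossil = n_fossil,
                 n_from_unit = nrow(hit),
                 percent_fossil = if (n_fossil) 100 * nrow(hit) / n_fossil else 0,
                 percent_all = if (nrow(matrix_taxa))
                   100 * nrow(hit) / nrow(matrix_taxa) else 0,
                 n_families = length(fams), families = fams,
                 absent_members = absent),
            class = "matrixRepresentation")
}

#' @export
print.matrixRepresentation <- function(x, ...) {
  cat(sprintf(
    "matrixRepresentation: %s - %d of %d fossil terminals (%.2f%%) from unit, %d families\n",
    x$name, x$n_from_unit, x$n_fossil, x$percent_fossil, x$n_families))
  if (length(x$absent_members)) {
    cat("  unit members not in matrix:",
        paste(x$absent_members, collapse = ", "), "\n")
  }
  invisible(x)
}
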