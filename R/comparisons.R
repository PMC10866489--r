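#' Violin-ready distribution summary
#'
#' The numeric summary behind a violin panel: median, interquartile range,
#' and the central 95% data interval (2.5th and 97.5th percentiles). The
#' "95% interval" is deliberately a data interval, not a standard-error
#' band; the choice is recorded in the result so downstream output is
#' auditable. Quantiles use linear interpolation between order statistics
#' (type 7).
#'
#' @param scores numeric vector of CCM2 percentages (n >= 1).
#' @param label group label.
#' @return A `distributionSummary`: list with `label`, `n`, `median`, `q1`,
#'   `q3`, `lo95`, `hi95`, `interval_type` (`"central 95% data interval"`)
#'   and the full sorted `sample`.
#' @export
summarizeDistribution <- function(scores, label = "group") {
  scores <- as.numeric(scores)
  if (!length(scores) || anyNA(scores)) {
    stop("'scores' must be non-empty and NA-free", call. = FALSE)
  }
  q <- stats::quantile(scores, c(0.025, 0.25, 0.5, 0.75, 0.975),
                       type = 7, names = FALSE)
  structure(list(label = label, n = length(scores), median = q[3],
                 q1 = q[2], q3 = q[4], lo95 = q[1], hi95 = q[5],
                 interval_type = "central 95% data interval",
                 sample = sort(scores)),
            class = "distributionSummary")
}

#' @export
print.distributionSummary <- function(x, ...) {
  cat(sprintf(
    "distributionSummary: %s  n=%d  median=%.2f  IQR=[%.2f, %.2f]  95%%=[%.2f, %.2f]\n",
    x$label, x$n, x$median, x$q1, x$q3, x$lo95, x$hi95))
  invisible(x)
}

#' Two-sample Mann-Whitney U comparison
#'
#' Two-sided Mann-Whitney U test of a location difference between two CCM2
#' samples, via [stats::wilcox.test()]. The exact null distribution is used
#' when `n_x * n_y <= 400` and there are no ties (exact enumeration over
#' rank assignments); otherwise the normal approximation with tie and
#' continuity corrections. When both routes are computable both p-values are
#' reported; the `method` tag records which is authoritative.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param labels length-2 character vector of group labels.
#' @return A `comparisonResult`: list with `label_x`, `label_y`, `n_x`,
#'   `n_y`, `U` (statistic for `x`), `p_mw`, `p_mw_exact`, `p_mw_approx`,
#'   `mw_method` (`"exact"`/`"approximate"`), and `NA` KS fields.
#' @export
mannWhitney <- function(x, y, labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(c(x, y))) {
    stop("samples must be non-empty and NA-free", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  ties <- any(duplicated(c(x, y)))
  use_exact <- (nx * ny <= 400) && !ties
  # exact p also reported alongside the approximation while cheap to compute
  p_exact <- if (!ties && nx * ny <= 2500) {
    stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
  } else NA_real_
  approx <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  U <- unname(suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE)$statistic))
  structure(list(label_x = labels[1], label_y = labels[2],
                 n_x = nx, n_y = ny, U = U,
                 p_mw = if (use_exact) p_exact else approx$p.value,
                 p_mw_exact = p_exact, p_mw_approx = approx$p.value,
                 mw_method = if (use_exact) "exact" else "approximate",
                 D = NA_real_, p_ks = NA_real_, ks_method = NA_character_),
            class = "comparisonResult")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided KS test of a difference in distribution shape:
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p-value at effective
#' sample size `n_x n_y / (n_x + n_y)`, via [stats::ks.test()] with
#' `exact = FALSE`. CCM2 samples routinely contain ties (many species share
#' a completeness score), which the asymptotic path tolerates.
#'
#' @inheritParams mannWhitney
#' @return A `comparisonResult` with `D`, `p_ks`, `ks_method =
#'   "approximate"` filled in and `NA` Mann-Whitney fields.
#' @export
ksTwoSample <- function(x, y, labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(c(x, y))) {
    stop("samples must be non-empty and NA-free", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(label_x = labels[1], label_y = labels[2],
                 n_x = length(x), n_y = length(y), U = NA_real_,
                 p_mw = NA_real_, p_mw_exact = NA_real_,
                 p_mw_approx = NA_real_, mw_method = NA_character_,
                 D = unname(kt$statistic), p_ks = kt$p.value,
                 ks_method = "approximate"),
            class = "comparisonResult")
}

#' Both two-sample tests on one pair
#' @inheritParams mannWhitney
#' @return A `comparisonResult` with both the Mann-Whitney and KS fields
#'   filled.
#' @export
comparePair <- function(x, y, labels = c("x", "y")) {
  mw <- mannWhitney(x, y, labels)
  ks <- ksTwoSample(x, y, labels)
  mw$D <- ks$D; mw$p_ks <- ks$p_ks; mw$ks_method <- ks$ks_method
  mw
}

#' @export
print.comparisonResult <- function(x, ...) {
  cat(sprintf("comparisonResult: %s (n=%d) vs %s (n=%d)\n",
              x$label_x, x$n_x, x$label_y, x$n_y))
  if (!is.na(x$U)) {
    cat(sprintf("  Mann-Whitney U=%.1f  p=%.5g (%s)\n", x$U, x$p_mw,
                x$mw_method))
  }
  if (!is.na(x$D)) {
    cat(sprintf("  Kolmogorov-Smirnov D=%.4f  p=%.5g (%s)\n", x$D, x$p_ks,
                x$ks_method))
  }
  invisible(x)
}

#' Run a pairwise comparison family with Bonferroni correction
#'
#' Runs both two-sample tests on every pair of groups in one results panel
#' (e.g. all pairwise landmass comparisons for one taxon group). The family
#' size `m = choose(k, 2)` sets the Bonferroni-adjusted significance level
#' `alpha / m`; each test's p-value is flagged against it. Families are one
#' panel and are never pooled across panels.
#'
#' @param groups named list (>= 2 entries) of numeric score vectors, or a
#'   list of `(label, scores)` pairs.
#' @param alpha base significance level (default 0.05).
#' @return A `comparisonFamily`: data.frame with one row per pair (`label_x`,
#'   `label_y`, `n_x`, `n_y`, `U`, `p_mw`, `mw_method`, `D`, `p_ks`,
#'   `ks_method`, `sig_mw`, `sig_ks`), with attributes `m`, `alpha`,
#'   `alpha_adjusted`.
#' @export
runFamily <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a fully named list", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "),
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  labs <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  alpha_adj <- alpha / m
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    r <- comparePair(groups[[i1]], groups[[i2]], c(labs[i1], labs[i2]))
    data.frame(label_x = r$label_x, label_y = r$label_y,
               n_x = r$n_x, n_y = r$n_y, U = r$U, p_mw = r$p_mw,
               mw_method = r$mw_method, D = r$D, p_ks = r$p_ks,
               ks_method = r$ks_method,
               sig_mw = r$p_mw < alpha_adj, sig_ks = r$p_ks < alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, m = m, alpha = alpha, alpha_adjusted = alpha_adj,
            class = c("comparisonFamily", "data.frame"))
}

#' @export
print.comparisonFamily <- function(x, ...) {
  cat(sprintf("comparisonFamily: m=%d comparisons, alpha=%.3g (adjusted %.3g)\n",
              attr(x, "m"), attr(x, "alpha"), attr(x, "alpha_adjusted")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Export a comparison family to CSV and JSON
#' @param family a `comparisonFamily`.
#' @param stem output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
writeComparisonFamily <- function(family, stem) {
  stopifnot(inherits(family, "comparisonFamily"))
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  df <- as.data.frame(family)
  df$m <- attr(family, "m")
  df$alpha_adjusted <- attr(family, "alpha_adjusted")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(list(m = attr(family, "m"),
                            alpha = attr(family, "alpha"),
                            alpha_adjusted = attr(family, "alpha_adjusted"),
                            comparisons = df),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
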