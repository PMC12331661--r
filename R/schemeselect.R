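#' Histogram of terminal genotype values per cross and scheme
#'
#' Bins all terminal lines on one global grid anchored at 0 with half-open
#' bins `[lo, hi)`, and counts lines per (cross, scheme, bin). The pooled
#' distribution over all combinations is kept alongside.
#'
#' @param results List of `scheme_result` objects (or a flat line table from
#'   [scheme_lines()]).
#' @param bin_width Bin width in trait units (> 0). The default of 3 matches
#'   the granularity at which count-like pod traits are usually tabulated.
#' @return List of class `gv_histogram`: `bin_width`, `breaks`, `counts`
#'   (`cross_id`, `scheme_id`, `bin_lo`, `bin_hi`, `n`; occupied bins only),
#'   `pooled` (`bin_lo`, `bin_hi`, `n`), `n_lines`.
#' @export
gv_histogram <- function(results, bin_width = 3) {
  if (bin_width <= 0) stop("bin_width must be positive")
  lines <- if (is.data.frame(results)) results else scheme_lines(results)
  if (nrow(lines) == 0) stop("no lines to bin")
  k <- floor(lines$gv / bin_width)
  kr <- range(k)
  breaks <- bin_width * seq(kr[1], kr[2] + 1)
  cnt <- stats::aggregate(list(n = rep(1L, nrow(lines))),
                          by = list(cross_id = lines$cross_id,
                                    scheme_id = lines$scheme_id,
                                    bin_lo = k * bin_width),
                          FUN = sum)
  cnt$bin_hi <- cnt$bin_lo + bin_width
  cnt <- cnt[order(cnt$cross_id, cnt$scheme_id, cnt$bin_lo),
             c("cross_id", "scheme_id", "bin_lo", "bin_hi", "n")]
  rownames(cnt) <- NULL
  pooled <- stats::aggregate(list(n = cnt$n), by = list(bin_lo = cnt$bin_lo),
                             FUN = sum)
  pooled$bin_hi <- pooled$bin_lo + bin_width
  pooled <- pooled[order(pooled$bin_lo), c("bin_lo", "bin_hi", "n")]
  rownames(pooled) <- NULL
  structure(list(bin_width = bin_width, breaks = breaks, counts = cnt,
                 pooled = pooled, n_lines = nrow(lines)),
            class = "gv_histogram")
}

#' Select cross-by-scheme combinations in the top two genotype-value intervals
#'
#' Identifies the two highest occupied bins of the pooled genotype-value
#' distribution and selects every (cross, scheme) combination with at least
#' one terminal line in them — the "highest two intervals" nomination rule.
#' Bin-boundary ties follow the half-open `[lo, hi)` convention. If all mass
#' sits in a single bin the report is flagged degenerate and that bin's
#' members are returned.
#'
#' @param hist A [gv_histogram()].
#' @return List of class `selection_report`: `rule`, `bins` (the selected
#'   intervals), `selected` (`cross_id`, `scheme_id`, `n_lines_in_top_bins`,
#'   `max_gv` if available), `degenerate`.
#' @export
select_top_intervals <- function(hist) {
  stopifnot(inherits(hist, "gv_histogram"))
  occ <- hist$pooled[hist$pooled$n > 0, , drop = FALSE]
  degenerate <- nrow(occ) < 2
  top <- utils::tail(occ[order(occ$bin_lo), ], 2)
  in_top <- hist$counts[hist$counts$bin_lo %in% top$bin_lo, , drop = FALSE]
  sel <- stats::aggregate(list(n_lines_in_top_bins = in_top$n),
                          by = list(cross_id = in_top$cross_id,
                                    scheme_id = in_top$scheme_id),
                          FUN = sum)
  sel <- sel[order(sel$cross_id, sel$scheme_id), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(rule = "top-two-occupied-intervals",
                 bin_width = hist$bin_width,
                 bins = top, selected = sel, degenerate = degenerate),
            class = "selection_report")
}

#' Select combinations meeting a breeding-goal threshold
#'
#' Nominates every (cross, scheme) combination with at least `k` terminal
#' lines whose genotype value strictly exceeds `goal` ("over" the goal).
#'
#' @param results List of `scheme_result` objects (or a [scheme_lines()]
#'   table).
#' @param goal Breeding-goal threshold in trait units.
#' @param k Minimum number of qualifying lines (default 1).
#' @return List of class `selection_report` with `selected` rows
#'   (`cross_id`, `scheme_id`, `n_lines_over_goal`, `max_gv`).
#' @export
apply_breeding_goal <- function(results, goal, k = 1L) {
  if (!is.finite(goal)) stop("goal must be finite")
  lines <- if (is.data.frame(results)) results else scheme_lines(results)
  combo <- paste(lines$cross_id, lines$scheme_id, sep = "\r")
  over <- tapply(lines$gv > goal, combo, sum)
  mx <- tapply(lines$gv, combo, max)
  keep <- names(over)[over >= k]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  sel <- data.frame(cross_id = vapply(parts, `[`, "", 1),
                    scheme_id = vapply(parts, `[`, "", 2),
                    n_lines_over_goal = as.integer(over[keep]),
                    max_gv = as.numeric(mx[keep]),
                    stringsAsFactors = FALSE)
  sel <- sel[order(sel$cross_id, sel$scheme_id), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(rule = "goal-threshold", goal = goal, k = as.integer(k),
                 selected = sel),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection report (", x$rule, ")\n", sep = "")
  if (!is.null(x$goal)) cat("  goal: gv >", x$goal, " (>=", x$k, "lines)\n")
  if (!is.null(x$bins)) {
    cat("  intervals: ",
        paste(sprintf("[%g, %g)", x$bins$bin_lo, x$bins$bin_hi),
              collapse = " + "), "\n", sep = "")
  }
  cat("  selected combinations:", nrow(x$selected), "\n")
  invisible(x)
}
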