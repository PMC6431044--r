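#' Barcode-rank curve with knee and inflection points
#'
#' Ranks barcodes by decreasing total count (ties averaged), builds the
#' log-total versus log-rank curve with one point per distinct total, and
#' locates its inflection point (steepest descent) and knee point
#' (minimum signed curvature of a fitted smoothing spline). The total at
#' the knee is the upper retention threshold U: any barcode at least that
#' large is always treated as a cell.
#'
#' @param totals Per-barcode total UMI counts (or a count matrix /
#'   SummarizedExperiment, in which case column sums are used).
#' @param lower Ambient threshold T; points with totals at or below it
#'   are excluded from the inflection search window. Default 100.
#' @param exclude_rank_frac Fraction of the smallest ranks (the initial
#'   plateau) excluded from the inflection search. Default 0.01.
#' @return An object of class `knee_result`: list with `totals`, `ranks`
#'   (average-tie ranks, rank 1 = largest total), `curve` (data frame of
#'   `rank`, `total`, `log_rank`, `log_total`, one row per distinct
#'   positive total, decreasing total), `inflection`
#'   (`list(rank, total)`), `knee` (`list(rank, total, low_confidence)`),
#'   `fit` (the `smooth.spline` object, or `NULL` on fallback) and
#'   `fit_window` (log-rank range used for the spline).
#' @details If the spline fit fails (too few points in the window), the
#'   knee falls back to the inflection point with a warning and is
#'   flagged low-confidence; the knee total is never below the inflection
#'   total.
#' @export
barcode_ranks <- function(totals, lower = 100, exclude_rank_frac = 0.01) {
    if (is(totals, "SummarizedExperiment") || length(dim(totals)) == 2) {
        totals <- Matrix::colSums(counts_matrix(totals))
    }
    totals <- as.numeric(totals)
    ranks <- rank(-totals, ties.method = "average")
    curve <- .rank_curve(totals, ranks)
    if (nrow(curve) < 2) {
        stop("all totals are equal; no barcode-rank curve")
    }

    infl <- find_inflection(curve, lower = lower,
                            exclude_rank_frac = exclude_rank_frac)
    knee <- tryCatch(
        find_knee(curve, inflection = infl),
        error = function(e) {
            warning("knee spline fit failed (", conditionMessage(e),
                    "); falling back to the inflection point")
            list(rank = infl$rank, total = infl$total, low_confidence = TRUE,
                 fit = NULL, fit_window = NULL)
        }
    )

    structure(
        list(
            totals = totals,
            ranks = ranks,
            curve = curve,
            inflection = infl[c("rank", "total")],
            knee = knee[c("rank", "total", "low_confidence")],
            fit = knee$fit,
            fit_window = knee$fit_window
        ),
        class = "knee_result"
    )
}

# One point per distinct positive total: tied barcodes share the average
# rank, so each distinct total maps to a single (log rank, log total).
.rank_curve <- function(totals, ranks) {
    pos <- totals > 0
    if (!any(pos)) {
        stop("no positive totals")
    }
    ut <- sort(unique(totals[pos]), decreasing = TRUE)
    r_u <- vapply(split(ranks[pos], factor(totals[pos], levels = ut)),
                  function(r) r[1], numeric(1))
    data.frame(
        rank = unname(r_u),
        total = ut,
        log_rank = log(unname(r_u)),
        log_total = log(ut)
    )
}

#' Inflection point of the barcode-rank curve
#'
#' Finds the point of steepest descent: the most negative finite
#' difference of log-total with respect to log-rank, searched to the
#' right of the initial plateau (the first `exclude_rank_frac` of ranks)
#' and restricted to totals above `lower` so that noisy differences among
#' ambient barcodes cannot dominate. The right edge of the steepest
#' segment is reported.
#'
#' @param curve Curve data frame from [barcode_ranks()].
#' @param lower Ambient threshold T.
#' @param exclude_rank_frac Leading rank fraction to skip.
#' @return `list(rank, total)` at the inflection.
#' @export
find_inflection <- function(curve, lower = 100, exclude_rank_frac = 0.01) {
    n_barcodes <- max(curve$rank)
    keep <- curve$rank > exclude_rank_frac * n_barcodes &
        curve$total > lower
    sub <- curve[keep, , drop = FALSE]
    if (nrow(sub) < 3) {
        sub <- curve  # degenerate input; search the whole curve
    }
    if (nrow(sub) < 2) {
        stop("not enough distinct totals to locate an inflection")
    }
    d1 <- diff(sub$log_total) / diff(sub$log_rank)
    i <- which.min(d1)
    list(rank = sub$rank[i + 1], total = sub$total[i + 1])
}

#' Knee point of the barcode-rank curve
#'
#' Fits a cubic smoothing spline f to log-total versus log-rank on the
#' window from the smallest rank up to (and including) the inflection
#' point, evaluates its first and second derivatives analytically from
#' the spline basis, and returns the point minimizing the signed
#' curvature `f'' / (1 + f'^2)^1.5` over a dense grid of 1000 log-ranks.
#' Curvature ties are broken toward smaller rank (a larger, more
#' conservative retention threshold). The smoothing parameter is chosen
#' by generalized cross-validation with a floor that prevents
#' interpolation.
#'
#' @param curve Curve data frame from [barcode_ranks()].
#' @param inflection `list(rank, total)` from [find_inflection()].
#' @param grid_points Number of grid evaluations. Default 1000.
#' @return `list(rank, total, low_confidence, fit, fit_window)`; the total
#'   is clamped to be at least the inflection total, and
#'   `low_confidence` is `TRUE` when the minimum curvature is weak
#'   (magnitude below 0.5: a near-linear curve with no real knee).
#' @export
find_knee <- function(curve, inflection, grid_points = 1000) {
    window <- curve$rank <= inflection$rank
    sub <- curve[window, , drop = FALSE]
    if (nrow(sub) < 4) {
        stop("fewer than 4 curve points in the knee fit window")
    }
    fit <- stats::smooth.spline(sub$log_rank, sub$log_total, cv = FALSE)
    if (fit$spar < 0.1) {
        fit <- stats::smooth.spline(sub$log_rank, sub$log_total, spar = 0.1)
    }
    grid <- seq(min(sub$log_rank), max(sub$log_rank),
                length.out = grid_points)
    d1 <- stats::predict(fit, grid, deriv = 1)$y
    d2 <- stats::predict(fit, grid, deriv = 2)$y
    curvature <- d2 / (1 + d1^2)^1.5
    i <- which.min(curvature)
    knee_total <- exp(stats::predict(fit, grid[i])$y)
    # a visible knee bends the log-log curve with curvature well beyond
    # unit magnitude; near-linear curves only produce smoothing wiggles
    low_conf <- curvature[i] > -0.5
    list(
        rank = exp(grid[i]),
        total = max(knee_total, inflection$total),
        low_confidence = low_conf,
        fit = fit,
        fit_window = range(sub$log_rank)
    )
}

#' Upper retention threshold U
#'
#' Returns the total-count threshold above which barcodes are always
#' called cells regardless of their p-value: a manual override if given,
#' otherwise the knee total; with `ignore_knee = TRUE` the threshold is
#' `Inf`, so no barcode is auto-retained and calls rest on the p-values
#' alone.
#'
#' @param k A `knee_result`.
#' @param override Optional manual threshold.
#' @param ignore_knee Disable knee-based retention entirely.
#' @return The threshold U (numeric; possibly `Inf`).
#' @export
upper_threshold <- function(k, override = NULL, ignore_knee = FALSE) {
    if (ignore_knee) {
        return(Inf)
    }
    if (!is.null(override)) {
        return(as.numeric(override))
    }
    k$knee$total
}

#' @exportS3Method base::print
print.knee_result <- function(x, ...) {
    cat("Barcode rank curve:", length(x$totals), "barcodes,",
        nrow(x$curve), "distinct positive totals\n")
    cat("  knee:       total", signif(x$knee$total, 5), "at rank",
        signif(x$knee$rank, 5),
        if (isTRUE(x$knee$low_confidence)) "(low confidence)" else "", "\n")
    cat("  inflection: total", signif(x$inflection$total, 5), "at rank",
        signif(x$inflection$rank, 5), "\n")
    invisible(x)
}

#' Export the rank curve and fitted spline for plotting
#'
#' Writes a TSV with one row per distinct total: rank, total, and (where
#' the spline window covers the point) the fitted log-total, for
#' diagnostic barcode-rank plots.
#'
#' @param k A `knee_result`.
#' @param path Output file path.
#' @export
write_rank_curve <- function(k, path) {
    stopifnot(inherits(k, "knee_result"))
    out <- k$curve
    out$fitted_log_total <- NA_real_
    if (!is.null(k$fit)) {
        inside <- out$log_rank >= k$fit_window[1] &
            out$log_rank <= k$fit_window[2]
        out$fitted_log_total[inside] <-
            stats::predict(k$fit, out$log_rank[inside])$y
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
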