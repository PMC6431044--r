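#' Benjamini-Hochberg correction with known positives
#'
#' Applies the BH adjustment to the tested barcodes only (untested
#' barcodes, marked `NA`, are excluded entirely, which reduces the
#' severity of the correction), with known positives contributing a
#' p-value of zero so that they take adjusted value 0 and lighten the
#' correction on everything else.
#'
#' @param pvals Per-barcode p-values with `NA` for untested barcodes.
#' @param known_positive Logical mask of known true positives; must be a
#'   subset of the tested barcodes.
#' @return Per-barcode BH-adjusted values (`NA` where untested).
#' @examples
#' bh_with_known_positives(c(0.01, 0.02, 0.03), rep(FALSE, 3))
#' @export
bh_with_known_positives <- function(pvals,
                                    known_positive = rep(FALSE,
                                                         length(pvals))) {
    tested <- !is.na(pvals)
    if (!any(tested)) {
        stop("no tested barcodes to correct")
    }
    if (any(known_positive & !tested)) {
        stop("'known_positive' must be a subset of the tested barcodes")
    }
    p <- pvals[tested]
    p[known_positive[tested]] <- 0
    out <- rep(NA_real_, length(pvals))
    out[tested] <- stats::p.adjust(p, method = "BH")
    out
}

#' Call cells by testing barcodes against the ambient profile
#'
#' The full pipeline: estimate the ambient profile from barcodes with
#' totals at or below `lower` (T), compute Monte Carlo
#' Dirichlet-multinomial p-values for every barcode above T, detect the
#' knee of the barcode-rank curve to fix the upper retention threshold U,
#' apply the BH correction with the knee-retained barcodes
#' (`total >= U`) as known positives, and call as cells every barcode
#' with `FDR <= fdr_threshold` or `total >= U`. Barcodes at or below T
#' are never called. The run is fully deterministic given `seed`.
#'
#' @param x Matrix-like object or SummarizedExperiment of UMI counts.
#'   Genes with all-zero counts are dropped internally (the barcode set,
#'   and hence every total, is unchanged).
#' @param lower Ambient threshold T (default 100).
#' @param n_iters Monte Carlo iterations R (default 10000).
#' @param fdr_threshold FDR working point (default 0.001, i.e. 0.1\%).
#' @param seed Optional integer seed for the Monte Carlo sampling.
#' @param alpha Optional fixed Dirichlet-multinomial scale, skipping the
#'   maximum likelihood fit.
#' @param knee_override Optional manual U.
#' @param ignore_knee If `TRUE`, disable knee retention (U = `Inf`) and
#'   call cells on p-values alone.
#' @param sampler `"urn"` or `"naive"`; see
#'   [sample_dirmult_likelihoods()].
#' @return An object of class `empty_drops`: list with `table` (one row
#'   per barcode: `barcode`, `total`, `log_likelihood`, `n_below`,
#'   `n_iters`, `p_value`, `limited`, `fdr`, `retained_by_knee`,
#'   `is_cell`, `power_limited`), `profile` (the `ambient_profile`),
#'   `knee` (the `knee_result`), `U`, and the calling parameters. Raw
#'   p-values of knee-retained barcodes are reported as computed; the
#'   zeroing happens only inside the BH correction. `power_limited`
#'   flags tested non-calls whose p-value sat at the Monte Carlo floor,
#'   separating power-limited non-calls from confident ones.
#' @examples
#' set.seed(1)
#' m <- cbind(
#'     rdirmult_matrix(rep(30, 200), rep(0.01, 100), 20),      # ambient
#'     rdirmult_matrix(rep(500, 20), rep(0.01, 100), Inf)      # cells
#' )
#' res <- empty_drops(m, lower = 50, n_iters = 1000, seed = 7)
#' table(res$table$is_cell)
#' @export
empty_drops <- function(x, lower = 100, n_iters = 10000,
                        fdr_threshold = 0.001, seed = NULL, alpha = NULL,
                        knee_override = NULL, ignore_knee = FALSE,
                        sampler = c("urn", "naive")) {
    sampler <- match.arg(sampler)
    if (fdr_threshold <= 0 || fdr_threshold >= 1) {
        stop("'fdr_threshold' must be in (0, 1)")
    }
    m <- counts_matrix(x)
    m <- m[Matrix::rowSums(m) > 0, , drop = FALSE]

    if (!is.null(seed)) {
        withr::local_seed(seed)
    }
    profile <- build_ambient_profile(m, lower = lower, alpha = alpha)
    tab <- compute_pvalues(m, profile, n_iters = n_iters, sampler = sampler)

    knee <- barcode_ranks(tab$total, lower = lower)
    U <- upper_threshold(knee, override = knee_override,
                         ignore_knee = ignore_knee)

    tested <- !is.na(tab$p_value)
    retained <- tested & tab$total >= U
    tab$fdr <- bh_with_known_positives(tab$p_value, retained)
    tab$retained_by_knee <- retained
    tab$is_cell <- tested &
        ((!is.na(tab$fdr) & tab$fdr <= fdr_threshold) | retained)
    tab$power_limited <- tested & tab$limited & !tab$is_cell

    structure(
        list(
            table = tab,
            profile = profile,
            knee = knee,
            U = U,
            lower = lower,
            n_iters = n_iters,
            fdr_threshold = fdr_threshold,
            seed = seed
        ),
        class = "empty_drops"
    )
}

#' @exportS3Method base::print
print.empty_drops <- function(x, ...) {
    tab <- x$table
    cat("empty_drops result:", nrow(tab), "barcodes;",
        sum(!is.na(tab$p_value)), "tested (total >", x$lower, ")\n")
    cat("  U =", signif(x$U, 5), "; alpha =", signif(x$profile$alpha, 5),
        "\n")
    cat("  cells called at FDR", x$fdr_threshold, ":", sum(tab$is_cell),
        "(", sum(tab$retained_by_knee), "retained by knee )\n")
    invisible(x)
}

#' Expected-cell-count quantile baseline
#'
#' The quantile rule used by CellRanger: keep every barcode whose total
#' is at least 10\% of the 99th percentile of the `expected_cells`
#' largest totals. The percentile is computed by linear interpolation on
#' the sorted top totals ([stats::quantile()] type 7).
#'
#' @param totals Per-barcode total counts.
#' @param expected_cells Expected number of cells Y (between 1 and the
#'   number of barcodes).
#' @return Logical mask of retained barcodes.
#' @export
cellranger_call <- function(totals, expected_cells) {
    n <- length(totals)
    if (expected_cells < 1 || expected_cells > n) {
        stop("'expected_cells' must be between 1 and the number of barcodes")
    }
    top <- sort(totals, decreasing = TRUE)[seq_len(expected_cells)]
    threshold <- 0.1 * stats::quantile(top, 0.99, names = FALSE, type = 7)
    totals >= threshold
}

#' Knee-point baseline
#'
#' Keeps every barcode whose total is at least the knee total U.
#'
#' @param totals Per-barcode total counts.
#' @param knee A `knee_result`, or a numeric threshold U directly.
#' @return Logical mask of retained barcodes.
#' @export
knee_call <- function(totals, knee) {
    U <- if (inherits(knee, "knee_result")) knee$knee$total else knee
    totals >= U
}
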