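#' Sum counts over the low-count (presumed empty) barcodes
#'
#' Barcodes whose total UMI count is at or below the threshold `lower`
#' (T) are assumed to be empty droplets; their counts are summed per gene
#' to give the ambient count vector A.
#'
#' @param x Matrix-like object or SummarizedExperiment of UMI counts.
#' @param lower Total-count threshold T; membership is inclusive
#'   (`total <= lower`). Default 100.
#' @return List with `ambient_counts` (named per-gene integer vector) and
#'   `ambient_barcodes` (character or integer identifiers of the barcode
#'   set used).
#' @export
ambient_counts <- function(x, lower = 100) {
    m <- counts_matrix(x)
    if (lower < 1) {
        stop("'lower' must be at least 1")
    }
    totals <- Matrix::colSums(m)
    keep <- totals <= lower
    if (!any(keep)) {
        stop("no barcode has a total count <= ", lower,
             "; cannot estimate the ambient profile")
    }
    A <- Matrix::rowSums(m[, keep, drop = FALSE])
    bcs <- colnames(m)
    list(
        ambient_counts = A,
        ambient_barcodes = if (is.null(bcs)) which(keep) else bcs[keep]
    )
}

#' Good-Turing smoothed gene proportions
#'
#' Converts a vector of ambient gene counts into strictly positive
#' proportions using simple Good-Turing smoothing (Gale-Sampson): the
#' total unseen mass P0 = n1/N (n1 singletons, N total counts) is split
#' equally among zero-count genes, and observed counts receive smoothed
#' estimates renormalized to 1 - P0. Positivity of every proportion keeps
#' the Dirichlet-multinomial likelihood defined for any barcode.
#'
#' The regular regime is delegated to [edgeR::goodTuringProportions()].
#' Two degenerate regimes are handled directly, since the frequency
#' regression is then undefined: if there are no singletons (P0 = 0) or
#' fewer than two distinct positive frequencies, each zero-count gene
#' receives the floor 1/(N + G) (G genes in total) and the observed genes
#' share the remainder in proportion to their counts.
#'
#' @param counts Non-negative integer vector of per-gene counts with at
#'   least two total counts.
#' @return Numeric vector of proportions: strictly positive, summing to 1.
#' @examples
#' p <- good_turing_proportions(c(0, 5, 3, 1, 1))
#' stopifnot(all(p > 0), abs(sum(p) - 1) < 1e-10)
#' @export
good_turing_proportions <- function(counts) {
    counts <- as.numeric(counts)
    if (any(counts < 0) || any(counts != floor(counts))) {
        stop("'counts' must be non-negative integers")
    }
    N <- sum(counts)
    if (N < 2) {
        stop("need a total of at least 2 ambient counts")
    }
    pos <- counts[counts > 0]
    n1 <- sum(pos == 1)
    degenerate <- n1 == 0 || length(unique(pos)) < 2
    if (!degenerate) {
        p <- as.numeric(edgeR::goodTuringProportions(counts))
        if (all(is.finite(p)) && all(p > 0) && abs(sum(p) - 1) < 1e-8) {
            return(p)
        }
        # smoothing failed numerically; fall through to the floor rule
    }
    .floor_proportions(counts, N)
}

# Degenerate-regime proportions: zero-count genes get the floor
# 1/(N + G) each, observed genes split the remaining mass by raw counts.
.floor_proportions <- function(counts, N) {
    G <- length(counts)
    zero <- counts == 0
    p <- numeric(G)
    p0 <- 1 / (N + G)
    p[zero] <- p0
    p[!zero] <- counts[!zero] / N * (1 - sum(zero) * p0)
    p
}

#' Maximum likelihood estimate of the Dirichlet-multinomial scale
#'
#' Estimates the overdispersion scale alpha of the Dirichlet-multinomial
#' model by maximizing the summed log-likelihood of the ambient barcodes,
#' treating the smoothed proportions as known. Small alpha means strong
#' overdispersion; the multinomial is recovered as alpha grows.
#'
#' Maximization is a bounded one-dimensional search over log10(alpha)
#' (golden-section/Brent via [stats::optimize()]); a warning is issued if
#' the optimum is pinned at a bound, which for the upper bound simply
#' means the counts look multinomial.
#'
#' @param x Matrix-like object or SummarizedExperiment of UMI counts.
#' @param ambient_barcodes Identifiers (names or indices) of the barcode
#'   set used to fit alpha.
#' @param proportions Strictly positive per-gene proportions summing to 1.
#' @param interval Bounds on log10(alpha). Default `c(-2, 4)`.
#' @param tol Convergence tolerance on log10(alpha). Default `1e-5`.
#' @return The estimated alpha (positive scalar).
#' @export
estimate_alpha <- function(x, ambient_barcodes, proportions,
                           interval = c(-2, 4), tol = 1e-5) {
    m <- counts_matrix(x)
    if (length(ambient_barcodes) == 0) {
        stop("empty ambient barcode set")
    }
    if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-6) {
        stop("'proportions' must be strictly positive and sum to 1")
    }
    sub <- m[, ambient_barcodes, drop = FALSE]
    agg <- .aggregate_entries(sub)

    objective <- function(log10_alpha) {
        .dm_total_loglik_agg(10^log10_alpha, proportions, agg)
    }
    opt <- stats::optimize(objective, interval = interval, maximum = TRUE,
                           tol = tol)
    edge <- min(opt$maximum - interval[1], interval[2] - opt$maximum)
    if (edge < 10 * tol) {
        warning("alpha estimate pinned at an optimization bound (log10 alpha = ",
                signif(opt$maximum, 4), ")")
    }
    10^opt$maximum
}

# Collapse a sparse submatrix into weighted unique (gene, count) pairs and
# weighted unique totals, so the DM log-likelihood is cheap to re-evaluate
# across candidate alpha values.
.aggregate_entries <- function(sub) {
    G <- nrow(sub)
    y <- sub@x
    gene <- sub@i + 1
    key <- y * G + (gene - 1)
    if (length(key)) {
        k <- sort(key)
        new_run <- c(TRUE, k[-1] != k[-length(k)])
        uk <- k[new_run]
        w <- diff(c(which(new_run), length(k) + 1))
    } else {
        uk <- numeric(0)
        w <- numeric(0)
    }
    totals <- Matrix::colSums(sub)
    tt <- table(totals)
    list(
        gene = (uk %% G) + 1,
        y = uk %/% G,
        w = w,
        t_unique = as.numeric(names(tt)),
        t_w = as.numeric(tt),
        const = sum(lfactorial(totals)) - sum(lfactorial(y))
    )
}

.dm_total_loglik_agg <- function(alpha, proportions, agg) {
    ag <- alpha * proportions[agg$gene]
    entries <- sum(agg$w * (lgamma(agg$y + ag) - lgamma(ag)))
    sizes <- sum(agg$t_w * (lgamma(alpha) - lgamma(agg$t_unique + alpha)))
    entries + sizes + agg$const
}

#' Build the ambient RNA profile
#'
#' Chains [ambient_counts()], [good_turing_proportions()] and
#' [estimate_alpha()]: barcodes with totals at or below `lower` define
#' the ambient pool, their summed counts are smoothed into strictly
#' positive gene proportions, and the Dirichlet-multinomial scale alpha
#' is fitted to those same barcodes. The profile depends only on the
#' low-count barcode set, never on the barcodes that are later tested.
#'
#' @inheritParams ambient_counts
#' @param alpha Optional fixed alpha, skipping estimation.
#' @return An object of class `ambient_profile`: a list with
#'   `ambient_counts` (A), `proportions` (smoothed p), `alpha`, `lower`
#'   (T) and `ambient_barcodes` (the pool).
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(200, 2), nrow = 20)
#' prof <- build_ambient_profile(m, lower = 50)
#' @export
build_ambient_profile <- function(x, lower = 100, alpha = NULL) {
    m <- counts_matrix(x)
    amb <- ambient_counts(m, lower = lower)
    p <- good_turing_proportions(amb$ambient_counts)
    names(p) <- names(amb$ambient_counts)
    if (is.null(alpha)) {
        alpha <- estimate_alpha(m, amb$ambient_barcodes, p)
    } else if (!is.finite(alpha) || alpha <= 0) {
        stop("'alpha' must be positive and finite")
    }
    structure(
        list(
            ambient_counts = amb$ambient_counts,
            proportions = p,
            alpha = alpha,
            lower = lower,
            ambient_barcodes = amb$ambient_barcodes
        ),
        class = "ambient_profile"
    )
}

#' @exportS3Method base::print
print.ambient_profile <- function(x, ...) {
    cat("Ambient profile:", length(x$proportions), "genes,",
        length(x$ambient_barcodes), "barcodes with total <=", x$lower, "\n")
    cat("  alpha =", signif(x$alpha, 5),
        "; total ambient molecules =", sum(x$ambient_counts), "\n")
    invisible(x)
}

#' Export an ambient profile as TSV
#'
#' Writes one `gene<TAB>proportion` row per gene, preceded by a comment
#' line recording alpha and the pool threshold.
#'
#' @param profile An `ambient_profile`.
#' @param path Output file path.
#' @export
write_ambient_profile <- function(profile, path) {
    stopifnot(inherits(profile, "ambient_profile"))
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(sprintf("# alpha=%.10g lower=%d", profile$alpha,
                       as.integer(profile$lower)), con)
    genes <- names(profile$proportions)
    if (is.null(genes)) genes <- paste0("gene", seq_along(profile$proportions))
    writeLines(paste(genes, format(profile$proportions, digits = 12,
                                   scientific = TRUE, trim = TRUE),
                     sep = "\t"), con)
    invisible(path)
}
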