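#' Generate a synthetic unfiltered droplet count matrix
#'
#' Builds a labelled stand-in for a real unfiltered 10X run, with the
#' two-plateau barcode-rank geometry that cell calling relies on: a
#' heavy-tailed (Zipf) ambient gene profile; `n_empties` empty droplets
#' whose counts are Dirichlet-multinomial draws from that profile with
#' small lognormal totals; and `n_cells` cell-containing droplets drawn
#' from a handful of cell-type-specific expression profiles (lognormal
#' fold perturbations of the ambient proportions) with large lognormal
#' totals.
#'
#' @param n_genes,n_cells,n_empties Fixture dimensions. Defaults 2000
#'   genes, 2000 cells, 50000 empties.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   matrix exactly.
#' @param ambient_alpha Dirichlet-multinomial scale used to draw the
#'   empty droplets (moderate overdispersion by default).
#' @param empty_meanlog,empty_sdlog Lognormal parameters of the empty
#'   totals (default: around 50 molecules).
#' @param cell_meanlog,cell_sdlog Lognormal parameters of the cell totals
#'   (default: around 5000 molecules).
#' @param n_cell_types Number of distinct cell expression profiles.
#' @param type_lfc_sd Standard deviation of the log-fold perturbations
#'   that differentiate each cell type from the ambient profile.
#' @return A \linkS4class{SingleCellExperiment} whose `colData` carries
#'   the true `type` (`"empty"` or `"cell"`), and whose metadata records
#'   the generation parameters and a `transition_band`: the total-count
#'   interval (99th percentile of empty totals, 99th percentile of cell
#'   totals) inside which a sensible upper retention threshold must fall.
#' @export
make_base_fixture <- function(n_genes = 2000, n_cells = 2000,
                              n_empties = 50000, seed = NULL,
                              ambient_alpha = 100,
                              empty_meanlog = log(50), empty_sdlog = 0.6,
                              cell_meanlog = log(5000), cell_sdlog = 0.15,
                              n_cell_types = 3, type_lfc_sd = 1) {
    if (n_genes < 2 || n_empties < 1 || n_cells < 0) {
        stop("invalid fixture dimensions")
    }
    if (!is.null(seed)) {
        withr::local_seed(seed)
    }

    p_amb <- (seq_len(n_genes))^-1
    p_amb <- p_amb / sum(p_amb)

    empty_totals <- pmax(1L, as.integer(round(
        stats::rlnorm(n_empties, empty_meanlog, empty_sdlog))))
    empties <- rdirmult_matrix(empty_totals, p_amb, ambient_alpha)

    if (n_cells > 0) {
        type_p <- lapply(seq_len(n_cell_types), function(i) {
            p <- p_amb * exp(stats::rnorm(n_genes, 0, type_lfc_sd))
            p / sum(p)
        })
        cell_totals <- pmax(1L, as.integer(round(
            stats::rlnorm(n_cells, cell_meanlog, cell_sdlog))))
        type_of <- sample.int(n_cell_types, n_cells, replace = TRUE)
        cells <- matrix(0, n_genes, n_cells)
        for (j in seq_len(n_cells)) {
            cells[, j] <- stats::rmultinom(1, cell_totals[j],
                                           type_p[[type_of[j]]])[, 1]
        }
        m <- cbind(empties, as(Matrix::Matrix(cells, sparse = TRUE),
                               "CsparseMatrix"))
        labels <- c(rep("empty", n_empties), rep("cell", n_cells))
        band <- c(
            lower = unname(stats::quantile(empty_totals, 0.99)),
            upper = unname(stats::quantile(cell_totals, 0.99))
        )
    } else {
        m <- empties
        labels <- rep("empty", n_empties)
        band <- c(lower = NA_real_, upper = NA_real_)
    }
    rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
    colnames(m) <- sprintf("BC%06d", seq_len(ncol(m)))

    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(type = labels),
        metadata = list(
            params = list(
                n_genes = n_genes, n_cells = n_cells,
                n_empties = n_empties, seed = seed,
                ambient_alpha = ambient_alpha,
                empty_meanlog = empty_meanlog, empty_sdlog = empty_sdlog,
                cell_meanlog = cell_meanlog, cell_sdlog = cell_sdlog,
                n_cell_types = n_cell_types, type_lfc_sd = type_lfc_sd
            ),
            ambient_proportions = p_amb,
            transition_band = band
        )
    )
}

#' Downsample a count vector or matrix without replacement
#'
#' Draws exactly `round(fraction * total)` molecules from each barcode's
#' molecules without replacement (multivariate hypergeometric across
#' genes), so the expected count of each gene is `fraction` times its
#' original count and totals are hit exactly.
#'
#' @param y Non-negative integer vector, or a matrix-like object whose
#'   columns are downsampled independently.
#' @param fraction Fraction of each total to keep, in (0, 1].
#' @return Object of the same shape with downsampled counts.
#' @export
downsample_counts <- function(y, fraction) {
    if (fraction <= 0 || fraction > 1) {
        stop("'fraction' must be in (0, 1]")
    }
    if (is.null(dim(y))) {
        m <- counts_matrix(matrix(as.numeric(y), ncol = 1))
        newx <- cpp_downsample_columns(m@x, m@p, fraction)
        out <- numeric(length(y))
        out[m@i + 1] <- newx
        return(out)
    }
    m <- counts_matrix(y)
    m@x <- cpp_downsample_columns(m@x, m@p, fraction)
    Matrix::drop0(m)
}

#' Simulate a labelled benchmark dataset from a base matrix
#'
#' Reproduces the evaluation design for cell-calling methods. The base
#' matrix is split at the inflection point of its barcode-rank curve:
#' barcodes below it form the empty set G0, whose summed counts make an
#' ambient molecule pool. Simulated empty droplets are drawn from that
#' pool without replacement (a global permutation of the pool partitioned
#' into the required totals) so that their totals are exactly the
#' multiset of G0 totals. `G1` large cells are sampled with replacement
#' from the above-inflection barcodes; `G2` small cells are sampled
#' likewise and downsampled to `downsample_fraction` of their totals.
#' In all sampled cell profiles, a fixed random `scramble_fraction` of
#' genes (chosen once per simulation) have their counts permuted among
#' themselves, with a fresh permutation per barcode, to break any
#' resemblance to the ambient pool while preserving totals.
#'
#' @param base Matrix-like object or SummarizedExperiment (e.g. from
#'   [make_base_fixture()] or [read_10x()]).
#' @param G1 Number of large cells.
#' @param G2 Number of small (downsampled) cells.
#' @param seed Optional integer seed.
#' @param downsample_fraction Fraction retained for small cells
#'   (default 0.1).
#' @param scramble_fraction Fraction of genes scrambled in cell profiles
#'   (default 0.1).
#' @param lower Ambient threshold passed to the rank-curve analysis of
#'   the base data.
#' @return An object of class `simulated_dataset`: list with `counts`
#'   (`dgCMatrix`), `labels` (factor with levels `empty`, `large_cell`,
#'   `small_cell`) and `params`.
#' @export
simulate_from_base <- function(base, G1, G2, seed = NULL,
                               downsample_fraction = 0.1,
                               scramble_fraction = 0.1, lower = 100) {
    m <- counts_matrix(base)
    if (!is.null(seed)) {
        withr::local_seed(seed)
    }
    totals <- Matrix::colSums(m)
    br <- barcode_ranks(totals, lower = lower)
    infl <- br$inflection$total

    g0 <- totals < infl
    above <- which(totals > infl)
    if (!any(g0)) {
        stop("no barcodes below the inflection point; pool is empty")
    }
    if (length(above) == 0) {
        stop("no barcodes above the inflection point to sample cells from")
    }

    # Empties: permute the pooled molecules, partition into the G0 totals.
    pool <- Matrix::rowSums(m[, g0, drop = FALSE])
    empty_totals <- as.integer(totals[g0])
    molecules <- sample(rep.int(seq_len(nrow(m)), pool))
    keep <- empty_totals > 0
    emp <- Matrix::sparseMatrix(
        i = molecules,
        j = rep.int(which(keep), empty_totals[keep]),
        x = 1, dims = c(nrow(m), length(empty_totals))
    )

    n_genes <- nrow(m)
    scramble_genes <- sample.int(n_genes,
                                 max(1L, round(scramble_fraction * n_genes)))

    large <- as.matrix(m[, sample(above, G1, replace = TRUE), drop = FALSE])
    colnames(large) <- NULL  # sampling with replacement duplicates barcodes
    small <- m[, sample(above, G2, replace = TRUE), drop = FALSE]
    colnames(small) <- NULL
    small <- as.matrix(downsample_counts(small, downsample_fraction))
    for (j in seq_len(G1)) {
        large[scramble_genes, j] <-
            large[sample(scramble_genes), j]
    }
    for (j in seq_len(G2)) {
        small[scramble_genes, j] <-
            small[sample(scramble_genes), j]
    }

    counts <- cbind(
        emp,
        as(Matrix::Matrix(large, sparse = TRUE), "CsparseMatrix"),
        as(Matrix::Matrix(small, sparse = TRUE), "CsparseMatrix")
    )
    rownames(counts) <- rownames(m)
    colnames(counts) <- c(
        sprintf("EMPTY%06d", seq_len(ncol(emp))),
        sprintf("LARGE%06d", seq_len(G1)),
        sprintf("SMALL%06d", seq_len(G2))
    )
    labels <- factor(
        c(rep("empty", ncol(emp)), rep("large_cell", G1),
          rep("small_cell", G2)),
        levels = c("empty", "large_cell", "small_cell")
    )
    structure(
        list(
            counts = counts,
            labels = labels,
            params = list(
                G1 = G1, G2 = G2,
                downsample_fraction = downsample_fraction,
                scramble_fraction = scramble_fraction,
                seed = seed, inflection_total = infl,
                scrambled_genes = scramble_genes
            )
        ),
        class = "simulated_dataset"
    )
}

#' @exportS3Method base::print
print.simulated_dataset <- function(x, ...) {
    cat("Simulated dataset:", nrow(x$counts), "genes x", ncol(x$counts),
        "barcodes\n")
    print(table(x$labels))
    invisible(x)
}

#' Evaluate cell-calling methods on a labelled simulation
#'
#' Runs the ambient-profile test ([empty_drops()]), the knee-point
#' baseline and the expected-cell-count quantile baseline (with the true
#' number of simulated cells as the expected count) on a simulated
#' dataset, and reports for each method the recall on large and small
#' cells and the observed FDR (the proportion of detected barcodes that
#' are known empty droplets; `NA` if nothing is detected).
#'
#' @param sim A `simulated_dataset`.
#' @param lower,n_iters,fdr_threshold,seed Parameters passed to
#'   [empty_drops()].
#' @param expected_cells Expected cell count for the quantile baseline;
#'   defaults to `G1 + G2`.
#' @return Data frame with one row per method: `method`, `recall_large`,
#'   `recall_small`, `observed_fdr`, `n_called`.
#' @export
evaluate_methods <- function(sim, lower = 100, n_iters = 10000,
                             fdr_threshold = 0.001, seed = NULL,
                             expected_cells = NULL) {
    stopifnot(inherits(sim, "simulated_dataset"))
    if (is.null(expected_cells)) {
        expected_cells <- sim$params$G1 + sim$params$G2
    }
    counts <- filter_zero_genes(sim$counts)
    totals <- Matrix::colSums(counts)

    res <- empty_drops(counts, lower = lower, n_iters = n_iters,
                       fdr_threshold = fdr_threshold, seed = seed)
    calls <- list(
        emptydrops = res$table$is_cell,
        knee = knee_call(totals, res$knee),
        cellranger = cellranger_call(totals, expected_cells)
    )

    lab <- sim$labels
    do.call(rbind, lapply(names(calls), function(meth) {
        called <- calls[[meth]]
        data.frame(
            method = meth,
            recall_large = mean(called[lab == "large_cell"]),
            recall_small = mean(called[lab == "small_cell"]),
            observed_fdr = if (any(called)) {
                sum(called & lab == "empty") / sum(called)
            } else {
                NA_real_
            },
            n_called = sum(called),
            stringsAsFactors = FALSE
        )
    }))
}

#' Run the full simulation benchmark grid
#'
#' For every `(G1, G2)` scenario, repeats [simulate_from_base()] and
#' [evaluate_methods()] for `iterations` iterations with independently
#' derived seeds, collecting per-iteration recall and observed FDR for
#' each method.
#'
#' @param base Base matrix (see [simulate_from_base()]).
#' @param scenarios Data frame with columns `G1` and `G2`, or `NULL` for
#'   the default grid `{500, 2000} x {500, 2000}`.
#' @param iterations Iterations per scenario (default 10).
#' @param lower,n_iters,fdr_threshold Calling parameters.
#' @param seed Root seed from which all per-iteration seeds are derived.
#' @return Data frame of per-iteration results with `G1`, `G2`,
#'   `iteration` prepended to the [evaluate_methods()] columns.
#' @seealso [summarize_benchmark()] for mean and standard error per
#'   scenario and method.
#' @export
benchmark_scenarios <- function(base, scenarios = NULL, iterations = 10,
                                lower = 100, n_iters = 10000,
                                fdr_threshold = 0.001, seed = 1) {
    if (is.null(scenarios)) {
        scenarios <- expand.grid(G1 = c(500, 2000), G2 = c(500, 2000))
    }
    withr::local_seed(seed)
    seeds <- matrix(
        sample.int(.Machine$integer.max - 1, 2 * nrow(scenarios) * iterations),
        ncol = 2
    )
    out <- list()
    row <- 0L
    for (s in seq_len(nrow(scenarios))) {
        for (it in seq_len(iterations)) {
            row <- row + 1L
            sim <- simulate_from_base(base, G1 = scenarios$G1[s],
                                      G2 = scenarios$G2[s],
                                      seed = seeds[row, 1], lower = lower)
            ev <- evaluate_methods(sim, lower = lower, n_iters = n_iters,
                                   fdr_threshold = fdr_threshold,
                                   seed = seeds[row, 2])
            ev <- cbind(
                data.frame(G1 = scenarios$G1[s], G2 = scenarios$G2[s],
                           iteration = it),
                ev
            )
            out[[row]] <- ev
        }
    }
    do.call(rbind, out)
}

#' Summarize a benchmark run
#'
#' Mean and standard error of recall and observed FDR per scenario and
#' method, across iterations.
#'
#' @param results Output of [benchmark_scenarios()].
#' @return Data frame with one row per scenario and method.
#' @export
summarize_benchmark <- function(results) {
    key <- interaction(results$G1, results$G2, results$method, drop = TRUE)
    se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    rows <- lapply(split(results, key), function(d) {
        data.frame(
            G1 = d$G1[1], G2 = d$G2[1], method = d$method[1],
            iterations = nrow(d),
            recall_large = mean(d$recall_large),
            recall_large_se = se(d$recall_large),
            recall_small = mean(d$recall_small),
            recall_small_se = se(d$recall_small),
            observed_fdr = mean(d$observed_fdr, na.rm = TRUE),
            observed_fdr_se = se(d$observed_fdr),
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$G1, out$G2, out$method), ]
}

#' Write a simulated dataset to disk
#'
#' Writes the counts in 10X format plus a `labels.tsv` with the true
#' per-barcode category.
#'
#' @param sim A `simulated_dataset`.
#' @param path Output directory.
#' @param version 10X dialect passed to [write_10x()].
#' @export
write_simulated_dataset <- function(sim, path, version = "2") {
    stopifnot(inherits(sim, "simulated_dataset"))
    write_10x(sim$counts, path, version = version)
    utils::write.table(
        data.frame(barcode = colnames(sim$counts), label = sim$labels),
        file.path(path, "labels.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
    )
    invisible(path)
}
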