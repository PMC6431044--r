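# Shared fixture builders and independent oracles.

# Deterministic 3x4 count matrix with dimnames.
tiny_counts <- function() {
    m <- Matrix::sparseMatrix(
        i = c(1, 1, 2, 3, 3), j = c(1, 2, 2, 3, 4), x = c(2, 1, 5, 3, 7),
        dims = c(3, 4)
    )
    dimnames(m) <- list(paste0("G", 1:3), paste0("BC", 1:4))
    m
}

# Independent Dirichlet-multinomial draws (gamma + multinomial route),
# used as an oracle against the package's urn-based sampler.
rdirmult_r <- function(n, size, proportions, alpha) {
    vapply(seq_len(n), function(i) {
        p <- rgamma(length(proportions), shape = alpha * proportions)
        rmultinom(1, size, p / sum(p))[, 1]
    }, numeric(length(proportions)))
}

# Small ambient + planted-cell matrix: `n_ambient` barcodes of DM counts
# from a Zipf ambient profile, plus `n_cells` barcodes drawn from a
# distinct profile.
ambient_cells_matrix <- function(n_genes = 100, n_ambient = 1000,
                                 ambient_total = 50, n_cells = 50,
                                 cell_total = 400, alpha = 20) {
    p_amb <- (1:n_genes)^-1
    p_amb <- p_amb / sum(p_amb)
    amb <- rdirmult_matrix(rep(ambient_total, n_ambient), p_amb, alpha)
    cells <- rdirmult_matrix(rep(cell_total, n_cells), rev(p_amb), Inf)
    m <- cbind(amb, cells)
    rownames(m) <- paste0("G", seq_len(n_genes))
    colnames(m) <- paste0("BC", seq_len(ncol(m)))
    m
}

# Ambient profile object with known parameters (bypasses estimation).
fixed_profile <- function(proportions, alpha, lower) {
    structure(
        list(
            ambient_counts = NULL, proportions = proportions,
            alpha = alpha, lower = lower, ambient_barcodes = character(0)
        ),
        class = "ambient_profile"
    )
}

# All compositions of total t over n parts (columns), for exact
# enumeration of small Dirichlet-multinomial state spaces.
compositions <- function(t, n) {
    if (n == 1) {
        return(matrix(t, nrow = 1))
    }
    out <- list()
    for (k in 0:t) {
        rest <- compositions(t - k, n - 1)
        out[[k + 1]] <- rbind(k, rest)
    }
    do.call(cbind, out)
}

# Jittered two-plateau totals with a known gap between plateaus.
two_plateau_totals <- function(n_high = 500, n_low = 20000, seed = 1) {
    withr::with_seed(seed, {
        c(round(rlnorm(n_high, log(1000), 0.1)),
          round(rlnorm(n_low, log(10), 0.3)))
    })
}
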