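# Independent straight-line implementation of simple Good-Turing
# smoothing (Gale & Sampson 1995), used as an oracle for
# good_turing_proportions() in the non-degenerate regime.
#
# Recipe: build the frequency-of-frequencies table (r, n_r); transform
# Z_r = n_r / (0.5 * (t - q)) with q, t the neighbouring observed
# frequencies (q = 0 before the first, t = 2r - q after the last); fit
# log Z = a + b log r by least squares; smoothed estimate
# r*_LGT = (r + 1) (1 + 1/r)^b; Turing estimate r*_T = (r+1) n_{r+1}/n_r;
# use the Turing estimate until the first r at which it differs from the
# smoothed one by less than 1.96 approximate standard deviations (or has
# no n_{r+1}), then switch permanently; renormalize the observed mass to
# 1 - P0 with P0 = n_1 / N, and split P0 equally among unseen species.
sgt_reference <- function(counts) {
    N <- sum(counts)
    obs <- counts[counts > 0]
    r <- sort(unique(obs))
    n <- vapply(r, function(v) sum(obs == v), numeric(1))
    k <- length(r)
    stopifnot(k >= 2)

    q <- c(0, r[-k])
    t_next <- c(r[-1], 2 * r[k] - r[k - 1])
    Z <- n / (0.5 * (t_next - q))
    fit <- stats::lm.fit(cbind(1, log(r)), log(Z))
    b <- fit$coefficients[2]

    r_lgt <- (r + 1) * (1 + 1 / r)^b
    n_next <- vapply(r + 1, function(v) {
        i <- match(v, r)
        if (is.na(i)) 0 else n[i]
    }, numeric(1))
    r_turing <- (r + 1) * n_next / n

    switched <- FALSE
    r_star <- numeric(k)
    for (i in seq_len(k)) {
        if (!switched) {
            if (n_next[i] == 0) {
                switched <- TRUE
            } else {
                sd_t <- sqrt((r[i] + 1)^2 * (n_next[i] / n[i]^2) *
                             (1 + n_next[i] / n[i]))
                if (abs(r_turing[i] - r_lgt[i]) <= 1.96 * sd_t) {
                    switched <- TRUE
                }
            }
        }
        r_star[i] <- if (switched) r_lgt[i] else r_turing[i]
    }

    P0 <- if (1 %in% r) n[match(1, r)] / N else 0
    N_star <- sum(n * r_star)
    p_of_r <- (1 - P0) * r_star / N_star

    p <- numeric(length(counts))
    n0 <- sum(counts == 0)
    if (n0 > 0) p[counts == 0] <- P0 / n0
    p[counts > 0] <- p_of_r[match(counts[counts > 0], r)]
    p
}
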