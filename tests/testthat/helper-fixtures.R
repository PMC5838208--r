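# Shared in-code fixtures and independent oracles.

# small beta matrix with named groups
make_toy_beta <- function(n_sites = 6, n_ref = 3, n_case = 4, seed = 7) {
    set.seed(seed)
    b <- matrix(runif(n_sites * (n_ref + n_case)), n_sites,
                dimnames = list(sprintf("cg%03d", seq_len(n_sites)),
                                c(sprintf("r%d", seq_len(n_ref)),
                                  sprintf("c%d", seq_len(n_case)))))
    groups <- setNames(rep(c("REF", "CASE"), c(n_ref, n_case)), colnames(b))
    BetaSet(b, groups)
}

# exhaustive pairwise-median oracle for the Hodges-Lehmann estimate
hl_oracle <- function(case, ref) {
    d <- numeric(0)
    for (ci in case) for (rj in ref) d <- c(d, ci - rj)
    sort(d)[ceiling(length(d) / 2)] / 2 + sort(d)[floor(length(d) / 2) + 1] / 2
}

# full enumeration oracle for the one-sided Mann-Whitney p-value with a shift
mw_enum_oracle <- function(case, ref, shift = 0, side = "greater") {
    x <- case - shift
    pool <- c(x, ref)
    m <- length(x)
    r <- rank(pool)
    u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    splits <- utils::combn(length(pool), m)
    u_all <- apply(splits, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
    if (side == "greater") mean(u_all >= u_obs) else mean(u_all <= u_obs)
}

# full enumeration oracle for the one-sided signed-rank p-value vs mu
sr_enum_oracle <- function(v, mu = 0.5, side = "greater") {
    d <- v - mu
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    v_all <- as.matrix(signs) %*% r
    if (side == "greater") mean(v_all >= v_obs) else mean(v_all <= v_obs)
}

# random valid mixture for property tests
random_mixture <- function(K, seed) {
    set.seed(seed)
    w <- runif(K, 0.05, 1)
    GaussianMixture1D(mu = runif(K, -0.4, 0.4),
                      sigma = runif(K, 0.005, 0.2),
                      w = w / sum(w))
}

# dense-grid argmax scan: the independent MAP-partition oracle
grid_partition_oracle <- function(m, n_grid = 200001L) {
    lo <- min(m@mu - 6 * m@sigma); hi <- max(m@mu + 6 * m@sigma)
    x <- seq(lo, hi, length.out = n_grid)
    dom <- max.col(componentLogDensity(m, x), ties.method = "first")
    ch <- which(diff(dom) != 0L)
    list(x = x, step = x[2] - x[1], change_at = (x[ch] + x[ch + 1L]) / 2,
         dom = dom)
}
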