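# Independent oracles used across test files.

# all permutations of a vector, built by recursive insertion (independent of
# the expand.grid construction inside the package)
perms_recursive <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_recursive(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# brute-force one-sided permutation p for a 4-point series
perm_p_bruteforce <- function(d) {
  if (stats::sd(d) == 0) return(1)
  r_obs <- stats::cor(d, 1:4)
  rs <- vapply(perms_recursive(1:4), function(o) stats::cor(d, o), 0)
  sum(rs <= r_obs + 1e-12) / length(rs)
}

# brute-force conditional exact p at dispersion 0 and size factors s_a, s_b:
# splits of the total are binomial(total, s_a/(s_a+s_b))
nb_p_bruteforce <- function(k_a, k_b, s_a = 1, s_b = 1) {
  k <- k_a + k_b
  if (k == 0) return(1)
  pr <- stats::dbinom(0:k, k, s_a / (s_a + s_b))
  sum(pr[pr <= pr[k_a + 1] * (1 + 1e-12)])
}

# brute-force two-sided Fisher p by enumerating all tables with fixed margins
fisher_p_bruteforce <- function(a, b, c, d) {
  m <- a + b; n1 <- a + c; N <- a + b + c + d
  lo <- max(0, n1 - (N - m)); hi <- min(n1, m)
  pr <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(N - m, n1 - x) - lchoose(N, n1))
  }, 0)
  obs <- pr[a - lo + 1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# position scan for stop codons without vectorised trinucleotide tricks
stop_density_bruteforce <- function(s) {
  L <- nchar(s)
  hits <- 0
  for (i in seq_len(max(0, L - 2))) {
    if (substr(s, i, i + 2) %in% c("TAA", "TAG", "TGA")) hits <- hits + 1
  }
  hits / L
}

# grid-search maximum-likelihood logistic slope (intercept profiled on a grid
# too); accurate to the grid resolution
logistic_grid_oracle <- function(x, y, b0_range = c(-6, 6),
                                 b1_range = c(-6, 6), step = 0.001) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  # coarse-to-fine search on the slope, profiling the intercept
  best <- c(NA, NA, -Inf)
  for (pass in 1:5) {
    b1s <- seq(b1_range[1], b1_range[2], length.out = 61)
    b0s <- seq(b0_range[1], b0_range[2], length.out = 61)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[idx[1]], b1s[idx[2]], max(ll))
    w0 <- diff(range(b0s)) / 10; w1 <- diff(range(b1s)) / 10
    b0_range <- best[1] + c(-w0, w0)
    b1_range <- best[2] + c(-w1, w1)
  }
  list(b0 = best[1], b1 = best[2])
}

# small quiet pipeline config for tests
test_config <- function(...) {
  pipeline_config(out_dir = withr::local_tempdir(.local_envir = parent.frame()),
                  ...)
}
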