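# Independent oracles and shared fixtures. Each oracle is a deliberately
# naive reference implementation (enumeration, brute-force summation, fine
# grids) kept separate from the code paths it checks.

# Exact hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_p <- function(overlap, set_size, bg_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(bg_size - set_size, query_size - ks)) /
    choose(bg_size, query_size)
}

# Exact two-sided rank-sum p by enumerating every rank assignment (mid-ranks).
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  sums <- combn(n, na, function(ix) sum(r[ix]))
  p_lo <- mean(sums <= w + 1e-9)
  p_hi <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# NB quantile by brute-force CDF summation over counts 0..1000.
oracle_nb_quantile <- function(q, mu, size) {
  cdf <- cumsum(dnbinom(0:1000, size = size, mu = mu))
  which(cdf >= q)[1] - 1
}

# Benjamini-Hochberg by the step-up definition.
oracle_bh <- function(p) {
  n <- length(p); o <- order(p)
  adj <- rep(NA_real_, n)
  running <- 1
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# Fine-grid trapezoid DSS oracle.
oracle_dss <- function(fit, range, t = 10, cap = 100, npts = 10000) {
  xs <- seq(range[1], range[2], length.out = npts)
  yy <- pmax(0, pmin(predict(fit, xs), cap) - t)
  h <- diff(xs[1:2])
  100 * h * (sum(yy) - (yy[1] + yy[npts]) / 2) / ((100 - t) * diff(range))
}

# Two well-separated gaussian blobs (cells in columns), truth = 1/2.
make_blobs <- function(n_per = 200, n_genes = 50, shift = 10, seed = 5) {
  set.seed(seed)
  c1 <- matrix(rnorm(n_genes * n_per), n_genes)
  c1[1:10, ] <- c1[1:10, ] + shift
  c2 <- matrix(rnorm(n_genes * n_per), n_genes)
  c2[11:20, ] <- c2[11:20, ] + shift
  X <- cbind(c1, c2) - min(c1, c2)
  dimnames(X) <- list(paste0("g", seq_len(n_genes)),
                      paste0("c", seq_len(2 * n_per)))
  list(mat = Matrix::Matrix(X, sparse = TRUE), truth = rep(1:2, each = n_per))
}

# Small hashed experiment reused across tests (generated once per session).
tiny_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(cells_per_well = 25, n_genes = 700, module_size = 20,
                        seed = 42)
      cache <<- generate_hashed_experiment(cfg)
    }
    cache
  }
})
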