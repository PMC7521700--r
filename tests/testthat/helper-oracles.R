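# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Benjamini-Hochberg step-up computed literally from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, mapped back to the
# original order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# single-linkage clusters of sorted values with a gap cut: two values
# share a cluster iff they are connected by steps of size <= tol
brute_gap_clusters <- function(mz, tol) {
  o <- order(mz)
  x <- mz[o]
  cl <- cumsum(c(1, diff(x) > tol))
  out <- integer(length(mz))
  out[o] <- cl
  out
}

# interval union length by marking positions
brute_union_length <- function(from, to, len) {
  pos <- rep(FALSE, len)
  for (i in seq_along(from)) pos[from[i]:to[i]] <- TRUE
  sum(pos)
}

# per-gene prevalence classification by an explicit loop
brute_pangenome <- function(pam, core = 0.99, soft = 0.95, shell = 0.15) {
  out <- character(nrow(pam))
  for (i in seq_len(nrow(pam))) {
    f <- sum(pam[i, ]) / ncol(pam)
    out[i] <- if (f >= core) "core" else if (f >= soft) "soft_core"
      else if (f >= shell) "shell" else "cloud"
  }
  out
}

# exhaustive two-sample permutation test on the absolute mean difference
brute_permutation_p <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  combos <- utils::combn(length(x), n)
  stats <- apply(combos, 2, function(idx) {
    abs(mean(x[idx]) - mean(x[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# standard simulation used by several tests: 10 fixers on an even
# incorporation grid, 10 non-fixers, 50 metabolites, triplicates,
# CV 0.1
recovery_sim <- function(seed = 42L, n_metabolites = 50L) {
  mets <- random_metabolites(n_metabolites, seed = seed + 1L)
  truths <- isolate_truths(10, 10)
  sim <- simulate_peak_lists(mets, truths,
                             sim_config(noise_cv = 0.1, seed = seed))
  list(sim = sim, truths = truths)
}
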