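# Independent brute-force oracles, deliberately separate from the
# package's code paths.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted p-values.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided one-sample Wilcoxon signed-rank p by enumeration of
# all 2^n sign assignments of the midranks (zeros dropped first).
bruteWilcoxonP <- function(x, mu0 = 0) {
  x <- x - mu0
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  dist <- 0
  for (b in seq_len(n)) {
    dist <- c(dist, dist + r[b])  # grow the W distribution subset by subset
  }
  min(1, 2 * min(mean(dist <= W), mean(dist >= W)))
}

# all permutations of 1..n, one per row
allPerms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# shared small-cohort generator config: fronto-limbic volumes only,
# no lateralization unless planted
volOnlyConfig <- function(seed = 1) {
  rs <- defaultRegionSpecs()
  rs <- rs[rs$measure == "volume" & rs$region %in% frontolimbicRegions(), ]
  clearLateralization(cohortConfig(region_specs = rs, seed = seed))
}

# tiny cohort for I/O tests
tinyCohort <- function(seed = 11, n = 4) {
  simulateCohort(cohortConfig(n_subjects = n, seed = seed), seed = seed)
}
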