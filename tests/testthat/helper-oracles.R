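# Independent oracles, coded from the textbook formulas with scalar loops,
# deliberately separate from the package implementations they check.

# Weir & Cockerham (1984) per-site variance components for two populations,
# one site at a time. g1, g2: integer vectors of 0/1/2 calls (NA = missing).
wc_site_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  r <- 2
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# naive double-loop GRM evaluation
grm_oracle <- function(calls) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  n <- nrow(calls); m <- ncol(calls)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) {
      xj <- calls[j, i]; xk <- calls[k, i]
      if (is.na(xj)) xj <- 2 * p[i]
      if (is.na(xk)) xk <- 2 * p[i]
      s <- s + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    }
    A[j, k] <- s / m
  }
  A
}

# small deterministic genotype-table fixture
toy_geno <- function(calls, chrom = NULL, pos = NULL, depths = NULL, ...) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_table(calls, chrom = chrom, pos = pos, depths = depths, ...)
}

# deterministic two-group fixture: n per group, m sites, frequencies given
two_pop_geno <- function(p_a, p_b, n = 20, seed = 1) {
  set.seed(seed)
  m <- length(p_a)
  calls <- rbind(
    matrix(rbinom(n * m, 2, rep(p_a, each = n)), nrow = n),
    matrix(rbinom(n * m, 2, rep(p_b, each = n)), nrow = n))
  ids <- c(sprintf("A%02d", 1:n), sprintf("B%02d", 1:n))
  list(geno = toy_geno(calls, individuals = ids),
       groups = data.frame(individual_id = ids,
                           group = rep(c("feral", "domesticated"), each = n)))
}
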