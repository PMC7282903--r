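# Fixtures are built in code; nothing is read from disk.

# Tiny deterministic two-locus matrix used across unit tests.
tiny_matrix <- function() {
  genotype_matrix(
    ids = c("w1", "w2", "w3", "e1"),
    population = c("p1", "p1", "p2", "g1"),
    source = c("in_situ", "in_situ", "in_situ", "ex_situ"),
    alleles = matrix(c(
      100L, 102L, 200L, 200L,
      100L, 100L, 200L, 202L,
      102L, 104L, NA, NA,
      100L, 102L, 200L, 200L
    ), nrow = 4, byrow = TRUE),
    loci = c("L1", "L2")
  )
}

# Randomized valid matrix for property tests (includes missing genotypes).
random_matrix <- function(seed, n = 12, n_loci = 3, n_pops = 2,
                          p_missing = 0.1, with_ex_situ = TRUE) {
  set.seed(seed)
  alleles <- matrix(NA_integer_, n, 2L * n_loci)
  for (l in seq_len(n_loci)) {
    codes <- sample(100:140, sample(2:6, 1))
    a <- sample(codes, 2L * n, replace = TRUE)
    alleles[, 2L * l - 1L] <- a[seq_len(n)]
    alleles[, 2L * l] <- a[n + seq_len(n)]
    miss <- runif(n) < p_missing
    alleles[miss, c(2L * l - 1L, 2L * l)] <- NA_integer_
  }
  src <- rep("in_situ", n)
  if (with_ex_situ && n > 3) src[seq_len(max(1, n %/% 4))] <- "ex_situ"
  genotype_matrix(
    ids = sprintf("ind%02d", seq_len(n)),
    population = paste0("pop_", sample.int(n_pops, n, replace = TRUE)),
    source = src,
    alleles = alleles,
    loci = paste0("L", seq_len(n_loci))
  )
}

# N individuals each homozygous for a private allele at one locus: every
# allele has exactly one carrier, so capture has a clean hypergeometric form.
private_allele_matrix <- function(N = 10) {
  genotype_matrix(
    ids = paste0("w", seq_len(N)),
    population = rep("p1", N),
    source = rep("in_situ", N),
    alleles = matrix(rep(100L + seq_len(N), each = 2), ncol = 2, byrow = TRUE),
    loci = "L1"
  )
}

# Independently coded two-variable OLS via the normal equations, as the
# oracle for log_capture_fit.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# Monte-Carlo standard error of a curve mean at one grid point.
curve_se <- function(curve, cat, n) {
  row <- curve[curve$category == cat & curve$n == n, ]
  row$sd / sqrt(attr(curve, "replicates"))
}
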