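test_that("pairwise FST is 1 for fixed differences and ~0 for a duplicated population", {
  # two populations fixed for different alleles at every locus
  n <- 10
  al1 <- matrix(100L, n, 4); al2 <- matrix(120L, n, 4)
  gm <- genotype_matrix(paste0("i", 1:(2 * n)),
                        rep(c("A", "B"), each = n),
                        rep("in_situ", 2 * n),
                        rbind(al1, al2), c("L1", "L2"))
  f <- pairwise_fst_matrix(gm)
  expect_equal(f$matrix["A", "B"], 1)

  # one population relabelled as two: no differentiation
  base <- random_matrix(5, n = 60, n_loci = 8, n_pops = 1, p_missing = 0,
                        with_ex_situ = FALSE)
  base$population <- rep(c("X", "Y"), length.out = 60)
  gm2 <- genotype_matrix(base$ids, base$population, base$source,
                         base$alleles, base$loci)
  f2 <- pairwise_fst_matrix(gm2)
  expect_lt(abs(f2$matrix["X", "Y"]), 0.02)
})

test_that("FST summary statistics cover the off-diagonal pairs", {
  gm <- generate_structured_population(
    synthetic_spec(n_populations = 3, n_per_pop = 30, n_loci = 20,
                   target_fst = 0.15, seed = 77))
  f <- pairwise_fst_matrix(gm)
  off <- f$matrix[upper.tri(f$matrix)]
  expect_equal(f$mean, mean(off))
  expect_equal(f$min, min(off))
  expect_equal(f$max, max(off))
  expect_equal(f$sd, sd(off))
  expect_true(isSymmetric(f$matrix))
  expect_error(pairwise_fst_matrix(random_matrix(1, n_pops = 1)), "2 populations")
})

test_that("spectrum summaries use strict 'below' and are monotone in the cutoff", {
  gm <- genotype_matrix(c("a", "b"), c("p", "p"), rep("in_situ", 2),
                        matrix(c(100L, 100L, 100L, 102L), 2, byrow = TRUE), "L1")
  tab <- tabulate_alleles(gm)  # freqs 0.75, 0.25
  expect_equal(unname(spectrum_summaries(tab, 0.05)), 0)
  # hand-built table: alleles at 0.004, 0.03, 0.2, 0.8
  tab2 <- tab[c(1, 2, 1, 2), ]
  tab2$freq <- c(0.004, 0.03, 0.2, 0.8)
  expect_equal(unname(spectrum_summaries(tab2, 0.05)), 0.5)
  expect_equal(unname(spectrum_summaries(tab2, c(0.001, 0.01, 0.05, 0.5, 1))),
               c(0, 0.25, 0.5, 0.75, 1))
  s <- spectrum_summaries(tabulate_alleles(random_matrix(9)), c(0.001, 0.01, 0.05))
  expect_true(all(diff(s) >= 0))
})

test_that("log fit recovers exact relationships and matches the OLS oracle", {
  n <- c(5, 10, 20, 50, 100, 200)
  y <- 10 + 5 * log(n)
  fit <- log_capture_fit(n, y)
  expect_equal(fit$slope, 5)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$adj_r_squared, 1)

  # two points: interpolation, zero residuals, adjusted R^2 undefined
  fit2 <- log_capture_fit(c(10, 100), c(40, 90))
  expect_equal(fit2$intercept + fit2$slope * log(10), 40)
  expect_equal(fit2$intercept + fit2$slope * log(100), 90)
  expect_true(is.na(fit2$adj_r_squared))

  # noisy fixture vs independent normal-equations oracle
  set.seed(13)
  nn <- sample(5:300, 25)
  yy <- 20 + 12 * log(nn) + rnorm(25, 0, 6)
  fit3 <- log_capture_fit(nn, yy)
  oracle <- ols_oracle(log(nn), yy)
  expect_equal(fit3$intercept, unname(oracle["intercept"]), tolerance = 1e-8)
  expect_equal(fit3$slope, unname(oracle["slope"]), tolerance = 1e-8)
  # adjusted R^2 definition
  r2 <- fit3$r_squared
  expect_equal(fit3$adj_r_squared, 1 - (1 - r2) * (25 - 1) / (25 - 2))

  expect_error(log_capture_fit(c(10, 10, 10), c(1, 2, 3)), "degenerate")
})

test_that("one-way ANOVA matches the hand-computed oracle", {
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4)))
  # between-SS 1.5 (df 1), within-SS 4 (df 4) -> F = 1.5
  expect_equal(res$f, 1.5)
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE))
  # cross-check against stats::oneway.test with equal variances
  set.seed(2)
  g <- list(a = rnorm(8), b = rnorm(6, 1), c = rnorm(7, -0.5))
  mine <- one_way_anova(g)
  ref <- oneway.test(y ~ grp,
                     data = data.frame(y = unlist(g),
                                       grp = rep(names(g), lengths(g))),
                     var.equal = TRUE)
  expect_equal(mine$f, unname(ref$statistic))
  expect_equal(mine$p, unname(ref$p.value))

  # degenerate groups
  res_inf <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_identical(res_inf$f, Inf)
  expect_identical(res_inf$p, 0)
  expect_error(one_way_anova(list(a = 1:3)), "2 non-empty groups")
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "zero")
})

test_that("BH adjustment matches hand computation and stats::p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(sample(3:30, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone on the order statistics
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
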