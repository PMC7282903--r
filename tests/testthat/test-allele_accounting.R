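test_that("tabulate_alleles counts copies and excludes missing from both sides", {
  gm <- tiny_matrix()
  tab <- tabulate_alleles(gm, "in_situ")
  # L1: w1 100/102, w2 100/100, w3 102/104 -> 100:3, 102:2, 104:1 over 6 copies
  l1 <- tab[tab$locus == "L1", ]
  expect_identical(l1$count[match(c(100, 102, 104), l1$allele)], c(3L, 2L, 1L))
  expect_equal(l1$freq[l1$allele == 100], 0.5)
  # L2: w3 missing -> denominator 4, not 6
  expect_identical(unname(attr(tab, "denominators")["L2"]), 4L)
  expect_equal(tab$freq[tab$locus == "L2" & tab$allele == 200], 0.75)
  # per-locus frequencies sum to 1
  for (l in unique(tab$locus)) {
    expect_equal(sum(tab$freq[tab$locus == l]), 1, tolerance = 1e-12)
  }
})

test_that("homozygous duo yields one entry at frequency 1", {
  gm <- genotype_matrix(c("a", "b"), c("p", "p"), rep("in_situ", 2),
                        matrix(rep(100L, 4), 2), "L1")
  tab <- tabulate_alleles(gm)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$count, 4L)
  expect_equal(tab$freq, 1)
})

test_that("an all-missing locus is dropped with a warning", {
  gm <- genotype_matrix(c("a", "b"), c("p", "p"), rep("in_situ", 2),
                        matrix(c(100L, 100L, NA, NA, 100L, 102L, NA, NA),
                               2, byrow = TRUE), c("L1", "L2"))
  expect_warning(tab <- tabulate_alleles(gm), "L2")
  expect_identical(unique(tab$locus), "L1")
})

test_that("frequency classification uses strict inequalities", {
  expect_setequal(classify_allele_frequency(0.15), c("all", "very_common", "common"))
  expect_setequal(classify_allele_frequency(0.02), c("all", "low_frequency"))
  # boundary cases fall through the strict bounds
  expect_setequal(classify_allele_frequency(0.10), c("all", "common"))
  expect_setequal(classify_allele_frequency(0.01), "all")
  expect_setequal(classify_allele_frequency(0.005), c("all", "rare"))
})

test_that("named bands are mutually exclusive and every allele is in 'all'", {
  for (seed in 1:5) {
    tab <- tabulate_alleles(random_matrix(seed, n = 20, n_loci = 4))
    m <- category_membership(tab$freq)
    expect_true(all(m[, "all"]))
    # very_common / low_frequency / rare cannot overlap
    expect_true(all(m[, "very_common"] + m[, "low_frequency"] + m[, "rare"] <= 1))
  }
})

test_that("min-copy filter removes 1-2 copy alleles without renormalizing", {
  gm <- tiny_matrix()
  tab <- tabulate_alleles(gm, "in_situ")
  red <- apply_min_copy_filter(tab)
  # L1 counts were 100:3, 102:2, 104:1 -> boundary: 3 kept, 2 and 1 removed
  expect_identical(red$allele[red$locus == "L1"], 100L)
  expect_true(all(red$count > 2))
  # retained entries keep their original frequencies
  kept <- merge(red, tab, by = c("locus", "allele"))
  expect_equal(kept$freq.x, kept$freq.y)
  expect_identical(attr(red, "variant"), "reduced")
  expect_identical(apply_min_copy_filter(tab, 0)$count, tab$count)
  expect_identical(attr(apply_min_copy_filter(tab, 0), "variant"), "full")
})

test_that("filter warns when a locus loses every allele", {
  gm <- genotype_matrix(c("a"), "p", "in_situ",
                        matrix(c(100L, 102L), 1), "L1")
  tab <- tabulate_alleles(gm)
  expect_warning(red <- apply_min_copy_filter(tab), "L1")
  expect_identical(nrow(red), 0L)
})

test_that("capture percentages match the worked arithmetic", {
  # wild alleles {A,B,C,D} equally frequent; collection carries {A,B} -> 50%
  gm <- genotype_matrix(
    ids = c("w1", "w2"), population = c("p", "p"), source = rep("in_situ", 2),
    alleles = matrix(c(100L, 102L, 104L, 106L), 2, byrow = TRUE), loci = "L1")
  ex <- genotype_matrix("e1", "g", "ex_situ", matrix(c(100L, 102L), 1), "L1")
  cap <- capture_percentages(tabulate_alleles(gm), ex)
  expect_equal(cap$percent[cap$category == "all"], 50)

  # collection identical to the wild set -> 100% in every non-empty category
  wild <- random_matrix(3, with_ex_situ = FALSE)
  cap_full <- capture_percentages(tabulate_alleles(wild), wild)
  expect_true(all(cap_full$percent[!is.na(cap_full$percent)] == 100))

  # empty collection -> 0% everywhere (defined categories)
  none <- genotype_matrix(character(0), character(0), character(0),
                          matrix(integer(0), 0, 2 * length(wild$loci)), wild$loci)
  cap0 <- capture_percentages(tabulate_alleles(wild), none)
  expect_true(all(cap0$percent[!is.na(cap0$percent)] == 0))

  # empty category reported as NA, not 0; empty table is an error
  expect_true(is.na(cap$percent[cap$category == "rare"]))
  expect_error(capture_percentages(tabulate_alleles(wild)[0, ], wild), "empty")
})

test_that("capture is monotone in the collection and under the reduced filter", {
  for (seed in 11:15) {
    wild <- random_matrix(seed, n = 16, n_loci = 3, with_ex_situ = FALSE)
    tab <- tabulate_alleles(wild)
    red <- apply_min_copy_filter(tab)
    set.seed(seed)
    sizes <- c(4, 8, 12)
    prev <- rep(-1, 5)
    ids <- sample(wild$ids)
    for (n in sizes) {
      sub <- wild[ids[seq_len(n)]]
      cap <- capture_percentages(tab, sub)$percent
      ok <- !is.na(cap) & !is.na(prev)
      expect_true(all(cap[ok] >= prev[ok]))
      prev <- cap
      # removing the hardest alleles cannot lower the captured fraction
      if (nrow(red) > 0) {
        cap_red <- capture_percentages(red, sub)$percent
        expect_true(cap_red[1] >= cap[1] - 1e-9)
      }
    }
  }
})
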