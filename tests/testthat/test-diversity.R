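test_that("heterozygosity matches the unbiased formula and edge cases", {
  # two alleles at p = 0.5 in n = 10 diploids: He = (20/19) * 0.5
  rows <- c(geno_rows(c(1L, 2L), 4), geno_rows(c(1L, 1L), 3),
            geno_rows(c(2L, 2L), 3))
  h <- heterozygosity(make_ds(rows), "A")
  expect_equal(unname(h$He), 20 / 19 * 0.5, tolerance = 1e-12)
  expect_equal(unname(h$Ho), 0.4)

  mono <- heterozygosity(make_ds(geno_rows(c(7L, 7L), 5)), "A")
  expect_equal(unname(mono$Ho), 0)
  expect_equal(unname(mono$He), 0)

  allhet <- heterozygosity(make_ds(geno_rows(c(1L, 2L), 6)), "A")
  expect_equal(unname(allhet$Ho), 1)

  # bounds, and He = 0 iff monomorphic
  ds <- random_hwe_ds(15, 5, seed = 5)
  h2 <- heterozygosity(ds, NULL)
  expect_true(all(h2$Ho >= 0 & h2$Ho <= 1 & h2$He >= 0 & h2$He <= 1))
})

test_that("allelic richness is the exact hypergeometric rarefaction", {
  # counts (18, 2), g = 2, against exhaustive subsample enumeration
  rows <- c(geno_rows(c(1L, 1L), 9), geno_rows(c(2L, 2L), 1))
  ds <- make_ds(rows)
  expected <- 2 - choose(18, 2) / choose(20, 2) - choose(2, 2) / choose(20, 2)
  expect_equal(unname(allelic_richness(ds, "A", 2)), expected,
               tolerance = 1e-12)
  # g at the full gene count returns the observed allele count
  expect_equal(unname(allelic_richness(ds, "A", 20)), 2)
  # single allele floors at 1
  expect_equal(unname(allelic_richness(make_ds(geno_rows(c(3L, 3L), 6)),
                                       "A", 4)), 1)
  expect_error(allelic_richness(ds, "A", 1), ">= 2")
  # monotone non-decreasing in g
  ds2 <- random_hwe_ds(20, 4, k = 6, seed = 9)
  ar <- vapply(2:20, function(g) mean(allelic_richness(ds2, "A", g)),
               numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("FIS matches a brute-force variance-component oracle", {
  # independent implementation of the single-population Weir-Cockerham f
  oracle_f <- function(a) {
    nn <- nrow(a)
    alleles <- sort(unique(as.vector(a)))
    b_t <- c_t <- 0
    for (al in alleles) {
      p <- mean(a == al)
      h <- mean(a[, 1] != a[, 2] & (a[, 1] == al | a[, 2] == al))
      b_t <- b_t + nn / (nn - 1) *
        (p * (1 - p) - (2 * nn - 1) / (4 * nn) * h)
      c_t <- c_t + h / 2
    }
    1 - c_t / (b_t + c_t)
  }
  set.seed(11)
  for (rep_ in 1:3) {
    ds <- random_hwe_ds(25, 4, k = 5)
    a1 <- ds$alleles[, 1:2]
    expect_equal(fis(subset_loci(ds, 1), "A"), oracle_f(a1),
                 tolerance = 1e-10)
  }
  # Hardy-Weinberg-exact genotype counts give f ~ 0
  rows <- c(geno_rows(c(1L, 1L), 25), geno_rows(c(1L, 2L), 50),
            geno_rows(c(2L, 2L), 25))
  expect_lt(abs(fis(make_ds(rows), "A")), 0.02)
  # all homozygotes with both alleles present: f = 1
  rows2 <- c(geno_rows(c(1L, 1L), 5), geno_rows(c(2L, 2L), 5))
  expect_equal(fis(make_ds(rows2), "A"), 1)
})

test_that("HWE exact test reproduces enumeration and its conventions", {
  rows <- c(geno_rows(c(1L, 1L), 25), geno_rows(c(1L, 2L), 50),
            geno_rows(c(2L, 2L), 25))
  expect_gt(hwe_exact_test(make_ds(rows), "A", "L1"), 0.5)
  expect_lt(hwe_exact_test(make_ds(geno_rows(c(1L, 2L), 20)), "A", "L1"),
            0.01)
  expect_equal(hwe_exact_test(make_ds(geno_rows(c(4L, 4L), 10)), "A", "L1"),
               1)
  # Monte Carlo branch converges to the enumerated p on a small table
  rows2 <- c(geno_rows(c(1L, 1L), 6), geno_rows(c(1L, 2L), 3),
             geno_rows(c(2L, 2L), 5))
  ds2 <- make_ds(rows2)
  p_enum <- hwe_exact_test(ds2, "A", "L1")
  p_mc <- hwe_exact_test(ds2, "A", "L1", mc_reps = 1e5, seed = 1,
                         max_tables = 0)
  expect_lt(abs(p_enum - p_mc), 0.01)
  # multi-allelic enumeration agrees with Monte Carlo
  rows3 <- c(geno_rows(c(1L, 2L), 4), geno_rows(c(2L, 3L), 4),
             geno_rows(c(1L, 3L), 2), geno_rows(c(1L, 1L), 2))
  ds3 <- make_ds(rows3)
  p3 <- hwe_exact_test(ds3, "A", "L1")
  p3mc <- hwe_exact_test(ds3, "A", "L1", mc_reps = 1e5, seed = 2,
                         max_tables = 0)
  expect_lt(abs(p3 - p3mc), 0.015)
})

test_that("LD permutation test flags association and holds its size", {
  set.seed(21)
  # a locus against a shuffled copy of itself: perfect association
  al <- cbind(sample(rep(1:4, 10)), sample(rep(1:4, 10)))
  ds <- genotype_dataset(cbind(al, al), c("L1", "L2"), paste0("i", 1:40),
                         rep("A", 40))
  r <- ld_test(ds, "A", "L1", "L2", permutations = 499, seed = 3)
  expect_lte(r$p, 5 / 500)
  # independent loci: null p approximately uniform (type-I error at 5%)
  set.seed(22)
  ps <- replicate(120, {
    ds2 <- random_hwe_ds(30, 2, k = 4)
    ld_test(ds2, "A", 1, 2, permutations = 199)$p
  })
  rej <- mean(ps < 0.05)
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 120) + 0.015)
  # insufficient joint calls flagged
  dsm <- make_ds(list(c(1L, 2L, NA, NA), c(1L, 2L, 3L, 4L),
                      c(2L, 2L, 3L, 3L), c(1L, 1L, 4L, 4L),
                      c(1L, 2L, 3L, 3L)))
  expect_warning(out <- ld_test(dsm, "A", 1, 2), "fewer than 5")
  expect_true(is.na(out$p))
})

test_that("Bonferroni constants match the published critical values", {
  expect_equal(bonferroni_alpha(0.05, 136), 0.05 / 136)
  expect_equal(round(bonferroni_alpha(0.05, 28), 3), 0.002)
  expect_equal(round(bonferroni_alpha(0.05, 8), 3), 0.006)
})

test_that("screens assemble the full test families with Bonferroni flags", {
  set.seed(25)
  ds <- random_hwe_ds(12, 3, k = 3, pops = 2)
  hw <- hwe_screen(ds, mc_reps = 200)
  expect_equal(nrow(hw), 2 * 3)
  expect_equal(attr(hw, "critical_p"), 0.05 / sum(!is.na(hw$p)))
  ld <- ld_screen(ds, permutations = 99, seed = 1)
  expect_equal(nrow(ld), 2 * choose(3, 2))
})

test_that("diversity and locus tables have coherent structure", {
  set.seed(26)
  ds <- random_hwe_ds(15, 4, k = 5, pops = 3)
  dt <- diversity_table(ds)
  expect_equal(dt$pop, c("A", "B", "C"))
  expect_true(all(dt$AR >= 1))
  expect_true(all(abs(dt$FIS) <= 1))
  ls <- locus_summary(ds)
  expect_true(all(ls$min <= ls$mean & ls$mean <= ls$max))
})
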