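fixed_two_pops <- function(n = 10, L = 2) {
  a1 <- matrix(1L, n, 2 * L); a2 <- matrix(2L, n, 2 * L)
  genotype_dataset(rbind(a1, a2), paste0("L", 1:L), paste0("i", 1:(2 * n)),
                   rep(c("A", "B"), each = n))
}

test_that("global theta hits both extremes and errors on no information", {
  expect_equal(global_fst(fixed_two_pops()), 1)
  set.seed(31)
  ds <- random_hwe_ds(500, 5, k = 6, pops = 2)   # one panmictic pool
  expect_lt(abs(global_fst(ds)), 0.01)
  mono <- make_ds(geno_rows(c(1L, 1L), 10), pop = rep(c("A", "B"), 5))
  expect_error(global_fst(mono), "monomorphic")
  expect_error(global_fst(make_ds(geno_rows(c(1L, 2L), 4))), "2 populations")
})

test_that("pairwise theta on a 2-population subset equals global theta", {
  set.seed(32)
  ds <- random_hwe_ds(15, 4, k = 4, pops = 3)
  pm <- pairwise_fst(ds, bootstraps = 0)
  sub <- subset_individuals(ds, ds$pop %in% c("A", "B"))
  expect_equal(pm$values["A", "B"], global_fst(sub), tolerance = 1e-12)
  expect_true(isSymmetric(pm$values))
  expect_true(all(diag(pm$values) == 0))
})

test_that("pairwise theta bootstrap flags and Bonferroni threshold", {
  set.seed(33)
  ds <- random_hwe_ds(20, 6, k = 4, pops = 2)    # identical source: theta ~ 0
  pm <- pairwise_fst(ds, bootstraps = 200, seed = 1)
  expect_gt(pm$p["A", "B"], 0.05)                # not significantly > 0
  sig <- pairwise_fst(fixed_two_pops(15, 6), bootstraps = 200, seed = 2)
  expect_lt(sig$p["A", "B"], 0.01)
  k8 <- random_hwe_ds(8, 3, k = 3, pops = 8)
  m8 <- pairwise_fst(k8, bootstraps = 0)
  expect_equal(attr(m8, "critical_p"), 0.05 / 28)
})

test_that("Hedrick G'ST matches extremes and a brute-force oracle", {
  expect_equal(hedrick_gst(fixed_two_pops()), 1, tolerance = 1e-12)
  set.seed(34)
  big <- random_hwe_ds(400, 4, k = 5, pops = 2)
  expect_lt(abs(hedrick_gst(big)), 0.02)         # no differentiation
  # independent evaluation of the formula on a small random case
  ds <- random_hwe_ds(12, 3, k = 4, pops = 2, seed = 35)
  hs_l <- ht_l <- numeric(0)
  for (l in 1:3) {
    ca <- allele_counts(ds, l, "A"); cb <- allele_counts(ds, l, "B")
    alle <- union(names(ca), names(cb))
    pa <- setNames(rep(0, length(alle)), alle); pa[names(ca)] <- ca / sum(ca)
    pb <- setNames(rep(0, length(alle)), alle); pb[names(cb)] <- cb / sum(cb)
    na_ <- sum(ca) / 2; nb <- sum(cb) / 2
    hs_l <- c(hs_l, mean(c(2 * na_ / (2 * na_ - 1) * (1 - sum(pa^2)),
                           2 * nb / (2 * nb - 1) * (1 - sum(pb^2)))))
    ht_l <- c(ht_l, 1 - sum(((pa + pb) / 2)^2))
  }
  gst <- (mean(ht_l) - mean(hs_l)) / mean(ht_l)
  gmax <- ((2 - 1) * (1 - mean(hs_l))) / (2 - 1 + mean(hs_l))
  expect_equal(hedrick_gst(ds), gst / gmax, tolerance = 1e-12)
})

test_that("linearized FST reproduces printed cells and its algebra", {
  fst <- hmch_pairwise_fst()
  lin <- linearize_fst(fst)
  expect_equal(round(lin$values["3", "9"], 3), 0.098)
  expect_equal(round(lin$values["1", "3"], 3), 0.035)
  # every printed linFST cell is the rounded transform of the printed FST
  expect_equal(round(lower_tri(lin), 3), lower_tri(hmch_linfst()))
  # zero maps to zero; strictly increasing and convex on [0, 1)
  x <- seq(0, 0.9, 0.05)
  y <- x / (1 - x)
  expect_equal(y[1], 0)
  expect_true(all(diff(y) > 0))
  expect_true(all(diff(diff(y)) > 0))
  # exact inverse
  expect_equal(y / (1 + y), x, tolerance = 1e-12)
  expect_warning(linearize_fst(pairwise_matrix(matrix(c(0, 1, 1, 0), 2),
                                               c("a", "b"), "fst")), "Inf")
})

test_that("Dps measures shared-allele distance", {
  set.seed(36)
  ds_same <- random_hwe_ds(20, 3, k = 4, pops = 1)
  two <- genotype_dataset(rbind(ds_same$alleles, ds_same$alleles),
                          ds_same$loci,
                          c(ds_same$individuals,
                            paste0(ds_same$individuals, "b")),
                          rep(c("A", "B"), each = 20))
  expect_equal(dps_matrix(two)$values["A", "B"], 0)       # identical freqs
  expect_equal(dps_matrix(fixed_two_pops())$values["A", "B"], 1)  # disjoint
  # brute-force min-overlap oracle on a random two-population case
  ds <- random_hwe_ds(10, 4, k = 5, pops = 2, seed = 37)
  sh <- vapply(1:4, function(l) {
    ca <- allele_counts(ds, l, "A"); cb <- allele_counts(ds, l, "B")
    alle <- union(names(ca), names(cb))
    pa <- setNames(rep(0, length(alle)), alle); pa[names(ca)] <- ca / sum(ca)
    pb <- setNames(rep(0, length(alle)), alle); pb[names(cb)] <- cb / sum(cb)
    sum(pmin(pa, pb))
  }, numeric(1))
  expect_equal(dps_matrix(ds)$values["A", "B"], 1 - mean(sh),
               tolerance = 1e-12)
})

test_that("AMOVA partitions variance sensibly and conserves percentages", {
  set.seed(38)
  # one pool split arbitrarily in two: among-population share ~ 0
  ds <- random_hwe_ds(30, 5, k = 5, pops = 2)
  am <- amova(ds, permutations = 99, seed = 1)
  expect_lt(am$percent["among_pops"], 5)
  expect_gt(am$p["among_pops"], 0.05)
  expect_equal(sum(am$percent), 100, tolerance = 0.1)
  # fixed differences: everything among populations
  am2 <- amova(fixed_two_pops(12, 3), permutations = 49, seed = 2)
  expect_equal(unname(am2$percent["among_pops"]), 100, tolerance = 0.1)
  expect_lt(am2$p["among_pops"], 0.05)
  expect_error(amova(make_ds(geno_rows(c(1L, 2L), 5))), "2 populations")
})

test_that("AMOVA among-population share tracks theta across migration", {
  set.seed(39)
  pcts <- thetas <- numeric(0)
  for (m in c(0.002, 0.02, 0.2)) {
    cfg <- synth_config(n_sites = 3, deme_ne = 60, migration_model = "island",
                        m_total = m, n_adults = 25, n_larvae = 0,
                        generations = 300, seed = round(m * 1e5))
    ds <- simulate_metapopulation(cfg)$dataset
    pcts <- c(pcts, amova(ds, permutations = 0)$percent["among_pops"])
    thetas <- c(thetas, global_fst(ds))
  }
  expect_equal(order(pcts), order(thetas))
  expect_true(all(diff(thetas) < 0))           # more migration, less structure
})
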