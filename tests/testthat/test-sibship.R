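# pedigree-recovery oracles: the generator's true family labels are the
# reference against which the likelihood-ratio clustering is scored

pair_recovery <- function(sim, pop) {
  fa <- infer_fullsib_families(sim$dataset, pop)
  truth <- sim$truth$pedigree
  truth <- truth[truth$pop == pop & truth$stage == "larva", ]
  estf <- fa$families$family[match(truth$individual, fa$families$individual)]
  tp <- fn <- 0
  n <- nrow(truth)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (truth$family[i] == truth$family[j]) {
      if (estf[i] == estf[j]) tp <- tp + 1 else fn <- fn + 1
    }
  }
  list(rate = tp / (tp + fn), fa = fa,
       true_k = length(unique(truth$family)))
}

test_that("unrelated larvae stay (almost) all singletons", {
  set.seed(61)
  singles <- vapply(1:3, function(r) {
    cfg <- synth_config(migration_model = "island", seed = 6100 + r)
    ds0 <- simulate_metapopulation(cfg)$dataset
    freqs <- lapply(seq_along(ds0$loci), function(l) {
      cnt <- allele_counts(ds0, l, "1"); cnt / sum(cnt)
    })
    al <- t(replicate(30, unlist(lapply(freqs, function(p)
      sample(as.integer(names(p)), 2, TRUE, p)))))
    ds <- genotype_dataset(al, ds0$loci, paste0("u", 1:30), rep("1", 30),
                           rep("larva", 30))
    fa <- infer_fullsib_families(ds, "1")
    sum(table(fa$families$family) == 1)
  }, numeric(1))
  expect_gte(max(singles), 28)
  expect_true(all(singles >= 24))
})

test_that("full-sib broods are recovered almost completely", {
  set.seed(62)
  rates <- vapply(1:3, function(r) {
    cfg <- synth_config(n_adults = rep(0, 10),
                        n_larvae = c(30, rep(0, 9)), brood_lambda = 5,
                        migration_model = "island", seed = 6200 + r)
    pair_recovery(simulate_metapopulation(cfg), "1")$rate
  }, numeric(1))
  expect_true(all(rates >= 0.9))
})

test_that("identical multilocus genotypes are grouped into one family", {
  set.seed(63)
  base <- random_hwe_ds(12, 8, k = 5)
  al <- base$alleles
  al[2, ] <- al[1, ]                      # clone of individual 1
  ds <- genotype_dataset(al, base$loci, base$individuals, base$pop,
                         rep("larva", 12))
  fa <- infer_fullsib_families(ds, "A")
  f <- setNames(fa$families$family, fa$families$individual)
  expect_equal(unname(f["i1"]), unname(f["i2"]))
})

test_that("monomorphic data carries no sibship information", {
  ds <- make_ds(geno_rows(c(5L, 5L), 6), stage = rep("larva", 6))
  expect_error(infer_fullsib_families(ds, "A"), "monomorphic")
  expect_error(infer_fullsib_families(make_ds(list(c(1L, 2L))), "A"),
               "fewer than 2 larvae")
})

test_that("pruning keeps one per family, least missing first, and is
           idempotent", {
  al <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, NA, NA), c(2L, 2L, 3L, 3L))
  ds <- genotype_dataset(al, c("L1", "L2"), c("a", "b", "c"),
                         rep("A", 3), rep("larva", 3))
  fams <- structure(list(families = data.frame(
    individual = c("a", "b", "c"), family = c("F1", "F1", "F2"),
    stringsAsFactors = FALSE), pop = "A", n_families = 2,
    mean_family_size = 1.5, max_family_size = 2),
    class = "family_assignment")
  out <- prune_to_one_per_family(ds, fams)
  expect_setequal(out$individuals, c("a", "c"))   # "b" has missing data
  out2 <- prune_to_one_per_family(out, fams)
  expect_identical(out2$individuals, out$individuals)
  # published family-shape example: 50 larvae in 37 families keep 37
  big <- genotype_dataset(matrix(rep(c(1L, 2L), 50), 50, 2, byrow = TRUE),
                          "L1", sprintf("l%02d", 1:50), rep("7", 50),
                          rep("larva", 50))
  fam_ids <- paste0("F", c(seq_len(37), sample(37, 13, replace = TRUE)))
  fams2 <- structure(list(families = data.frame(
    individual = big$individuals, family = fam_ids,
    stringsAsFactors = FALSE), pop = "7"), class = "family_assignment")
  expect_equal(length(prune_to_one_per_family(big, fams2)$individuals),
               length(unique(fam_ids)))
})

test_that("retained count equals family count plus adults, per population", {
  set.seed(64)
  cfg <- synth_config(n_sites = 3, migration_model = "island",
                      n_adults = c(5, 0, 8), n_larvae = c(10, 12, 0),
                      brood_lambda = 1, seed = 65)
  sim <- simulate_metapopulation(cfg)
  pruned <- prune_siblings(sim$dataset)
  summ <- attr(pruned, "family_summary")
  for (p in summ$pop) {
    n_adult <- sum(sim$dataset$pop == p & sim$dataset$stage == "adult")
    expect_equal(sum(pruned$pop == p),
                 summ$n_families[summ$pop == p] + n_adult)
  }
  # all-singleton families leave the dataset unchanged
  fa1 <- infer_fullsib_families(sim$dataset, "1")
  if (fa1$n_families == nrow(fa1$families))
    expect_equal(length(prune_to_one_per_family(sim$dataset, fa1)$individuals),
                 length(sim$dataset$individuals))
})

test_that("family-count error shrinks with more loci", {
  set.seed(66)
  bias <- function(L_keep) {
    err <- vapply(1:3, function(r) {
      cfg <- synth_config(n_adults = rep(0, 10),
                          n_larvae = c(24, rep(0, 9)), brood_lambda = 2,
                          migration_model = "island", seed = 6600 + r)
      sim <- simulate_metapopulation(cfg)
      ds <- subset_loci(sim$dataset, seq_len(L_keep))
      fa <- infer_fullsib_families(ds, "1")
      truth <- sim$truth$pedigree
      truth <- truth[truth$pop == "1", ]
      abs(fa$n_families - length(unique(truth$family)))
    }, numeric(1))
    mean(err)
  }
  expect_lte(bias(17), bias(8))
})
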