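# shared builders for small test datasets

# genotype_dataset from a list of per-individual genotype vectors (2L each)
make_ds <- function(rows, loci = NULL, pop = NULL, stage = NULL) {
  m <- do.call(rbind, rows)
  L <- ncol(m) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  n <- nrow(m)
  if (is.null(pop)) pop <- rep("A", n)
  if (is.null(stage)) stage <- rep("unknown", n)
  genotype_dataset(m, loci, paste0("i", seq_len(n)), pop, stage)
}

# n copies of one genotype row
geno_rows <- function(g, n) replicate(n, g, simplify = FALSE)

# random HWE dataset: k alleles per locus, Dirichlet-ish frequencies
random_hwe_ds <- function(n, L, k = 4, pops = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n * pops), function(i)
    unlist(lapply(seq_len(L), function(l) sample.int(k, 2, TRUE) + 100L)))
  make_ds(rows, pop = rep(LETTERS[seq_len(pops)], each = n))
}

# symmetric pairwise_matrix with random lower triangle
random_pm <- function(k, metric = "other", seed = NULL, rng = c(0, 1)) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, k, k)
  m[lower.tri(m)] <- runif(k * (k - 1) / 2, rng[1], rng[2])
  m <- m + t(m)
  pairwise_matrix(m, as.character(seq_len(k)), metric)
}

# pairwise response with MLPE-structured noise: u_i + u_j + e_ij
mlpe_response <- function(pred, beta, sd_u, sd_e) {
  k <- length(pred$sites)
  u <- rnorm(k, 0, sd_u)
  m <- matrix(0, k, k)
  prs <- t(combn(k, 2))
  for (q in seq_len(nrow(prs))) {
    i <- prs[q, 1]; j <- prs[q, 2]
    m[i, j] <- m[j, i] <- beta * pred$values[i, j] + u[i] + u[j] +
      rnorm(1, 0, sd_e)
  }
  pairwise_matrix(m, pred$sites, "other")
}

# single Wright-Fisher deme at size N for `gens` generations, k0 founder
# alleles, no mutation; returns a genotype_dataset of the whole deme
wf_single_deme <- function(N, gens, L = 17, k0 = 8, mu = 0) {
  demes <- list(matrix(sample.int(k0, N * 2 * L, TRUE) + 100L, N, 2 * L))
  fin <- wf_simulate(demes, matrix(1, 1, 1), gens, mu)[[1]]
  genotype_dataset(fin, paste0("L", seq_len(L)), paste0("i", seq_len(N)),
                   rep("A", N))
}
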