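# Per-population diversity statistics and marker screening.
#
# Conventions: expected heterozygosity is Nei's (1978) unbiased gene
# diversity 2n/(2n-1) * (1 - sum p^2); allelic richness uses exact
# hypergeometric rarefaction on gene counts; F-statistics follow
# Weir & Cockerham's (1984) variance components. Missing genotypes are
# dropped per locus (pairwise deletion).

#' Observed and unbiased expected heterozygosity
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label (`NULL` pools all individuals)
#' @return list with per-locus vectors `Ho`, `He`, `n` (called individuals)
#'   and the across-locus means `mean_Ho`, `mean_He`. Loci with fewer than
#'   two called individuals are excluded with a warning.
#' @export
heterozygosity <- function(ds, pop = NULL) {
  rows <- .pop_rows(ds, pop)
  L <- length(ds$loci)
  Ho <- He <- n <- setNames(rep(NA_real_, L), ds$loci)
  for (l in seq_len(L)) {
    j <- c(2L * l - 1L, 2L * l)
    a <- ds$alleles[rows, j, drop = FALSE]
    ok <- !is.na(a[, 1])
    nl <- sum(ok)
    if (nl < 2L) next
    n[l] <- nl
    Ho[l] <- mean(a[ok, 1] != a[ok, 2])
    p <- allele_counts(ds, l, pop) / (2 * nl)
    He[l] <- 2 * nl / (2 * nl - 1) * (1 - sum(p^2))
  }
  bad <- is.na(n)
  if (any(bad))
    warning("loci excluded (fewer than 2 called individuals): ",
            paste(ds$loci[bad], collapse = ", "))
  list(Ho = Ho, He = He, n = n,
       mean_Ho = mean(Ho, na.rm = TRUE), mean_He = mean(He, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of `g` gene copies, by the
#' exact hypergeometric formula `AR = sum_a [1 - C(N - n_a, g)/C(N, g)]`
#' on the observed gene counts (no resampling).
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label (`NULL` pools all)
#' @param g rarefaction size in gene copies (>= 2); defaults to the smallest
#'   per-locus called gene count across all populations of `ds`
#' @return named numeric vector of AR per locus (NA where no data)
#' @export
allelic_richness <- function(ds, pop = NULL, g = NULL) {
  if (is.null(g)) g <- min_gene_count(ds)
  if (g < 2) stop("rarefaction size g must be >= 2")
  L <- length(ds$loci)
  ar <- setNames(rep(NA_real_, L), ds$loci)
  for (l in seq_len(L)) {
    cnt <- allele_counts(ds, l, pop)
    N <- sum(cnt)
    if (N == 0) next
    if (g > N) stop("g exceeds called gene count (", N, ") at locus ", ds$loci[l])
    ar[l] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
  }
  ar
}

#' Smallest per-locus called gene count over all populations
#' @param ds a [genotype_dataset()]
#' @return integer
#' @export
min_gene_count <- function(ds) {
  m <- Inf
  for (p in pop_names(ds))
    for (l in seq_along(ds$loci))
      m <- min(m, sum(allele_counts(ds, l, p)))
  as.integer(m)
}

# Weir-Cockerham variance components summed over alleles of one locus.
# With r = 1 population only b and c are defined (a = 0).
.wc_locus <- function(freqs, het, ns) {
  # freqs: alleles x pops frequency matrix; het: alleles x pops observed
  # heterozygote proportion involving the allele; ns: per-pop sample sizes
  keep <- ns >= 1
  freqs <- freqs[, keep, drop = FALSE]; het <- het[, keep, drop = FALSE]
  ns <- ns[keep]
  r <- length(ns)
  if (r == 0) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(ns)
  a_tot <- b_tot <- c_tot <- 0
  nc <- if (r > 1) (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1) else NA_real_
  for (k in seq_len(nrow(freqs))) {
    p <- freqs[k, ]; h <- het[k, ]
    pbar <- sum(ns * p) / (r * nbar)
    hbar <- sum(ns * h) / (r * nbar)
    if (r > 1) {
      s2 <- sum(ns * (p - pbar)^2) / ((r - 1) * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    } else {
      a <- 0
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
    }
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

# per-locus WC components for the given populations; matrix loci x (a,b,c)
.wc_components <- function(ds, pops = pop_names(ds)) {
  L <- length(ds$loci)
  out <- matrix(0, L, 3, dimnames = list(ds$loci, c("a", "b", "c")))
  for (l in seq_len(L)) {
    j <- c(2L * l - 1L, 2L * l)
    alleles <- sort(unique(as.vector(ds$alleles[ds$pop %in% pops, j])))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) < 2) next
    r <- length(pops)
    freqs <- het <- matrix(0, length(alleles), r)
    ns <- numeric(r)
    for (ip in seq_len(r)) {
      a <- ds$alleles[ds$pop == pops[ip], j, drop = FALSE]
      a <- a[!is.na(a[, 1]), , drop = FALSE]
      ns[ip] <- nrow(a)
      if (!nrow(a)) next
      for (k in seq_along(alleles)) {
        freqs[k, ip] <- mean(c(a) == alleles[k])
        het[k, ip] <- mean(a[, 1] != a[, 2] &
                             (a[, 1] == alleles[k] | a[, 2] == alleles[k]))
      }
    }
    out[l, ] <- .wc_locus(freqs, het, ns)
  }
  out
}

#' Weir-Cockerham inbreeding coefficient
#'
#' Multi-locus small-sample-corrected f, from summed variance components:
#' `f = 1 - sum(c) / sum(b + c)`.
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label
#' @return numeric FIS estimate
#' @export
fis <- function(ds, pop) {
  comp <- .wc_components(ds, pop)
  s <- colSums(comp)
  if (s["b"] + s["c"] <= 0) return(NA_real_)
  unname(1 - s["c"] / (s["b"] + s["c"]))
}

#' Per-population diversity table
#'
#' One row per population: sample size, mean Ho, mean unbiased He, mean
#' rarefied allelic richness, and FIS.
#'
#' @param ds a [genotype_dataset()]
#' @param g rarefaction size (gene copies); default the dataset minimum
#' @return data frame
#' @export
diversity_table <- function(ds, g = NULL) {
  if (is.null(g)) g <- min_gene_count(ds)
  pops <- pop_names(ds)
  do.call(rbind, lapply(pops, function(p) {
    h <- suppressWarnings(heterozygosity(ds, p))
    data.frame(pop = p, n = sum(ds$pop == p),
               Ho = h$mean_Ho, He = h$mean_He,
               AR = mean(allelic_richness(ds, p, g), na.rm = TRUE),
               FIS = fis(ds, p), stringsAsFactors = FALSE)
  }))
}

#' Per-locus summary over the pooled sample
#'
#' @param ds a [genotype_dataset()]
#' @param g rarefaction size; default dataset minimum
#' @return data frame: locus, He, Ho, min/mean/max allele size, richness
#' @export
locus_summary <- function(ds, g = NULL) {
  if (is.null(g)) g <- min_gene_count(ds)
  h <- suppressWarnings(heterozygosity(ds, NULL))
  ar <- allelic_richness(ds, NULL, g)
  do.call(rbind, lapply(seq_along(ds$loci), function(l) {
    a <- as.vector(ds$alleles[, .locus_cols(ds, l)])
    a <- a[!is.na(a)]
    data.frame(locus = ds$loci[l], He = h$He[l], Ho = h$Ho[l],
               min = min(a), mean = mean(a), max = max(a),
               richness = ar[l], stringsAsFactors = FALSE)
  }))
}

# exact probability of a genotype table conditional on allele counts
# (Levene 1949): n! prod(n_a!) 2^h / ((2n)! prod(g!))
.log_table_prob <- function(g_het, g_hom, n, allele_cnt) {
  h <- sum(g_het)
  lfactorial(n) + sum(lfactorial(allele_cnt)) + h * log(2) -
    lfactorial(2 * n) - sum(lfactorial(c(g_het, g_hom)))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Probability-ordering exact test conditional on the observed allele
#' counts. Biallelic loci (and small multi-allelic tables) are fully
#' enumerated; larger tables use Monte Carlo pairing of the gene pool.
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label
#' @param locus locus name or index
#' @param mc_reps Monte Carlo draws when enumeration is infeasible
#' @param seed RNG seed for the Monte Carlo branch
#' @param max_tables enumeration budget (number of candidate tables)
#' @return p-value (1 for a monomorphic locus, by convention)
#' @export
hwe_exact_test <- function(ds, pop, locus, mc_reps = 10000, seed = NULL,
                           max_tables = 1e6) {
  j <- .locus_cols(ds, locus)
  a <- ds$alleles[.pop_rows(ds, pop), j, drop = FALSE]
  a <- a[!is.na(a[, 1]), , drop = FALSE]
  n <- nrow(a)
  if (n < 2) stop("fewer than 2 called individuals")
  alleles <- sort(unique(as.vector(a)))
  k <- length(alleles)
  if (k < 2) return(1)
  cnt <- tabulate(match(as.vector(a), alleles), k)
  ai <- match(a[, 1], alleles); bi <- match(a[, 2], alleles)
  obs <- table(factor(pmin(ai, bi), seq_len(k)), factor(pmax(ai, bi), seq_len(k)))
  obs_lp <- .table_lp(obs, n, cnt, k)

  enum <- .hwe_enumerate(cnt, n, k, max_tables)
  if (!is.null(enum)) {
    tot <- sum(exp(enum - max(enum)))
    p <- sum(exp(enum[enum <= obs_lp + 1e-9] - max(enum))) / tot
    return(min(1, p))
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- rep(seq_len(k), cnt)
  hits <- 0L
  for (r in seq_len(mc_reps)) {
    g <- matrix(sample(genes), ncol = 2)
    tab <- table(factor(pmin(g[, 1], g[, 2]), seq_len(k)),
                 factor(pmax(g[, 1], g[, 2]), seq_len(k)))
    if (.table_lp(tab, n, cnt, k) <= obs_lp + 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (mc_reps + 1)
}

.table_lp <- function(tab, n, cnt, k) {
  het <- tab[upper.tri(tab)]
  .log_table_prob(het, diag(tab), n, cnt)
}

# enumerate all genotype tables with the given allele counts; returns the
# vector of log-probabilities or NULL when the budget is exceeded
.hwe_enumerate <- function(cnt, n, k, max_tables) {
  if (k == 2) {
    # heterozygote count shares parity with min allele count
    hmax <- min(cnt)
    hs <- seq(hmax %% 2, hmax, by = 2)
    lp <- vapply(hs, function(h) {
      g11 <- (cnt[1] - h) / 2; g22 <- (cnt[2] - h) / 2
      .log_table_prob(h, c(g11, g22), n, cnt)
    }, numeric(1))
    return(lp)
  }
  env <- new.env()
  env$lp <- numeric(0); env$budget <- max_tables
  g <- matrix(0L, k, k)
  rec <- function(i, jj, rem) {
    if (env$budget <= 0) return(FALSE)
    if (i > k) {
      env$budget <- env$budget - 1
      env$lp <- c(env$lp, .log_table_prob(g[upper.tri(g)], diag(g), n, cnt))
      return(TRUE)
    }
    if (jj > k) {
      if (rem[i] != 0) return(TRUE)           # infeasible branch, prune
      return(rec(i + 1L, i + 1L, rem))
    }
    if (jj == i) {                             # homozygote cell, uses 2 genes
      ok <- TRUE
      for (x in 0:(rem[i] %/% 2L)) {
        g[i, i] <<- x
        r2 <- rem; r2[i] <- r2[i] - 2L * x
        ok <- rec(i, jj + 1L, r2)
        if (!ok) break
      }
      g[i, i] <<- 0L
      return(ok)
    }
    ok <- TRUE
    for (x in 0:min(rem[i], rem[jj])) {
      g[i, jj] <<- x
      r2 <- rem; r2[i] <- r2[i] - x; r2[jj] <- r2[jj] - x
      ok <- rec(i, jj + 1L, r2)
      if (!ok) break
    }
    g[i, jj] <<- 0L
    ok
  }
  done <- rec(1L, 1L, cnt)
  if (!done || env$budget <= 0) return(NULL)
  env$lp
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' G statistic on the two-locus genotype contingency table, with the null
#' distribution obtained by permuting one locus's genotypes across
#' individuals (complete cases only).
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label
#' @param locusA,locusB locus names or indices
#' @param permutations number of permutations
#' @param seed RNG seed
#' @return list: `G`, `p`, `n` (joint calls); `p` is `NA` with a warning
#'   when fewer than 5 joint calls are available
#' @export
ld_test <- function(ds, pop, locusA, locusB, permutations = 1000, seed = NULL) {
  ja <- .locus_cols(ds, locusA); jb <- .locus_cols(ds, locusB)
  rows <- .pop_rows(ds, pop)
  A <- ds$alleles[rows, ja, drop = FALSE]; B <- ds$alleles[rows, jb, drop = FALSE]
  ok <- !is.na(A[, 1]) & !is.na(B[, 1])
  A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  n <- nrow(A)
  if (n < 5) {
    warning("fewer than 5 joint calls; LD test undefined")
    return(list(G = NA_real_, p = NA_real_, n = n))
  }
  ga <- paste(A[, 1], A[, 2], sep = "/")
  gb <- paste(B[, 1], B[, 2], sep = "/")
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    stop("both loci must be polymorphic in the population")
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- tab[tab > 0]
    2 * sum(o * log(o / e[tab > 0]))
  }
  if (!is.null(seed)) set.seed(seed)
  G <- gstat(ga, gb)
  hits <- sum(vapply(seq_len(permutations),
                     function(i) gstat(ga, sample(gb)) >= G - 1e-12, logical(1)))
  list(G = G, p = (hits + 1) / (permutations + 1), n = n)
}

#' Bonferroni-corrected critical p-value
#' @param alpha family-wise error rate
#' @param m number of tests in the family
#' @return `alpha / m`
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Hardy-Weinberg screen over all population x locus combinations
#'
#' @param ds a [genotype_dataset()]
#' @param alpha family-wise error rate for the Bonferroni flag
#' @param ... passed to [hwe_exact_test()]
#' @return data frame: pop, locus, p, significant (Bonferroni over the full
#'   family of populations x loci)
#' @export
hwe_screen <- function(ds, alpha = 0.05, ...) {
  pops <- pop_names(ds)
  out <- expand.grid(pop = pops, locus = ds$loci,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$p <- mapply(function(p, l) {
    tryCatch(hwe_exact_test(ds, p, l, ...), error = function(e) NA_real_)
  }, out$pop, out$locus)
  crit <- bonferroni_alpha(alpha, sum(!is.na(out$p)))
  out$significant <- !is.na(out$p) & out$p < crit
  attr(out, "critical_p") <- crit
  out
}

#' Linkage-disequilibrium screen over all population x locus-pair combinations
#'
#' @param ds a [genotype_dataset()]
#' @param alpha family-wise error rate
#' @param permutations permutations per test
#' @param seed RNG seed
#' @return data frame: pop, locusA, locusB, p, significant
#' @export
ld_screen <- function(ds, alpha = 0.05, permutations = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- pop_names(ds)
  prs <- combn(ds$loci, 2)
  out <- do.call(rbind, lapply(pops, function(p)
    data.frame(pop = p, locusA = prs[1, ], locusB = prs[2, ],
               stringsAsFactors = FALSE)))
  out$p <- mapply(function(p, a, b) {
    tryCatch(suppressWarnings(
      ld_test(ds, p, a, b, permutations)$p), error = function(e) NA_real_)
  }, out$pop, out$locusA, out$locusB)
  crit <- bonferroni_alpha(alpha, sum(!is.na(out$p)))
  out$significant <- !is.na(out$p) & out$p < crit
  attr(out, "critical_p") <- crit
  out
}
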