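# Global and pairwise genetic differentiation, and two-level AMOVA.

#' Global Weir-Cockerham theta
#'
#' Multi-locus estimator as the ratio of summed variance components
#' `sum(a) / sum(a + b + c)`. Negative estimates are retained.
#'
#' @param ds a [genotype_dataset()] with >= 2 populations
#' @return numeric theta
#' @export
global_fst <- function(ds) {
  pops <- pop_names(ds)
  if (length(pops) < 2) stop("need at least 2 populations")
  comp <- .wc_components(ds, pops)
  s <- colSums(comp)
  tot <- sum(s)
  if (tot <= 0) stop("all loci monomorphic: theta undefined")
  unname(s["a"] / tot)
}

#' Hedrick's standardized differentiation G'ST
#'
#' `G'ST = GST / GST_max` with `GST_max = ((k-1)(1-HS)) / (k-1+HS)` for `k`
#' populations; HS and HT are averaged over loci before the ratio.
#'
#' @param ds a [genotype_dataset()] with >= 2 populations
#' @return numeric G'ST
#' @export
hedrick_gst <- function(ds) {
  pops <- pop_names(ds)
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  HS <- HT <- numeric(0)
  for (l in seq_along(ds$loci)) {
    per_pop <- lapply(pops, function(p) allele_counts(ds, l, p))
    ns <- vapply(per_pop, sum, numeric(1))
    if (any(ns < 2)) next
    alleles <- sort(unique(unlist(lapply(per_pop, names))))
    freqs <- vapply(per_pop, function(cnt) {
      f <- setNames(rep(0, length(alleles)), alleles)
      f[names(cnt)] <- cnt / sum(cnt)
      f
    }, numeric(length(alleles)))
    freqs <- matrix(freqs, nrow = length(alleles))
    hs_l <- mean(vapply(seq_len(k), function(i) {
      n <- ns[i] / 2
      2 * n / (2 * n - 1) * (1 - sum(freqs[, i]^2))
    }, numeric(1)))
    pbar <- rowMeans(freqs)
    ht_l <- 1 - sum(pbar^2)
    HS <- c(HS, hs_l); HT <- c(HT, ht_l)
  }
  HSm <- mean(HS); HTm <- mean(HT)
  if (HTm <= 0) stop("no polymorphism: G'ST undefined")
  if (HSm >= 1) stop("HS at ceiling: G'ST undefined")
  gst <- (HTm - HSm) / HTm
  gst_max <- ((k - 1) * (1 - HSm)) / (k - 1 + HSm)
  gst / gst_max
}

#' Pairwise Weir-Cockerham theta with locus-bootstrap significance
#'
#' Theta per population pair; significance of difference from zero by
#' bootstrapping loci (p = fraction of bootstrap replicates <= 0). The
#' Bonferroni flag uses `0.05 / (number of pairs)`.
#'
#' @param ds a [genotype_dataset()]
#' @param bootstraps bootstrap replicates over loci
#' @param seed RNG seed
#' @param alpha family-wise error rate for the Bonferroni flag
#' @return a [pairwise_matrix()] (metric `"fst"`) with `p` matrix and a
#'   `significant` attribute (logical matrix after Bonferroni)
#' @export
pairwise_fst <- function(ds, bootstraps = 1000, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  pops <- pop_names(ds)
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  theta <- pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(theta) <- 0
  L <- length(ds$loci)
  npairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    comp <- .wc_components(ds, c(pops[i], pops[j]))
    tot <- rowSums(comp)
    use <- tot != 0
    if (!any(use)) next                      # no shared polymorphism
    theta[i, j] <- theta[j, i] <- sum(comp[use, "a"]) / sum(tot[use])
    if (bootstraps > 0) {
      idx <- which(use)
      bt <- vapply(seq_len(bootstraps), function(b) {
        s <- sample(idx, length(idx), replace = TRUE)
        sum(comp[s, "a"]) / sum(tot[s])
      }, numeric(1))
      pmat[i, j] <- pmat[j, i] <- mean(bt <= 0)
    }
  }
  m <- pairwise_matrix(theta, pops, "fst", p = pmat)
  crit <- bonferroni_alpha(alpha, npairs)
  attr(m, "critical_p") <- crit
  attr(m, "significant") <- !is.na(pmat) & pmat < crit
  m
}

#' Slatkin's linearized FST
#'
#' Elementwise `FST / (1 - FST)`; negative inputs pass through the same
#' transform. Cells at exactly 1 map to `Inf` with a warning.
#'
#' @param m a [pairwise_matrix()] of FST values
#' @return a [pairwise_matrix()] with metric `"linfst"`
#' @export
linearize_fst <- function(m) {
  v <- if (inherits(m, "pairwise_matrix")) m$values else as.matrix(m)
  if (any(v == 1, na.rm = TRUE)) warning("FST = 1 linearizes to Inf")
  out <- v / (1 - v)
  diag(out) <- 0
  pairwise_matrix(out, rownames(v), "linfst")
}

#' Shared-allele genetic distance between populations
#'
#' `Dps = 1 - mean over loci of sum_a min(p_a, q_a)` computed on
#' population allele frequencies.
#'
#' @param ds a [genotype_dataset()]
#' @return a [pairwise_matrix()] with metric `"dps"`
#' @export
dps_matrix <- function(ds) {
  pops <- pop_names(ds)
  k <- length(pops)
  L <- length(ds$loci)
  # per-locus frequency tables per pop
  freqs <- lapply(pops, function(p) lapply(seq_len(L), function(l) {
    cnt <- allele_counts(ds, l, p)
    if (sum(cnt)) cnt / sum(cnt) else cnt
  }))
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    sh <- vapply(seq_len(L), function(l) {
      p <- freqs[[i]][[l]]; q <- freqs[[j]][[l]]
      if (!length(p) || !length(q)) return(NA_real_)
      alleles <- union(names(p), names(q))
      pv <- setNames(rep(0, length(alleles)), alleles); pv[names(p)] <- p
      qv <- setNames(rep(0, length(alleles)), alleles); qv[names(q)] <- q
      sum(pmin(pv, qv))
    }, numeric(1))
    d[i, j] <- d[j, i] <- 1 - mean(sh, na.rm = TRUE)
  }
  pairwise_matrix(d, pops, "dps")
}

# gene-level indicator representation of one locus: list(G = genes x alleles
# 0/1 matrix, ind = individual index per gene, ok = called individuals)
.locus_indicators <- function(ds, l) {
  j <- .locus_cols(ds, l)
  a <- ds$alleles[, j, drop = FALSE]
  ok <- which(!is.na(a[, 1]))
  if (!length(ok)) return(NULL)
  genes <- c(rbind(a[ok, 1], a[ok, 2]))
  alleles <- sort(unique(genes))
  if (length(alleles) < 2) return(NULL)
  G <- matrix(0L, length(genes), length(alleles))
  G[cbind(seq_along(genes), match(genes, alleles))] <- 1L
  list(G = G, ind = rep(ok, each = 2L))
}

# nested gene-level variance components for one locus given pop assignment;
# returns c(sig_a, sig_b, sig_w) summed over alleles
.amova_locus <- function(G, ind, pop_of_ind) {
  pop <- pop_of_ind[ind]
  pops <- unique(pop)
  r <- length(pops)
  M <- nrow(G)                                 # total genes
  Mp <- as.vector(table(factor(pop, pops)))    # genes per pop
  nind <- length(unique(ind))
  ind_f <- factor(ind)
  pop_f <- factor(pop, pops)
  mean_tot <- colMeans(G)
  mean_ind <- rowsum(G, ind_f) / 2
  mean_pop <- rowsum(G, pop_f) / Mp
  ind_pop <- pop_of_ind[as.integer(levels(ind_f))]
  SS_wi <- sum((G - mean_ind[ind_f, , drop = FALSE])^2)
  SS_ai <- 2 * sum((mean_ind - mean_pop[factor(ind_pop, pops), , drop = FALSE])^2)
  SS_ap <- sum(Mp * rowSums((mean_pop - rep(mean_tot, each = r))^2))
  df_ap <- r - 1; df_ai <- nind - r; df_wi <- nind
  MS_wi <- SS_wi / df_wi
  MS_ai <- if (df_ai > 0) SS_ai / df_ai else NA_real_
  MS_ap <- if (df_ap > 0) SS_ap / df_ap else NA_real_
  ncoef <- (M - sum(Mp^2) / M) / df_ap
  sig_w <- MS_wi
  sig_b <- if (is.na(MS_ai)) 0 else (MS_ai - MS_wi) / 2
  sig_a <- if (is.na(MS_ap) || ncoef <= 0) 0 else (MS_ap - MS_ai) / ncoef
  c(a = sig_a, b = sig_b, w = sig_w)
}

#' Two-level analysis of molecular variance
#'
#' Partitions gene-level variance into among-population, among-individual
#' (within populations), and within-individual components, using
#' allele-identity distances. Significance of the among-population
#' component is assessed by permuting individuals among populations; the
#' among-individual component by permuting gene copies among individuals
#' within populations.
#'
#' @param ds a [genotype_dataset()] with >= 2 populations
#' @param permutations permutation replicates
#' @param seed RNG seed
#' @return list of class `amova_result`: `components` (variance components),
#'   `percent`, `p` (p-values for the two testable levels)
#' @export
amova <- function(ds, permutations = 999, seed = NULL) {
  if (length(pop_names(ds)) < 2)
    stop("AMOVA among populations needs >= 2 populations")
  if (!is.null(seed)) set.seed(seed)
  locs <- lapply(seq_along(ds$loci), function(l) .locus_indicators(ds, l))
  locs <- locs[!vapply(locs, is.null, logical(1))]
  if (!length(locs)) stop("no polymorphic loci")
  comp_for <- function(pop_assign, locs_use = locs) {
    Reduce(`+`, lapply(locs_use, function(x)
      .amova_locus(x$G, x$ind, pop_assign)))
  }
  obs <- comp_for(ds$pop)
  tot <- sum(pmax(obs, 0))
  pct <- 100 * pmax(obs, 0) / tot
  # permutation: individuals among populations
  n <- length(ds$individuals)
  hits_a <- 0L
  for (b in seq_len(permutations)) {
    perm <- ds$pop[sample(n)]
    if (comp_for(perm)["a"] >= obs["a"] - 1e-12) hits_a <- hits_a + 1L
  }
  # permutation: gene copies among individuals within populations
  hits_b <- 0L
  for (b in seq_len(permutations)) {
    locs_p <- lapply(locs, function(x) {
      pop_gene <- ds$pop[x$ind]
      ord <- seq_along(x$ind)
      for (p in unique(pop_gene)) {
        w <- which(pop_gene == p)
        ord[w] <- w[sample(length(w))]
      }
      list(G = x$G[ord, , drop = FALSE], ind = x$ind)
    })
    if (comp_for(ds$pop, locs_p)["b"] >= obs["b"] - 1e-12) hits_b <- hits_b + 1L
  }
  p <- c(among_pops = (hits_a + 1) / (permutations + 1),
         among_individuals = (hits_b + 1) / (permutations + 1))
  structure(list(
    components = setNames(obs, c("among_pops", "among_individuals",
                                 "within_individuals")),
    percent = setNames(pct, c("among_pops", "among_individuals",
                              "within_individuals")),
    p = p), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components:\n")
  df <- data.frame(component = names(x$components),
                   sigma2 = round(unname(x$components), 5),
                   percent = round(unname(x$percent), 2),
                   p = c(round(unname(x$p), 4), NA))
  print(df, row.names = FALSE)
  invisible(x)
}
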