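# Bottleneck detection: heterozygosity excess under the infinite allele
# model, and the allele-frequency mode-shift diagnostic.
#
# A recently bottlenecked population transiently shows more gene diversity
# than expected at mutation-drift equilibrium for its (rapidly reduced)
# allele count. For each locus we simulate the equilibrium distribution of
# expected heterozygosity conditional on the observed allele count k and
# gene sample size 2n (Ewens sampling formula under the IAM -- exact and
# theta-free given k), standardize the observed value, and combine loci
# with a one-tailed Wilcoxon signed-rank test for excess. The TPM's
# geometric-step variance parameter is accepted for interface parity but is
# inert when the IAM fraction is 1, as here.

# core test on per-locus (k, 2n, He_obs) triples; exported pieces wrap it.
# DH is reported per locus; the Wilcoxon is taken on the centered
# conditional quantiles u - 1/2 (u = midrank of He_obs among the
# equilibrium draws), which are uniform -- hence symmetric -- under the
# null, where the left-skewed DH values themselves are not.
.het_excess_core <- function(k, n2, he_obs, replicates) {
  use <- which(k >= 2)
  if (length(use) < 4)
    stop("heterozygosity-excess test needs >= 4 polymorphic loci")
  # one equilibrium simulation per distinct (2n, k) pair, drawn in sorted
  # order so that results do not depend on locus ordering
  combos <- unique(cbind(n2[use], k[use]))
  combos <- combos[order(combos[, 1], combos[, 2]), , drop = FALSE]
  sims <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos)))
    sims[[ci]] <- esf_he_conditional(combos[ci, 1], combos[ci, 2],
                                     replicates)
  dh <- u <- rep(NA_real_, length(use))
  for (ix in seq_along(use)) {
    i <- use[ix]
    ci <- which(combos[, 1] == n2[i] & combos[, 2] == k[i])
    sim <- sims[[ci]]
    s <- sd(sim)
    if (s == 0) next
    dh[ix] <- (he_obs[i] - mean(sim)) / s
    u[ix] <- (sum(sim < he_obs[i]) + 0.5 * sum(sim == he_obs[i]) + 0.5) /
      (replicates + 1)
  }
  ok <- !is.na(dh)
  if (sum(ok) < 4) stop("too few informative loci after simulation")
  w <- suppressWarnings(wilcox.test(u[ok] - 0.5, alternative = "greater"))
  list(dh = dh[ok], u = u[ok], p = w$p.value)
}

#' Heterozygosity-excess bottleneck test (Wilcoxon, IAM)
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label
#' @param replicates equilibrium simulation replicates per locus
#' @param seed RNG seed
#' @param geometric_variance variance of the TPM geometric step
#'   distribution; recorded but inert at 100% IAM
#' @return object of class `bottleneck_result`: per-locus standardized
#'   differences `dh`, one-tailed Wilcoxon `p` (excess), `mode_shift`
#'   verdict, `replicates`, `seed`
#' @export
heterozygosity_excess_test <- function(ds, pop, replicates = 1000,
                                       seed = NULL,
                                       geometric_variance = 0.36) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(ds$loci)
  k <- n2 <- integer(L); he <- numeric(L)
  for (l in seq_len(L)) {
    cnt <- allele_counts(ds, l, pop)
    k[l] <- length(cnt)
    n2[l] <- sum(cnt)
    he[l] <- if (n2[l] >= 2)
      n2[l] / (n2[l] - 1) * (1 - sum((cnt / n2[l])^2)) else NA_real_
  }
  core <- .het_excess_core(k, n2, he, replicates)
  structure(list(pop = pop, dh = core$dh, p = core$p,
                 mode_shift = mode_shift_test(ds, pop),
                 replicates = replicates, seed = seed,
                 geometric_variance = geometric_variance),
            class = "bottleneck_result")
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat(sprintf("pop %s: Wilcoxon heterozygosity-excess p = %.4f; mode shift: %s\n",
              x$pop, x$p, x$mode_shift))
  invisible(x)
}

#' Allele-frequency mode-shift test
#'
#' Pools alleles across loci into ten frequency classes of width 0.1; a
#' population at mutation-drift equilibrium shows an L-shape with the
#' rarest class (0-0.1) most populous. Verdict is `"shifted"` iff that
#' class is not the mode.
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label
#' @return `"normal L-shape"` or `"shifted"`
#' @export
mode_shift_test <- function(ds, pop) {
  freqs <- unlist(lapply(seq_along(ds$loci), function(l) {
    cnt <- allele_counts(ds, l, pop)
    if (length(cnt) < 2) return(numeric(0))
    cnt / sum(cnt)
  }))
  if (!length(freqs)) stop("no polymorphic loci")
  classes <- cut(freqs, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  tab <- table(classes)
  if (which.max(tab) == 1L) "normal L-shape" else "shifted"
}

#' Bottleneck test table over all populations
#'
#' @param ds a [genotype_dataset()]
#' @param replicates simulation replicates per locus
#' @param seed RNG seed
#' @param alpha family-wise error rate for the Bonferroni flag
#' @return data frame: pop, p, mode_shift, significant
#' @export
bottleneck_table <- function(ds, replicates = 1000, seed = NULL,
                             alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  pops <- pop_names(ds)
  res <- lapply(pops, function(p)
    heterozygosity_excess_test(ds, p, replicates))
  crit <- bonferroni_alpha(alpha, length(pops))
  out <- data.frame(pop = pops,
                    p = vapply(res, `[[`, numeric(1), "p"),
                    mode_shift = vapply(res, `[[`, character(1), "mode_shift"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < crit
  attr(out, "critical_p") <- crit
  out
}
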