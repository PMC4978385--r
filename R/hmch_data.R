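# Published reference values for the Huachuca Mountains / Canelo Hills
# Arizona treefrog breeding-site network, bundled as plain data frames so
# that the summary calculations built on them (hierarchical total Ne,
# linearized FST, sample accounting, multiple-testing constants) can be
# reproduced without the deposited raw genotypes.

#' Published population attributes of the treefrog breeding-site network
#'
#' One row per sampling site: sample sizes (total / adults / larvae),
#' sibling-pruned sizes, mean observed and expected heterozygosity,
#' rarefied allelic richness, and the LD-based effective population size
#' with its jackknifed 95% CI (`Inf` marks infinite upper bounds). Sites
#' "2" and "5" were too small for population-level analyses and carry `NA`
#' statistics.
#'
#' @return data frame with columns `pop`, `n_total`, `n_adults`,
#'   `n_larvae`, `n_larvae_pruned`, `n_total_pruned`, `Ho`, `He`, `AR`,
#'   `ne`, `ne_low`, `ne_high`
#' @export
hmch_population_table <- function() {
  data.frame(
    pop = c("1", "3", "4", "6", "7", "8", "9", "10", "2", "5"),
    n_total = c(19, 43, 48, 34, 50, 28, 49, 22, 5, 1),
    n_adults = c(19, 0, 0, 6, 0, 0, 29, 22, 5, 1),
    n_larvae = c(0, 43, 48, 28, 50, 28, 20, 0, 0, 0),
    n_larvae_pruned = c(0, 30, 23, 14, 37, 24, 11, 0, 0, 0),
    n_total_pruned = c(19, 30, 23, 20, 37, 24, 40, 22, 5, 1),
    Ho = c(0.69, 0.67, 0.65, 0.69, 0.70, 0.66, 0.69, 0.67, NA, NA),
    He = c(0.73, 0.69, 0.67, 0.73, 0.74, 0.71, 0.68, 0.74, NA, NA),
    AR = c(6.1, 5.8, 5.5, 6.0, 5.7, 6.2, 5.5, 6.2, NA, NA),
    ne = c(140.5, 277.9, 79.0, 51.7, 109.1, 43.3, 199.2, 32.5, NA, NA),
    ne_low = c(54.6, 88.0, 36.5, 31.4, 56.8, 29.4, 65.8, 23.1, NA, NA),
    ne_high = c(Inf, Inf, 7999.7, 120.0, 526.0, 74.9, 415.3, 50.4, NA, NA),
    stringsAsFactors = FALSE)
}

#' Published global differentiation of the network
#' @return named numeric vector: `fst`, `gst_prime`
#' @export
hmch_global_differentiation <- function() c(fst = 0.04, gst_prime = 0.19)

# lower-triangle helper: build a symmetric pairwise_matrix from the
# published lower triangle (row-major over pops 3..10 vs earlier pops)
.hmch_lower <- function(vals, metric) {
  pops <- c("1", "3", "4", "6", "7", "8", "9", "10")
  m <- matrix(NA_real_, 8, 8, dimnames = list(pops, pops))
  diag(m) <- 0
  idx <- 1
  for (i in 2:8) for (j in seq_len(i - 1)) {
    m[i, j] <- vals[idx]
    idx <- idx + 1
  }
  pairwise_matrix(m, pops, metric)
}

#' Published pairwise FST matrix
#' @return a [pairwise_matrix()] (metric `"fst"`) over the 8 analyzed sites
#' @export
hmch_pairwise_fst <- function() {
  .hmch_lower(c(
    0.0342,
    0.0245, 0.0348,
    0.0136, 0.0357, 0.0218,
    0.0247, 0.0464, 0.0362, 0.0086,
    0.0396, 0.0585, 0.0527, 0.0151, 0.0212,
    0.0621, 0.0891, 0.0670, 0.0345, 0.0291, 0.0301,
    0.0382, 0.0883, 0.0749, 0.0292, 0.0382, 0.0390, 0.0444), "fst")
}

#' Published linearized FST matrix
#' @return a [pairwise_matrix()] (metric `"linfst"`)
#' @export
hmch_linfst <- function() {
  .hmch_lower(c(
    0.035,
    0.025, 0.036,
    0.014, 0.037, 0.022,
    0.025, 0.049, 0.038, 0.009,
    0.041, 0.062, 0.056, 0.015, 0.022,
    0.066, 0.098, 0.072, 0.036, 0.030, 0.031,
    0.040, 0.097, 0.081, 0.030, 0.040, 0.041, 0.046), "linfst")
}

#' Published shared-allele distance (Dps) matrix
#' @return a [pairwise_matrix()] (metric `"dps"`)
#' @export
hmch_dps <- function() {
  .hmch_lower(c(
    0.278,
    0.256, 0.275,
    0.237, 0.286, 0.249,
    0.249, 0.293, 0.277, 0.212,
    0.302, 0.315, 0.311, 0.244, 0.240,
    0.333, 0.380, 0.330, 0.269, 0.246, 0.253,
    0.309, 0.392, 0.370, 0.277, 0.303, 0.307, 0.283), "dps")
}

#' Published larval full-sib family structure
#' @return data frame: pop, n_families, mean_family_size, max_sibs
#' @export
hmch_family_table <- function() {
  data.frame(pop = c("3", "4", "6", "7", "8", "9"),
             n_families = c(30, 23, 20, 37, 24, 40),
             mean_family_size = c(1.43, 2.09, 1.70, 1.35, 1.17, 1.23),
             max_sibs = c(7, 5, 6, 3, 2, 3),
             stringsAsFactors = FALSE)
}
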