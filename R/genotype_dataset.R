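#' Diploid microsatellite genotype dataset
#'
#' Container for diploid allele-size calls at microsatellite loci, with a
#' population label and life stage for every individual. Alleles are stored
#' as an integer matrix with two columns per locus; a genotype is either
#' fully called (two positive allele sizes) or missing (both `NA`) -- a
#' half-called genotype is treated as missing, the conservative convention
#' for fragment data. Heterozygotes are stored orientation-free: the smaller
#' allele always sits in the first column.
#'
#' @param alleles integer matrix, `n x 2L`: columns `2l-1, 2l` hold the two
#'   allele sizes of locus `l`.
#' @param loci character vector of `L` locus names.
#' @param individuals character vector of `n` unique individual ids.
#' @param pop character vector of population labels, one per individual.
#' @param stage life stage per individual: `"adult"`, `"larva"` or
#'   `"unknown"` (default).
#'
#' @return An object of class `genotype_dataset` with elements `alleles`,
#'   `loci`, `individuals`, `pop`, `stage`.
#' @export
genotype_dataset <- function(alleles, loci, individuals, pop,
                             stage = rep("unknown", length(individuals))) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- length(individuals)
  L <- length(loci)
  if (nrow(alleles) != n || ncol(alleles) != 2L * L)
    stop("alleles must be an n x 2L matrix matching individuals and loci")
  if (anyDuplicated(individuals))
    stop("individual ids must be unique")
  if (length(pop) != n)
    stop("pop must give one label per individual")
  if (n > 0) {
    stage <- match.arg(stage, c("adult", "larva", "unknown"),
                       several.ok = TRUE)
    if (length(stage) == 1L) stage <- rep(stage, n)
  } else stage <- character(0)
  if (any(alleles <= 0L, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  # enforce per-locus missingness and orientation-free storage
  for (l in seq_len(L)) {
    j <- c(2L * l - 1L, 2L * l)
    half <- xor(is.na(alleles[, j[1]]), is.na(alleles[, j[2]]))
    if (any(half)) alleles[half, j] <- NA_integer_
    swap <- !is.na(alleles[, j[1]]) & alleles[, j[1]] > alleles[, j[2]]
    if (any(swap)) {
      tmp <- alleles[swap, j[1]]
      alleles[swap, j[1]] <- alleles[swap, j[2]]
      alleles[swap, j[2]] <- tmp
    }
  }
  dimnames(alleles) <- list(individuals,
                            paste0(rep(loci, each = 2L), c(".1", ".2")))
  structure(list(alleles = alleles, loci = loci,
                 individuals = individuals,
                 pop = as.character(pop), stage = stage),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$individuals), "individuals,",
      length(x$loci), "loci,", length(unique(x$pop)), "populations\n")
  tab <- table(x$pop)
  cat("  per population:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$alleles))))
  invisible(x)
}

# column indices for one locus
.locus_cols <- function(ds, locus) {
  l <- if (is.character(locus)) match(locus, ds$loci) else as.integer(locus)
  if (is.na(l) || l < 1L || l > length(ds$loci)) stop("unknown locus: ", locus)
  c(2L * l - 1L, 2L * l)
}

.pop_rows <- function(ds, pop) {
  if (is.null(pop)) seq_along(ds$individuals) else which(ds$pop %in% pop)
}

#' Population labels in order of first appearance
#' @param ds a [genotype_dataset()]
#' @return character vector
#' @export
pop_names <- function(ds) unique(ds$pop)

#' Per-individual fraction of missing locus calls
#' @param ds a [genotype_dataset()]
#' @return named numeric vector in \[0, 1\]
#' @export
missing_fraction <- function(ds) {
  L <- length(ds$loci)
  miss <- is.na(ds$alleles[, seq(1L, 2L * L, by = 2L), drop = FALSE])
  setNames(rowMeans(miss), ds$individuals)
}

#' Gene (allele copy) counts at a locus
#'
#' @param ds a [genotype_dataset()]
#' @param locus locus name or index
#' @param pop population label(s), or `NULL` for all individuals
#' @return named integer vector: count of each allele size among called genes
#' @export
allele_counts <- function(ds, locus, pop = NULL) {
  j <- .locus_cols(ds, locus)
  a <- ds$alleles[.pop_rows(ds, pop), j]
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  tab <- table(a)
  setNames(as.integer(tab), names(tab))
}

#' Subset a genotype dataset by individuals
#' @param ds a [genotype_dataset()]
#' @param keep logical, integer, or character index of individuals to retain
#' @return a [genotype_dataset()]
#' @export
subset_individuals <- function(ds, keep) {
  if (is.character(keep)) keep <- match(keep, ds$individuals)
  genotype_dataset(ds$alleles[keep, , drop = FALSE], ds$loci,
                   ds$individuals[keep], ds$pop[keep], ds$stage[keep])
}

#' Drop individuals with too much missing data
#'
#' Individuals whose fraction of missing locus calls exceeds `max_missing`
#' are removed -- the standard quality screen for multi-attempt microsatellite
#' genotyping (a 25% ceiling by default).
#'
#' @param ds a [genotype_dataset()]
#' @param max_missing maximum tolerated missing fraction, in \[0, 1\]
#' @return the filtered dataset, with a `report` attribute: data frame of the
#'   removed individuals (`individual`, `pop`, `missing`)
#' @export
filter_missing <- function(ds, max_missing = 0.25) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  mf <- missing_fraction(ds)
  drop <- mf > max_missing
  out <- subset_individuals(ds, !drop)
  attr(out, "report") <- data.frame(individual = ds$individuals[drop],
                                    pop = ds$pop[drop],
                                    missing = unname(mf[drop]),
                                    stringsAsFactors = FALSE)
  out
}

#' Exclude populations with too few individuals
#'
#' Sites sampled too thinly for population-level statistics are dropped
#' wholesale (the study design retains only sites with roughly 19+ samples;
#' the default threshold of 10 reproduces that split).
#'
#' @param ds a [genotype_dataset()]
#' @param min_n smallest retained population size (>= 2)
#' @return filtered dataset with a `report` attribute listing excluded
#'   populations and their sizes
#' @export
exclude_small_pops <- function(ds, min_n = 10) {
  stopifnot(min_n >= 2)
  tab <- table(ds$pop)[pop_names(ds)]
  small <- names(tab)[tab < min_n]
  if (length(small) == length(tab)) stop("all populations below min_n")
  out <- subset_individuals(ds, !(ds$pop %in% small))
  attr(out, "report") <- data.frame(pop = small,
                                    n = as.integer(tab[small]),
                                    stringsAsFactors = FALSE)
  out
}

#' Subset a genotype dataset by loci
#' @param ds a [genotype_dataset()]
#' @param loci locus names or indices to retain
#' @return a [genotype_dataset()]
#' @export
subset_loci <- function(ds, loci) {
  if (is.character(loci)) loci <- match(loci, ds$loci)
  cols <- as.vector(rbind(2L * loci - 1L, 2L * loci))
  genotype_dataset(ds$alleles[, cols, drop = FALSE], ds$loci[loci],
                   ds$individuals, ds$pop, ds$stage)
}
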