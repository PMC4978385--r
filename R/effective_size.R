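# Linkage-disequilibrium effective population size (single-sample, random
# mating) and the hierarchical total Ne over a structured set of sites.

# allele-count matrix (individuals x alleles) for one locus; NA rows = no call
.count_matrix <- function(ds, rows, l) {
  j <- c(2L * l - 1L, 2L * l)
  a <- ds$alleles[rows, j, drop = FALSE]
  alleles <- sort(unique(as.vector(a)))
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) < 2) return(NULL)
  X <- matrix(NA_real_, nrow(a), length(alleles),
              dimnames = list(NULL, alleles))
  ok <- !is.na(a[, 1])
  for (k in seq_along(alleles))
    X[ok, k] <- (a[ok, 1] == alleles[k]) + (a[ok, 2] == alleles[k])
  X
}

# mean Burrows r^2 over allele pairs for one locus pair (complete cases)
.burrows_pair <- function(X, Y, pcrit) {
  ok <- !is.na(X[, 1]) & !is.na(Y[, 1])
  S <- sum(ok)
  if (S < 3) return(NULL)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  p <- colMeans(X) / 2; q <- colMeans(Y) / 2
  ua <- p >= pcrit & p <= 1 - pcrit
  ub <- q >= pcrit & q <= 1 - pcrit
  if (!any(ua) || !any(ub)) return(NULL)
  X <- X[, ua, drop = FALSE]; Y <- Y[, ub, drop = FALSE]
  p <- p[ua]; q <- q[ub]
  # Burrows composite disequilibrium with the S/(S-1) correction
  D <- (crossprod(X, Y) / S - outer(2 * p, 2 * q)) / 2 * (S / (S - 1))
  r2 <- D^2 / outer(p * (1 - p), q * (1 - q))
  list(r2 = as.vector(r2), S = S)
}

# expected sampling value of r^2 under random mating (Waples 2006)
.exp_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

# solve the drift expectation for Ne (random-mating quadratic solution);
# Inf when the corrected r2 is non-positive, and a clamped discriminant
# when drift signal is too strong for the quadratic's range
.solve_ne <- function(r2d, S) {
  if (is.na(r2d) || r2d <= 0) return(Inf)
  if (S >= 30) (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * r2d))) / (2 * r2d)
  else (0.308 + sqrt(max(0, 0.308^2 - 2.08 * r2d))) / (2 * r2d)
}

#' LD (single-sample) effective population size
#'
#' Burrows composite disequilibrium r-squared averaged over allele pairs of
#' all locus pairs (alleles rarer than `pcrit` excluded; per-pair complete
#' cases), corrected by the expected sampling value for the harmonic-mean
#' sample size and inverted under the random-mating drift expectation.
#' The confidence interval jackknifes locus pairs through a chi-square
#' approximation with jackknife-effective degrees of freedom, which yields
#' infinite upper bounds when drift signal is weak.
#'
#' @param ds a [genotype_dataset()]
#' @param pop population label
#' @param pcrit minimum allele frequency retained (default 0.02)
#' @param seed unused (the estimator is deterministic); kept for interface
#'   symmetry with the stochastic stages
#' @return object of class `ne_estimate`: `pop`, `ne`, `ci_low`, `ci_high`,
#'   `r2`, `exp_r2`, `S`, `n_pairs`, `pcrit`, `method`
#' @export
ldne <- function(ds, pop, pcrit = 0.02, seed = NULL) {
  rows <- .pop_rows(ds, pop)
  if (length(rows) < 10) stop("LDNe needs >= 10 individuals")
  L <- length(ds$loci)
  cms <- lapply(seq_len(L), function(l) .count_matrix(ds, rows, l))
  usable <- which(!vapply(cms, is.null, logical(1)))
  if (length(usable) < 2) stop("fewer than 2 polymorphic loci")
  pair_r2 <- pair_w <- pair_S <- numeric(0)
  pair_l1 <- pair_l2 <- integer(0)
  for (ii in seq_along(usable)[-length(usable)]) {
    for (jj in seq((ii + 1), length(usable))) {
      b <- .burrows_pair(cms[[usable[ii]]], cms[[usable[jj]]], pcrit)
      if (is.null(b)) next
      pair_r2 <- c(pair_r2, mean(b$r2))
      pair_w <- c(pair_w, length(b$r2))
      pair_S <- c(pair_S, b$S)
      pair_l1 <- c(pair_l1, usable[ii])
      pair_l2 <- c(pair_l2, usable[jj])
    }
  }
  np <- length(pair_r2)
  if (np < 2) stop("fewer than 2 usable locus pairs")
  wsum <- sum(pair_w)
  r2 <- sum(pair_w * pair_r2) / wsum
  S <- wsum / sum(pair_w / pair_S)            # harmonic mean, comparison-weighted
  er2 <- .exp_r2(S)
  ne <- .solve_ne(r2 - er2, S)
  # delete-one-locus block jackknife on the weighted mean r2: locus pairs
  # sharing a locus are correlated, so whole loci are dropped at a time
  jl <- unique(c(pair_l1, pair_l2))
  jack <- vapply(jl, function(l) {
    keep <- pair_l1 != l & pair_l2 != l
    sum(pair_w[keep] * pair_r2[keep]) / sum(pair_w[keep])
  }, numeric(1))
  nj <- length(jack)
  varj <- (nj - 1) / nj * sum((jack - mean(jack))^2)
  if (varj > 0) {
    phi <- max(2, 2 * r2^2 / varj)            # effective chi-square df
    r2_lo <- phi * r2 / qchisq(0.975, phi)
    r2_hi <- phi * r2 / qchisq(0.025, phi)
    ci <- c(.solve_ne(r2_hi - er2, S), .solve_ne(r2_lo - er2, S))
  } else ci <- c(ne, ne)
  structure(list(pop = if (is.null(pop)) "all" else pop,
                 ne = ne, ci_low = ci[1], ci_high = ci[2],
                 r2 = r2, exp_r2 = er2, S = S, n_pairs = np,
                 pcrit = pcrit, method = "LD-random-mating"),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "Inf" else sprintf("%.1f", v)
  cat(sprintf("Ne[%s] = %s (95%% CI %s - %s); r2 = %.5f, E[r2] = %.5f, S = %.1f\n",
              x$pop, fmt(x$ne), fmt(x$ci_low), fmt(x$ci_high),
              x$r2, x$exp_r2, x$S))
  invisible(x)
}

#' Hierarchical total effective population size
#'
#' Sums local Ne values and divides by `(1 - FST)` to account for
#' among-population structure; infinite local entries are replaced by `cap`
#' before summation. Applied separately to point estimates and to the lower
#' and upper confidence bounds when these are supplied.
#'
#' @param locals list of `ne_estimate` objects, or a numeric vector of local
#'   point estimates
#' @param fst global FST (< 1)
#' @param cap replacement value for infinite local estimates (default 10000)
#' @param ci_low,ci_high optional numeric vectors of local CI bounds (taken
#'   from the `ne_estimate` objects when `locals` is a list)
#' @return list of class `total_ne`: `total`, `total_low`, `total_high`,
#'   `fst`, `cap`
#' @export
total_ne <- function(locals, fst, cap = 10000, ci_low = NULL, ci_high = NULL) {
  if (!length(locals)) stop("no local estimates")
  if (fst >= 1) stop("fst must be < 1")
  if (is.list(locals) && inherits(locals[[1]], "ne_estimate")) {
    ci_low <- vapply(locals, `[[`, numeric(1), "ci_low")
    ci_high <- vapply(locals, `[[`, numeric(1), "ci_high")
    locals <- vapply(locals, `[[`, numeric(1), "ne")
  }
  capit <- function(v) { v[is.infinite(v)] <- cap; v }
  tot <- function(v) if (is.null(v)) NA_real_ else sum(capit(v)) / (1 - fst)
  structure(list(total = tot(locals), total_low = tot(ci_low),
                 total_high = tot(ci_high), fst = fst, cap = cap),
            class = "total_ne")
}

#' @export
print.total_ne <- function(x, ...) {
  cat(sprintf("Total Ne = %.1f (CI %.1f - %.1f), FST = %.3g, cap = %g\n",
              x$total, x$total_low, x$total_high, x$fst, x$cap))
  invisible(x)
}

#' Summary of local Ne point estimates
#' @param locals list of `ne_estimate` objects or numeric vector
#' @return named numeric vector: `mean`, `min`, `max`
#' @export
summarize_local_ne <- function(locals) {
  if (!length(locals)) stop("no local estimates")
  if (is.list(locals)) locals <- vapply(locals, `[[`, numeric(1), "ne")
  if (any(!is.finite(locals))) stop("summary needs finite point estimates")
  c(mean = mean(locals), min = min(locals), max = max(locals))
}
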