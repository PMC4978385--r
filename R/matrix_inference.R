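# Landscape-genetic inference on pairwise matrices: Mantel and partial
# Mantel causal modeling, and maximum-likelihood population effects (MLPE)
# mixed models that account for the non-independence of site pairs sharing
# a site.

.check_aligned <- function(...) {
  ms <- list(...)
  s <- ms[[1]]$sites
  for (m in ms[-1])
    if (!identical(m$sites, s)) stop("pairwise matrices have mismatched sites")
  if (length(s) < 4) stop("need >= 4 sites")
  s
}

# permute a symmetric matrix's rows and columns simultaneously
.perm_lower <- function(v_mat, perm) {
  p <- v_mat[perm, perm]
  p[lower.tri(p)]
}

#' Mantel test
#'
#' Pearson correlation of lower triangles; one-tailed significance (r at
#' least as large as observed) over simultaneous row/column permutations of
#' the second matrix, with `p = (count + 1) / (permutations + 1)`.
#'
#' @param x,y [pairwise_matrix()] objects over the same sites
#' @param permutations number of matrix permutations (default 9999)
#' @param seed RNG seed
#' @return object of class `mantel_result`: `r`, `p`, `permutations`,
#'   `partialled` (`NA` for the simple test), `seed`
#' @export
mantel <- function(x, y, permutations = 9999, seed = NULL) {
  .check_aligned(x, y)
  vx <- lower_tri(x); vy <- lower_tri(y)
  if (sd(vx) == 0 || sd(vy) == 0) stop("constant matrix: Mantel r undefined")
  if (!is.null(seed)) set.seed(seed)
  r <- cor(vx, vy)
  k <- length(x$sites)
  hits <- 0L
  for (b in seq_len(permutations)) {
    rp <- cor(vx, .perm_lower(y$values, sample(k)))
    if (rp >= r - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r, p = (hits + 1) / (permutations + 1),
                 permutations = permutations, partialled = NA_character_,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  lab <- if (is.na(x$partialled)) "Mantel"
         else paste0("partial Mantel (| ", x$partialled, ")")
  cat(sprintf("%s r = %.3f, p = %.4f (%d permutations)\n",
              lab, x$r, x$p, x$permutations))
  invisible(x)
}

#' Partial Mantel test
#'
#' Correlation between the residuals of `x` on `z` and of `y` on `z`
#' (lower-triangle regressions); significance by permuting the residualized
#' `x` matrix (residual-permutation method).
#'
#' @param x,y,z [pairwise_matrix()] objects over the same sites; `z` is the
#'   controlled covariate
#' @param permutations permutations
#' @param seed RNG seed
#' @return a `mantel_result` with `partialled` set
#' @export
partial_mantel <- function(x, y, z, permutations = 9999, seed = NULL) {
  .check_aligned(x, y, z)
  vx <- lower_tri(x); vy <- lower_tri(y); vz <- lower_tri(z)
  if (sd(vx) == 0 || sd(vy) == 0) stop("constant matrix: r undefined")
  if (!is.null(seed)) set.seed(seed)
  if (sd(vz) == 0) {                # degenerate control = simple Mantel
    rx <- vx - mean(vx); ry <- vy - mean(vy)
  } else {
    rx <- residuals(lm(vx ~ vz)); ry <- residuals(lm(vy ~ vz))
  }
  # a covariate identical to x or y annihilates it: nothing left to
  # correlate, so the partial association is zero by convention
  if (sd(rx) < 1e-10 * max(sd(vx), 1e-300) ||
      sd(ry) < 1e-10 * max(sd(vy), 1e-300))
    return(structure(list(r = 0, p = 1, permutations = permutations,
                          partialled = z$metric, seed = seed),
                     class = "mantel_result"))
  r <- cor(rx, ry)
  # residuals reassembled as a symmetric matrix for row/column permutation
  k <- length(x$sites)
  rmat <- matrix(0, k, k)
  rmat[lower.tri(rmat)] <- rx
  rmat <- rmat + t(rmat)
  hits <- 0L
  for (b in seq_len(permutations)) {
    rp <- cor(.perm_lower(rmat, sample(k)), ry)
    if (rp >= r - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r, p = (hits + 1) / (permutations + 1),
                 permutations = permutations,
                 partialled = if (!is.null(attr(z, "name"))) attr(z, "name")
                              else z$metric,
                 seed = seed),
            class = "mantel_result")
}

#' Causal-modeling table of simple and partial Mantel tests
#'
#' One simple Mantel per predictor, plus a partial Mantel of each predictor
#' against the genetic distance controlling for each other predictor in
#' turn -- the diagnostic grid used to separate correlated landscape
#' hypotheses.
#'
#' @param genetic [pairwise_matrix()] of genetic distances
#' @param predictors named list of [pairwise_matrix()] resistance matrices
#' @param permutations permutations per test
#' @param seed RNG seed
#' @return data frame: predictor, controlled_for (`NA` = simple test), r, p
#' @export
causal_model_table <- function(genetic, predictors, permutations = 9999,
                               seed = NULL) {
  stopifnot(length(predictors) >= 1)
  nm <- names(predictors)
  if (is.null(nm)) stop("predictors must be a named list")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (a in nm) {
    mt <- mantel(predictors[[a]], genetic, permutations)
    rows[[length(rows) + 1]] <- data.frame(
      predictor = a, controlled_for = NA_character_, r = mt$r, p = mt$p,
      stringsAsFactors = FALSE)
    for (b in setdiff(nm, a)) {
      pm <- partial_mantel(predictors[[a]], genetic, predictors[[b]],
                           permutations)
      rows[[length(rows) + 1]] <- data.frame(
        predictor = a, controlled_for = b, r = pm$r, p = pm$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# pairs-sharing-one-site adjacency for k sites (n = k(k-1)/2 pairs)
.mlpe_adjacency <- function(k) {
  prs <- t(combn(k, 2))
  n <- nrow(prs)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    shared <- length(intersect(prs[i, ], prs[j, ]))
    if (shared == 1) A[i, j] <- A[j, i] <- 1
  }
  A
}

# ML profile log-likelihood pieces at fixed rho
.mlpe_profile <- function(rho, A, X, y) {
  n <- length(y)
  C <- diag(n) + rho * A
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  # whiten: solve L' z = v with C = L'L (chol gives upper R: C = R'R)
  wX <- backsolve(ch, X, transpose = TRUE)
  wy <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(wX)
  b <- tryCatch(solve(XtX, crossprod(wX, wy)), error = function(e) NULL)
  if (is.null(b)) return(NULL)
  res <- wy - wX %*% b
  sigma2 <- sum(res^2) / n
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(ll = ll, beta = drop(b), sigma2 = sigma2, XtX = XtX, chol = ch)
}

#' Fit a maximum-likelihood population-effects (MLPE) model
#'
#' Regression of a pairwise response on pairwise predictors with the MLPE
#' error structure: `cor(e_ij, e_kl) = rho` when the pairs share exactly
#' one site, 1 when identical, 0 otherwise -- the covariance induced by an
#' additive random effect per site. `rho` is profiled out by golden-section
#' search over its positive-definite range; fixed effects are mean-centered
#' by default. Information criteria treat the number of site pairs as the
#' sample size.
#'
#' @param response [pairwise_matrix()] of genetic distances
#' @param predictors named list of [pairwise_matrix()] objects (may be
#'   empty for the intercept-plus-random-effect null)
#' @param center mean-center the predictors (default TRUE)
#' @param rho optional fixed value of the pair correlation; `NULL` (the
#'   default) estimates it by ML. `rho = 0` reduces the fit to ordinary
#'   least squares.
#' @return object of class `mlpe_fit`: `coefficients`, `rho`, `sigma2`,
#'   `loglik`, `AIC`, `AICc`, `BIC`, `R2beta`, `n_pairs`, `fixed`,
#'   `response`
#' @export
mlpe_fit <- function(response, predictors = list(), center = TRUE,
                     rho = NULL) {
  if (length(predictors)) .check_aligned(response, predictors[[1]])
  k <- length(response$sites)
  if (k < 5) stop("MLPE needs >= 5 sites")
  y <- lower_tri(response)
  n <- length(y)
  nm <- names(predictors)
  X <- cbind(`(Intercept)` = rep(1, n))
  for (a in nm) {
    v <- lower_tri(predictors[[a]])
    if (center) v <- v - mean(v)
    X <- cbind(X, v)
  }
  colnames(X) <- c("(Intercept)", nm)
  A <- .mlpe_adjacency(k)
  lam_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  rho_max <- if (lam_min < 0) -1 / lam_min else 1
  if (is.null(rho)) {
    obj <- function(r) {
      pr <- .mlpe_profile(r, A, X, y)
      if (is.null(pr)) -Inf else pr$ll
    }
    opt <- optimize(obj, c(0, rho_max - 1e-6), maximum = TRUE, tol = 1e-8)
    # compare against the boundary rho = 0
    if (obj(0) >= opt$objective) rho <- 0 else rho <- opt$maximum
  } else if (rho < 0 || rho >= rho_max)
    stop("rho outside the positive-definite range [0, ", round(rho_max, 3), ")")
  fit <- .mlpe_profile(rho, A, X, y)
  if (is.null(fit)) stop("covariance not positive definite at the optimum")
  p <- ncol(X)
  npar <- p + 2                                # betas + sigma2 + rho
  ll <- fit$ll
  aic <- -2 * ll + 2 * npar
  aicc <- aic + 2 * npar * (npar + 1) / (n - npar - 1)
  bic <- -2 * ll + npar * log(n)
  # R2beta: Wald-F comparison against the intercept + random-effect null
  q <- p - 1
  if (q > 0) {
    covb <- fit$sigma2 * solve(fit$XtX)
    bq <- fit$beta[-1]
    Fstat <- drop(t(bq) %*% solve(covb[-1, -1, drop = FALSE], bq)) / q
    nu <- n - p
    r2b <- (q / nu * Fstat) / (1 + q / nu * Fstat)
  } else r2b <- 0
  structure(list(coefficients = setNames(fit$beta, colnames(X)),
                 rho = rho, sigma2 = fit$sigma2, loglik = ll,
                 AIC = aic, AICc = aicc, BIC = bic, R2beta = r2b,
                 n_pairs = n, fixed = nm,
                 response = response$metric),
            class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("MLPE fit (%s ~ %s): rho = %.3f, logLik = %.2f\n",
              x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$rho, x$loglik))
  print(round(x$coefficients, 5))
  cat(sprintf("AICc = %.2f  BIC = %.2f  R2beta = %.3f\n",
              x$AICc, x$BIC, x$R2beta))
  invisible(x)
}

#' Rank a suite of MLPE candidate models
#'
#' @param fits named list of `mlpe_fit` objects sharing the response
#' @param threshold delta flagged as competitive (default 2)
#' @return data frame sorted by AICc: model, R2beta, BIC, dBIC, AICc,
#'   dAICc, competitive
#' @export
rank_models <- function(fits, threshold = 2) {
  stopifnot(length(fits) >= 1)
  resp <- unique(vapply(fits, `[[`, character(1), "response"))
  if (length(resp) != 1) stop("all fits must share the response")
  nm <- names(fits)
  if (is.null(nm))
    nm <- vapply(fits, function(f)
      if (length(f$fixed)) paste(f$fixed, collapse = " + ") else "(null)",
      character(1))
  out <- data.frame(model = nm,
                    R2beta = vapply(fits, `[[`, numeric(1), "R2beta"),
                    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
                    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
                    stringsAsFactors = FALSE)
  out$dBIC <- out$BIC - min(out$BIC)
  out$dAICc <- out$AICc - min(out$AICc)
  out$competitive <- out$dAICc <= threshold
  out[order(out$AICc), c("model", "R2beta", "BIC", "dBIC", "AICc", "dAICc",
                         "competitive")]
}
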