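test_that("Mantel statistic and permutation p behave at the extremes", {
  x <- random_pm(8, seed = 111)
  m <- mantel(x, x, permutations = 999, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 1000)
  expect_error(mantel(x, pairwise_matrix(matrix(0, 8, 8) + diag(0, 8),
                                         x$sites), 99), "constant")
  # cross-check r against the independent vegan implementation
  skip_if_not_installed("vegan")
  y <- random_pm(8, seed = 112)
  expect_equal(mantel(x, y, permutations = 99, seed = 2)$r,
               unname(vegan::mantel(x$values, y$values,
                                    permutations = 99)$statistic),
               tolerance = 1e-12)
})

test_that("Mantel p is calibrated under independence and never zero", {
  set.seed(113)
  ps <- replicate(150, {
    mantel(random_pm(7), random_pm(7), permutations = 99)$p
  })
  expect_true(all(ps > 0))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 1.96 * sqrt(0.05 * 0.95 / 150) + 0.02)
})

test_that("partial Mantel isolates and annihilates as constructed", {
  set.seed(114)
  x <- random_pm(8); y <- random_pm(8); z <- random_pm(8)
  # z uncorrelated with both: partial r ~ simple r
  simple <- mantel(x, y, permutations = 99, seed = 3)$r
  partial <- partial_mantel(x, y, z, permutations = 99, seed = 3)$r
  expect_lt(abs(simple - partial), 0.25)
  # x controlled by itself: nothing left
  self <- partial_mantel(x, y, x, permutations = 99, seed = 4)
  expect_equal(self$r, 0)
  # y = x + z exactly: removing z recovers x perfectly
  ysum <- pairwise_matrix(x$values + z$values, x$sites, "other")
  expect_gt(partial_mantel(x, ysum, z, permutations = 99, seed = 5)$r, 0.99)
  # constant covariate degenerates to the simple Mantel
  const <- pairwise_matrix(matrix(1, 8, 8) - diag(1, 8), x$sites, "other")
  expect_equal(partial_mantel(x, y, const, permutations = 999, seed = 6)$r,
               mantel(x, y, permutations = 999, seed = 6)$r,
               tolerance = 1e-12)
})

test_that("the causal-model table enumerates simple and partial tests", {
  set.seed(115)
  gen <- random_pm(6, "dps")
  preds <- list(distance = random_pm(6), slope = random_pm(6),
                canopy = random_pm(6))
  tab <- causal_model_table(gen, preds, permutations = 49, seed = 7)
  p <- length(preds)
  expect_equal(nrow(tab), p + p * (p - 1))
  expect_equal(sum(is.na(tab$controlled_for)), p)
  one <- causal_model_table(gen, preds["distance"], permutations = 49)
  expect_equal(nrow(one), 1)
})

test_that("pure isolation-by-distance is recovered by the Mantel grid", {
  set.seed(116)
  hits <- replicate(10, {
    land <- simulate_landscape(n_sites = 8, site_span = 4000,
                               cellsize = 250, margin_m = 1000,
                               seed = sample.int(1e6, 1))
    d <- euclid_matrix(land$sites)
    slope_r <- effective_resistance(build_surface(land$slope, "slope"),
                                    land$sites)
    noise <- matrix(0, 8, 8)
    noise[lower.tri(noise)] <- rnorm(28, 0, 0.3 * 0.001 * sd(lower_tri(d)))
    gen <- pairwise_matrix(0.001 * d$values + noise + t(noise),
                           d$sites, "dps")
    tab <- causal_model_table(gen, list(distance = d, slope = slope_r),
                              permutations = 199, seed = sample.int(1e6, 1))
    dist_simple <- tab$p[tab$predictor == "distance" &
                           is.na(tab$controlled_for)]
    dist_simple < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("MLPE reduces to OLS at rho 0 and nails a noise-free response", {
  set.seed(117)
  d <- random_pm(8, "resistance")
  yv <- 2 * lower_tri(d) + rnorm(28, 0, 0.4)
  ym <- matrix(0, 8, 8); ym[lower.tri(ym)] <- yv; ym <- ym + t(ym)
  resp <- pairwise_matrix(ym, d$sites, "other")
  f0 <- mlpe_fit(resp, list(distance = d), rho = 0)
  xo <- lower_tri(d) - mean(lower_tri(d))
  expect_equal(unname(f0$coefficients), unname(coef(lm(yv ~ xo))),
               tolerance = 1e-10)
  # noise-free: R2beta ~ 1 and minimal AICc among candidates
  pure <- pairwise_matrix(3 * d$values, d$sites, "other")
  fits <- list(distance = mlpe_fit(pure, list(distance = d)),
               null = mlpe_fit(pure, list()),
               other = mlpe_fit(pure, list(other = random_pm(8, seed = 99))))
  expect_gt(fits$distance$R2beta, 0.999)
  rk <- rank_models(fits)
  expect_equal(rk$model[1], "distance")
})

test_that("MLPE recovers slope and pair correlation from structured noise", {
  set.seed(118)
  d <- random_pm(8, "resistance", rng = c(0, 2))
  bs <- rs <- numeric(40)
  for (r in 1:40) {
    resp <- mlpe_response(d, beta = 2, sd_u = 1, sd_e = sqrt(4 / 3))
    f <- mlpe_fit(resp, list(distance = d))
    bs[r] <- f$coefficients["distance"]; rs[r] <- f$rho
  }
  expect_lt(abs(mean(bs) - 2) / 2, 0.1)
  expect_gt(mean(rs), 0.1); expect_lt(mean(rs), 0.5)
})

test_that("log-likelihood never drops when adding a predictor; AICc can", {
  set.seed(119)
  d <- random_pm(8, "resistance")
  resp <- mlpe_response(d, beta = 1, sd_u = 0.5, sd_e = 0.5)
  f1 <- mlpe_fit(resp, list(distance = d))
  f2 <- mlpe_fit(resp, list(distance = d, junk = random_pm(8)))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_gt(f2$AICc, f2$AIC)
  expect_equal(f1$n_pairs, 28)
})

test_that("model ranking flags competitors and is translation invariant", {
  set.seed(120)
  d <- random_pm(8, "resistance")
  resp <- mlpe_response(d, beta = 1.5, sd_u = 0.3, sd_e = 0.3)
  fits <- list(a = mlpe_fit(resp, list(distance = d)),
               b = mlpe_fit(resp, list()))
  rk <- rank_models(fits)
  expect_equal(rk$dAICc[1], 0)
  expect_true(all(diff(rk$AICc) >= 0))
  shifted <- fits
  shifted$a$AICc <- shifted$a$AICc + 100
  shifted$b$AICc <- shifted$b$AICc + 100
  expect_equal(rank_models(shifted)$dAICc, rk$dAICc)
  one <- rank_models(fits["a"])
  expect_equal(one$dAICc, 0)
})
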