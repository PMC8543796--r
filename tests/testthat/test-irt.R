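test_that("EM recovers generating parameters and keeps a monotone trace", {
  a <- c(1.2, 2.0, 1.6, 1.1, 1.9, 1.4, 2.3, 1.0)
  b <- c(-1.2, -0.6, -0.2, 0.1, 0.4, 0.8, 1.2, 0)
  y <- sim_2pl(1200, a, b, seed = 51)
  fit <- fit_2pl(y)
  expect_true(fit$converged)
  expect_lt(sqrt(mean((fit$b - b)^2)), 0.2)
  expect_lt(sqrt(mean((fit$a - a)^2)), 0.35)
  expect_true(all(diff(fit$trace) >= -1e-10))
  expect_true(all(fit$se_a > 0 & fit$se_b > 0))
  # quadrature-consistent likelihood at the estimates
  expect_equal(marginal_loglik_2pl(y, fit$a, fit$b, fit$nodes, fit$weights),
               fit$loglik, tolerance = 1e-10)
})

test_that("missing responses drop out of the likelihood", {
  y <- sim_2pl(600, c(1.5, 1.5, 1.5, 1.5), c(-0.5, 0, 0.5, 1), seed = 52)
  y_miss <- y
  y_miss[sample(length(y_miss), 200)] <- NA
  fit <- fit_2pl(y_miss)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= -1e-10))
  # loglik equals the sum over respondents of their observed-item marginals
  expect_equal(
    marginal_loglik_2pl(y_miss, fit$a, fit$b, fit$nodes, fit$weights),
    fit$loglik, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with guidance", {
  y <- sim_2pl(200, c(1.5, 1.5, 1.5), c(0, 0, 0), seed = 53)
  y[, 2] <- 1L
  expect_error(fit_2pl(y), "qc filters")
  expect_error(fit_2pl(y[, c(1, 3)]), "at least 3 items")
  y2 <- sim_2pl(200, c(1.5, 1.5, 1.5), c(0, 0, 0), seed = 53)
  y2[1, 1] <- 2L
  expect_error(fit_2pl(y2), "binary")
})

test_that("flipping all item codes mirrors difficulties, preserves fit", {
  y <- sim_2pl(800, c(1.3, 1.8, 1.1, 2.0, 1.5), c(-1, -0.3, 0.2, 0.7, 1.1),
               seed = 54)
  fit <- fit_2pl(y)
  fit_flip <- fit_2pl(1L - y)
  expect_equal(unname(fit_flip$b), unname(-fit$b), tolerance = 1e-4)
  expect_equal(unname(fit_flip$a), unname(fit$a), tolerance = 1e-4)
  fs <- fit_statistics(fit, y)
  fs_flip <- fit_statistics(fit_flip, 1L - y)
  expect_equal(fs_flip$m2, fs$m2, tolerance = 1e-4)
  expect_equal(fs_flip$srmr, fs$srmr, tolerance = 1e-4)
})

test_that("fit statistics are invariant to item and respondent order", {
  y <- sim_2pl(700, c(1.2, 1.9, 1.5, 1.1, 2.1, 1.7),
               c(-0.8, -0.2, 0.3, 0.9, 0, -1.1), seed = 55)
  fs <- fit_statistics(fit_2pl(y), y)
  set.seed(55)
  cols <- sample(ncol(y)); rows <- sample(nrow(y))
  yp <- y[rows, cols]
  fsp <- fit_statistics(fit_2pl(yp), yp)
  expect_equal(fsp$m2, fs$m2, tolerance = 1e-6)
  expect_equal(fsp$rmsea, fs$rmsea, tolerance = 1e-6)
  expect_equal(fsp$cfi, fs$cfi, tolerance = 1e-6)
  expect_equal(fsp$srmr, fs$srmr, tolerance = 1e-6)
})

test_that("parameter recovery improves with sample size on matched seeds", {
  a <- seq(1, 2.4, length.out = 10); b <- seq(-1.5, 1.5, length.out = 10)
  rmse_b <- vapply(c(500L, 4000L), function(n) {
    fit <- fit_2pl(sim_2pl(n, a, b, seed = 56))
    sqrt(mean((fit$b - b)^2))
  }, numeric(1))
  expect_lt(rmse_b[2], rmse_b[1])
})

test_that("fit classification follows the published cutoffs", {
  lab <- classify_fit(list(rmsea = 0.033, cfi = 0.952, srmr = 0.05))
  expect_identical(unname(lab["rmsea"]), "excellent")
  expect_identical(unname(lab["cfi"]), "good")
  expect_identical(unname(classify_fit(list(rmsea = 0.02, cfi = 0.753,
                                            srmr = 0.123))[c("cfi", "srmr")]),
                   c("poor", "poor"))
  # boundaries: 0.05 and 0.08 are both mediocre, just outside are not
  expect_identical(unname(classify_fit(list(rmsea = 0.05, cfi = 1,
                                            srmr = 0))["rmsea"]), "mediocre")
  expect_identical(unname(classify_fit(list(rmsea = 0.08, cfi = 1,
                                            srmr = 0))["rmsea"]), "mediocre")
  expect_identical(unname(classify_fit(list(rmsea = 0.081, cfi = 1,
                                            srmr = 0))["rmsea"]), "poor")
  expect_identical(unname(classify_fit(list(rmsea = 0.049, cfi = 1,
                                            srmr = 0))["rmsea"]), "excellent")
  expect_identical(unname(classify_fit(list(rmsea = NA, cfi = NA,
                                            srmr = 0.02))[["rmsea"]]),
                   "not computable")
})

test_that("independent items leave the baseline with nothing to improve on", {
  set.seed(57)
  y <- vapply(c(0.3, 0.45, 0.55, 0.6, 0.5), function(p) rbinom(400, 1L, p),
              integer(400))
  fit <- fit_2pl(y)
  fs <- fit_statistics(fit, y)
  # with no common factor the baseline already fits: CFI undefined
  expect_true(is.na(fs$cfi))
  expect_identical(unname(fs$labels["cfi"]), "not computable")
})

test_that("duplicated items trigger the local-dependence residual flag", {
  y <- sim_2pl(800, c(1.5, 1.2, 1.8, 1.4, 1.6), c(-0.5, 0, 0.5, 0.9, -1),
               seed = 58)
  y <- cbind(y, it06 = y[, 3])   # exact copy of item 3
  fit <- fit_2pl(y)
  rr <- residual_report(fit, y)
  expect_true(any(rr$flagged_pairs$item_i == "it03" &
                    rr$flagged_pairs$item_j == "it06"))
})

test_that("fit statistics need at least three items", {
  y <- sim_2pl(200, c(1.5, 1.5, 1.5), c(0, 0, 0), seed = 59)
  fit <- fit_2pl(y)
  expect_error(fit_statistics(fit, y[, 1:2]), "item pairs")
})

test_that("tetrachoric estimates match closed cases and a grid oracle", {
  # odds ratio 1: independence
  expect_equal(tetrachoric(matrix(c(25, 25, 25, 25), 2, 2)), 0,
               tolerance = 1e-6)
  # perfect concordance: +1 up to continuity correction
  expect_gt(tetrachoric(matrix(c(50, 0, 0, 50), 2, 2)), 0.99)
  # symmetric table vs brute-force likelihood maximization over rho
  tab <- matrix(c(40, 10, 10, 40), 2, 2)
  est <- tetrachoric(tab)
  rho_grid <- seq(-0.995, 0.995, by = 5e-4)
  nll <- vapply(rho_grid, function(r) {
    t1 <- qnorm(0.5)
    p00 <- integrate(function(x) dnorm(x) * pnorm((t1 - r * x) /
                                                    sqrt(1 - r^2)),
                     -Inf, t1, rel.tol = 1e-10)$value
    p <- pmax(c(p00, 0.5 - p00, 0.5 - p00, p00), 1e-12)
    -sum(c(40, 10, 10, 40) * log(p))
  }, numeric(1))
  expect_lt(abs(est - rho_grid[which.min(nll)]), 1e-3)
  expect_error(tetrachoric(matrix(c(0, 0, 10, 10), 2, 2)), "empty margin")
})

test_that("tetrachoric matrices respect overlap floors and degeneracy", {
  y <- sim_2pl(400, c(1.8, 1.8, 1.8), c(-0.3, 0, 0.3), seed = 60)
  y[1:390, 3] <- NA
  tm <- tetrachoric_matrix(y, min_overlap = 20L)
  expect_true(is.na(tm["it01", "it03"]))
  expect_false(is.na(tm["it01", "it02"]))
  expect_gt(tm["it01", "it02"], 0.2)
  expect_true(length(attr(tm, "skipped")) >= 1L)
})
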