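test_that("correlation pruning keeps one representative per cluster", {
  set.seed(61)
  a <- rnorm(50)
  x <- data.frame(a = a, a2 = a, b = rnorm(50))
  pr <- correlation_prune(x)
  expect_true(sum(c("a", "a2") %in% pr$selected) == 1)
  expect_true("b" %in% pr$selected)

  # all pairwise |r| small: everything kept
  y <- as.data.frame(matrix(rnorm(300), 100, 3,
                            dimnames = list(NULL, c("p", "q", "r"))))
  expect_setequal(correlation_prune(y)$selected, c("p", "q", "r"))

  # a correlated chain collapses to one representative
  n <- 400
  base <- rnorm(n)
  chain <- data.frame(A = base + rnorm(n, 0, 0.2),
                      B = base + rnorm(n, 0, 0.2),
                      C = base + rnorm(n, 0, 0.2))
  stopifnot(all(abs(cor(chain))[upper.tri(diag(3))] > 0.9))
  expect_length(correlation_prune(chain)$selected, 1)

  # forced members win their cluster
  pr2 <- correlation_prune(x, forced = "a2")
  expect_true("a2" %in% pr2$selected && !"a" %in% pr2$selected)

  expect_warning(correlation_prune(data.frame(k = rep(1, 10),
                                              m = rnorm(10))),
                 "constant")
})

test_that("standardisation yields exact z-scores and the slope identity", {
  set.seed(62)
  x <- data.frame(u = rnorm(30, 5, 3), v = rbinom(30, 1, 0.4))
  z <- standardize_columns(x)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)

  # y = 2x exactly: standardised slope 1, R^2 = 1
  d <- data.frame(y = 2 * x$u, x = x$u)
  zz <- standardize_columns(d)
  f <- fit_ols(zz[, "y"], zz[, "x", drop = FALSE])
  expect_equal(unname(f$coefficients[2]), 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # standardised slope = raw slope * sd(x)/sd(y) on random data
  y <- 3 + 1.7 * x$u + rnorm(30)
  raw <- oracle_ols(y, as.matrix(x["u"]))
  zs <- standardize_columns(data.frame(y = y, u = x$u))
  fz <- fit_ols(zs[, "y"], zs[, "u", drop = FALSE])
  expect_equal(unname(fz$coefficients[2]),
               unname(raw[2]) * sd(x$u) / sd(y), tolerance = 1e-10)

  expect_error(standardize_columns(data.frame(c1 = rep(2, 5))), "c1")
})

test_that("least squares matches the normal-equations oracle", {
  set.seed(63)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(0.5, -1, 2) + rnorm(20)
  f <- fit_ols(as.numeric(y), X)
  expect_equal(unname(f$coefficients), unname(oracle_ols(y, X)),
               tolerance = 1e-8)
  # p-values agree with lm
  lf <- lm(y ~ X)
  expect_equal(unname(f$p_values), unname(summary(lf)$coefficients[, 4]),
               tolerance = 1e-8)
  # intercept-only: R^2 = 0, RSS = TSS
  f0 <- fit_ols(as.numeric(y), matrix(nrow = 20, ncol = 0))
  expect_equal(f0$r_squared, 0)
  expect_equal(f0$rss, sum((y - mean(y))^2))
  # exact linear data: RSS ~ 0, R^2 = 1
  fe <- fit_ols(2 * X[, 1] + 3, X[, 1, drop = FALSE])
  expect_equal(fe$r_squared, 1, tolerance = 1e-12)
  # rank deficiency is reported
  expect_error(fit_ols(as.numeric(y), cbind(X, d = X[, 1])), "collinear")
})

test_that("AICc reproduces the closed form and penalty monotonicity", {
  # rss = n makes the log term vanish: AIC = 2p = 8, correction 8
  expect_equal(aicc(rss = 10, n = 10, k = 2), 16)
  # correction vanishes as n grows at fixed p
  base <- function(n) aicc(rss = n, n = n, k = 2) - 2 * 4
  expect_lt(base(1e6), 1e-4)
  expect_gt(base(10), 1)
  # equal RSS: smaller k wins
  expect_lt(aicc(5, 30, 2), aicc(5, 30, 3))
  expect_error(aicc(5, 6, 3), "insufficient")
})

test_that("Akaike weights follow the closed form and sum to one", {
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(7, 7)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  set.seed(64)
  x <- rnorm(20, 500, 30)
  expect_equal(sum(akaike_weights(x)), 1, tolerance = 1e-12)
  # invariant to the additive criterion constant
  expect_equal(akaike_weights(x), akaike_weights(x + 123.4),
               tolerance = 1e-12)
})

test_that("importance sums subset-renormalised weights over models containing a variable", {
  fits <- data.frame(x1 = c(TRUE, FALSE), x2 = c(FALSE, TRUE),
                     aicc = c(0, 2 * log(0.6 / 0.4)))
  # weights 0.6 / 0.4 by construction
  r <- rvi(fits, top_k = 2)
  expect_equal(unname(r["x1"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(r["x2"]), 0.4, tolerance = 1e-10)
  # absent variable scores zero; ubiquitous variable scores one
  fits$x3 <- FALSE; fits$x4 <- TRUE
  r2 <- rvi(fits, top_k = 2)
  expect_equal(unname(r2["x3"]), 0)
  expect_equal(unname(r2["x4"]), 1)
  expect_warning(rvi(fits, top_k = 10), "top_k")
})

test_that("the competition enumerates all subsets and ranks them coherently", {
  set.seed(65)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  cr <- compete_ranges(y ~ x1 + x2, d)
  expect_equal(nrow(cr$fits), 4)           # null, x1, x2, x1+x2
  expect_equal(cr$fits$delta_aicc[1], 0)
  expect_equal(sum(cr$fits$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(cr$fits$aicc))
  # nested-model property: adding a predictor never increases RSS
  rss_null <- cr$fits$rss[cr$fits$k == 0]
  rss_x1 <- cr$fits$rss[cr$fits$x1 & !cr$fits$x2]
  rss_full <- cr$fits$rss[cr$fits$x1 & cr$fits$x2]
  expect_lte(rss_x1, rss_null)
  expect_lte(rss_full, rss_x1)
  # the guard refuses combinatorial explosions unless overridden
  big <- as.data.frame(matrix(rnorm(30 * 22), 30))
  names(big) <- c("y", paste0("v", 1:21))
  expect_error(compete_ranges(y ~ ., big), "allow_large")
})

test_that("competition methods back-transform predictions and expose diagnostics", {
  set.seed(66)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 100 + 40 * d$x1 + rnorm(n, 0, 5)
  cr <- compete_ranges(y ~ x1 + x2, d)
  expect_true(cr$fits$x1[1])
  # predictions on the raw scale track lm on the same subset
  ref <- lm(y ~ x1, d)
  expect_equal(unname(predict(cr, d)), unname(fitted(ref)),
               tolerance = 1e-6)
  expect_equal(unname(residuals(cr)), unname(resid(ref)), tolerance = 1e-6)
  cf <- coef(cr)
  expect_equal(unname(cf["x1"]), unname(coef(ref)[2] * sd(d$x1) / sd(d$y)),
               tolerance = 1e-6)
  sm <- summary(cr)
  expect_s3_class(sm, "summary.range_competition")
  expect_true("null" %in% sm$table$model)
  expect_equal(sum(sm$table$weight), 1, tolerance = 1e-10)
  sims <- simulate(cr, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3))
  expect_output(print(cr), "Best model")
})

test_that("importance of the truly active variable dominates and grows with signal", {
  set.seed(67)
  n <- 100
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(X) <- paste0("v", 1:5)
  last_rvi <- -Inf
  for (beta in c(0.35, 0.7, 1.4)) {
    X$y <- beta * X$v1 + rnorm(n)
    cr <- compete_ranges(y ~ v1 + v2 + v3 + v4 + v5, X, top_k = 16)
    expect_equal(names(which.max(cr$rvi)), "v1")
    expect_gte(cr$rvi[["v1"]] + 1e-9, last_rvi)
    last_rvi <- cr$rvi[["v1"]]
  }
  expect_gt(last_rvi, 0.99)   # strong signal: present in every top model
})
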