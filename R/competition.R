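#' Prune highly correlated candidate predictors
#'
#' Builds the absolute Pearson correlation graph of the candidate
#' columns, takes connected components at `|r| > r_cluster` as clusters
#' of effectively interchangeable variables, and keeps one representative
#' per cluster: a forced variable if the cluster contains one, otherwise
#' the member with the highest mean `|r|` (computed over its
#' above-`r_rep` partners) to the rest of its cluster. Constant columns
#' have undefined correlations and are excluded with a warning.
#'
#' @param x Data frame or matrix of numeric candidate columns, >= 2 rows.
#' @param r_cluster Correlation threshold defining clusters. Default 0.9.
#' @param r_rep Threshold above which members compete for representative
#'   status. Default 0.7.
#' @param forced Character vector of variables that win representative
#'   status within their cluster (e.g. spring values of current speed and
#'   temperature).
#' @return List with `selected` (kept column names), `clusters` (list of
#'   character vectors), `report` (data frame: cluster id, member,
#'   kept).
#' @export
correlation_prune <- function(x, r_cluster = 0.9, r_rep = 0.7,
                              forced = character()) {
  x <- as.data.frame(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  sds <- vapply(x, stats::sd, 0)
  if (any(sds == 0)) {
    warning("excluding constant column(s): ",
            paste(names(x)[sds == 0], collapse = ", "))
    x <- x[sds > 0]
  }
  nm <- names(x)
  if (!length(nm))
    return(list(selected = character(), clusters = list(),
                report = data.frame()))
  r <- abs(stats::cor(as.matrix(x)))
  # connected components of the |r| > r_cluster graph
  adj <- r > r_cluster
  comp <- rep(NA_integer_, length(nm))
  cid <- 0L
  for (i in seq_along(nm)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  clusters <- split(nm, comp)
  selected <- character()
  rows <- list()
  for (cl in clusters) {
    if (length(cl) == 1) {
      keep <- cl
    } else if (any(cl %in% forced)) {
      keep <- intersect(forced, cl)[1]
    } else {
      score <- vapply(cl, function(v) {
        partners <- setdiff(cl, v)
        rv <- r[v, partners]
        mean(rv[rv > r_rep])
      }, 0)
      keep <- cl[which.max(score)]
    }
    selected <- c(selected, keep)
    rows[[length(rows) + 1]] <- data.frame(
      cluster = comp[match(cl[1], nm)], member = cl, kept = cl == keep)
  }
  list(selected = selected[order(match(selected, nm))],
       clusters = unname(clusters), report = do.call(rbind, rows))
}

#' Standardise a response and design to z-scores
#'
#' Centres and scales every column (including 0/1 dummies) to zero mean
#' and unit sample standard deviation, the scale on which regression
#' coefficients are comparable across predictors ("standardised betas").
#'
#' @param x Data frame or matrix of numeric columns.
#' @return Matrix of z-scores with attributes `"center"` and `"scale"`
#'   for back-transformation. Zero-variance columns raise an error naming
#'   the column.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x, center = mu, scale = sds)
  attr(z, "center") <- mu
  attr(z, "scale") <- sds
  z
}

# least squares via QR; returns coefficients, RSS, R2 and t-test p-values
.fit_ols <- function(y, X) {
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(Xi)[-keep], collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- y - Xi %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  dfres <- n - ncol(Xi)
  sigma2 <- rss / dfres
  Rinv <- backsolve(qr.R(qrx), diag(ncol(Xi)))
  se <- sqrt(rowSums(Rinv^2)[order(qrx$pivot)] * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), dfres)
  list(coefficients = beta, rss = rss,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       p_values = pval, residuals = as.numeric(res), df_residual = dfres)
}

#' Ordinary least squares with a stable decomposition
#'
#' QR-based least squares returning the quantities the model competition
#' needs. An intercept is always included.
#'
#' @param y Numeric response.
#' @param x Numeric predictor matrix (may have zero columns for the
#'   intercept-only model).
#' @return List with `coefficients` (intercept first), `rss`,
#'   `r_squared`, `p_values` (two-sided t tests), `residuals`,
#'   `df_residual`.
#' @export
fit_ols <- function(y, x) {
  x <- as.matrix(x)
  if (length(y) != nrow(x) && ncol(x) > 0)
    stop("length(y) does not match nrow(x)")
  if (length(y) <= ncol(x) + 2)
    stop("need n > k + 2 observations")
  .fit_ols(y, x)
}

#' Small-sample corrected Akaike information criterion
#'
#' For a Gaussian linear model with `k` slope parameters fitted to `n`
#' observations with residual sum of squares `rss`, using the
#' log-likelihood up to an additive constant (the `n log(2 pi) + n` term
#' is omitted; all differences, weights and importances are invariant to
#' it): `AIC = n log(rss / n) + 2 p` with `p = k + 2` (intercept, slopes,
#' error variance), and `AICc = AIC + 2 p (p + 1) / (n - p - 1)`.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of slope parameters (excluding the intercept).
#' @return AICc value.
#' @examples
#' aicc(rss = 10, n = 10, k = 2)  # log term vanishes: 8 + 8 = 16
#' @export
aicc <- function(rss, n, k) {
  p <- k + 2
  if (n <= p + 1) stop("insufficient sample for correction")
  aic <- if (rss <= 0) -Inf else n * log(rss / n) + 2 * p
  aic + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights
#'
#' Converts criterion values to relative model support:
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param x Numeric vector of AICc (or AIC) values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(x) {
  if (!length(x)) stop("no models")
  w <- exp(-(x - min(x)) / 2)
  w / sum(w)
}

#' Relative variable importance over the best models
#'
#' Sums Akaike weights over the models, among the `top_k` lowest-AICc
#' fits, that contain a given variable. Weights are renormalised within
#' the `top_k` subset; AICc ties at the subset boundary widen the subset.
#'
#' @param fits Data frame with columns `aicc` and logical membership
#'   columns named after variables, as produced by [compete_ranges()]
#'   (`object$fits`).
#' @param variables Character vector of variable names; defaults to all
#'   membership columns.
#' @param top_k Size of the best-model subset. Default 40. If larger than
#'   the number of fits, all fits are used with a warning.
#' @return Named numeric vector of importances in [0, 1].
#' @export
rvi <- function(fits, variables = NULL, top_k = 40) {
  if (is.null(variables))
    variables <- names(fits)[vapply(fits, is.logical, TRUE)]
  if (top_k > nrow(fits)) {
    warning("top_k exceeds number of fitted models; using all")
    top_k <- nrow(fits)
  }
  ord <- order(fits$aicc)
  cutoff <- fits$aicc[ord[top_k]]
  keep <- fits$aicc <= cutoff   # ties at the boundary widen the subset
  w <- akaike_weights(fits$aicc[keep])
  sub <- fits[keep, , drop = FALSE]
  vapply(variables, function(v) sum(w[sub[[v]]]), 0)
}

#' Compete all-subsets linear models of range size
#'
#' The central estimator: fits ordinary least squares regressions of a
#' (standardised) response on every subset of the candidate predictors,
#' including the intercept-only null, ranks them by small-sample
#' corrected AIC, and summarises the competition through Akaike weights
#' and relative variable importance over the best `top_k` models.
#' Response and predictors (including 0/1 dummies) are z-scored first, so
#' coefficients are standardised betas comparable across variables.
#'
#' @param formula Model formula giving the response and the candidate
#'   predictors, e.g. `total_km ~ time_since_introduction + habitat + ...`.
#'   Factors are expanded to 0/1 dummies via [stats::model.matrix()]
#'   before standardisation.
#' @param data Data frame; non-complete cases are dropped (and counted in
#'   the result).
#' @param top_k Best-model subset size for importance. Default 40.
#' @param weight_mode `"top_subset"` (default) renormalises the reported
#'   table weights within the displayed/top subset; `"all"` computes them
#'   across all fitted models. Importances always use the top-`top_k`
#'   renormalisation.
#' @param max_predictors Combinatorial guard: more than this many
#'   candidate predictors is refused unless `allow_large = TRUE`.
#' @param allow_large Override the guard.
#' @return Object of class `"range_competition"`: list with `fits` (data
#'   frame, one row per subset: logical membership columns, `k`, `rss`,
#'   `r_squared`, `aicc`, `delta_aicc`, `weight`, ranked by AICc),
#'   `rvi`, `best` (row index of the best fit), `coefficients` (named
#'   list per model id of standardised betas), `p_values`, `n`,
#'   `n_dropped`, `variables`, `scaling` (centres/scales), `response`,
#'   `call`, plus `residual_diagnostics` (skewness and excess kurtosis of
#'   the best model's residuals).
#' @seealso [summary.range_competition()], [rvi()], [aicc()]
#' @examples
#' d <- data.frame(y = rnorm(40), a = rnorm(40), b = rnorm(40))
#' cr <- compete_ranges(y ~ a + b, d)
#' cr$fits[, c("k", "aicc", "delta_aicc", "weight")]
#' @export
compete_ranges <- function(formula, data, top_k = 40,
                           weight_mode = c("top_subset", "all"),
                           max_predictors = 20, allow_large = FALSE) {
  weight_mode <- match.arg(weight_mode)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  n_dropped <- nrow(data) - nrow(mf)
  y_raw <- stats::model.response(mf)
  X_raw <- stats::model.matrix(attr(mf, "terms"), mf)
  X_raw <- X_raw[, colnames(X_raw) != "(Intercept)", drop = FALSE]
  vars <- colnames(X_raw)
  V <- length(vars)
  if (V > max_predictors && !allow_large)
    stop(V, " predictors would need ", 2^V,
         " models; set allow_large = TRUE to proceed")
  n <- length(y_raw)
  if (n <= V + 3) stop("too few complete cases for the largest model")

  Z <- standardize_columns(cbind(.response = y_raw, X_raw))
  y <- Z[, 1]
  X <- Z[, -1, drop = FALSE]

  nmod <- 2^V
  member <- matrix(FALSE, nmod, V, dimnames = list(NULL, vars))
  if (V > 0)
    for (j in seq_len(V))
      member[, j] <- bitwAnd(seq_len(nmod) - 1L, bitwShiftL(1L, j - 1L)) > 0
  fits <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    Xm <- X[, member[m, ], drop = FALSE]
    f <- .fit_ols(y, Xm)
    fits[[m]] <- f
  }
  k <- rowSums(member)
  rssv <- vapply(fits, `[[`, 0, "rss")
  tab <- data.frame(member, k = k, rss = rssv,
                    r_squared = vapply(fits, `[[`, 0, "r_squared"),
                    aicc = vapply(seq_len(nmod), function(m)
                      aicc(rssv[m], n, k[m]), 0),
                    check.names = FALSE)
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$weight <- akaike_weights(tab$aicc)
  rownames(tab) <- NULL
  imp <- rvi(tab, vars, top_k = min(top_k, nmod))
  diag_res <- fits[[1]]$residuals
  m2 <- mean((diag_res - mean(diag_res))^2)
  structure(list(
    fits = tab,
    rvi = imp,
    best = 1L,
    coefficients = lapply(fits, `[[`, "coefficients"),
    p_values = lapply(fits, `[[`, "p_values"),
    n = n, n_dropped = n_dropped,
    variables = vars,
    scaling = list(center = attr(Z, "center"), scale = attr(Z, "scale")),
    response = all.vars(formula)[1],
    top_k = top_k, weight_mode = weight_mode,
    residual_diagnostics = c(
      skewness = mean((diag_res - mean(diag_res))^3) / m2^1.5,
      excess_kurtosis = mean((diag_res - mean(diag_res))^4) / m2^2 - 3),
    terms = attr(mf, "terms"),
    model = mf,
    call = match.call()),
    class = "range_competition")
}

#' @export
print.range_competition <- function(x, digits = 3, ...) {
  cat(sprintf("All-subsets AICc competition: %d models over %d predictors, n = %d\n",
              nrow(x$fits), length(x$variables), x$n))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d incomplete case(s) dropped)\n", x$n_dropped))
  b <- x$fits[x$best, ]
  cat(sprintf("Best model: k = %d, R^2 = %.*f, AICc = %.*f, w = %.*f\n",
              b$k, digits, b$r_squared, digits, b$aicc, digits, b$weight))
  cf <- coef(x)
  cf <- cf[names(cf) != "(Intercept)"]
  if (length(cf)) {
    cat("Standardised betas:\n")
    print(round(cf, digits))
  }
  cat("Relative variable importance (top", x$top_k, "models):\n")
  print(round(sort(x$rvi, decreasing = TRUE), digits))
  invisible(x)
}

#' Standardised coefficients of a competed model
#'
#' @param object A [compete_ranges()] result.
#' @param model Row index into `object$fits` (models are ranked by AICc;
#'   1 is the best model).
#' @param ... Unused.
#' @return Named vector of standardised betas (with intercept, which is 0
#'   up to rounding on the z-scored scale).
#' @export
coef.range_competition <- function(object, model = object$best, ...) {
  object$coefficients[[model]]
}

#' Predict range size from the best competed model
#'
#' Predictions are produced on the raw response scale by back-transforming
#' the standardised fit.
#'
#' @param object A [compete_ranges()] result.
#' @param newdata Data frame with the predictor columns; omitted means the
#'   fitting data.
#' @param model Row index of the model to predict from (default best).
#' @param ... Unused.
#' @return Numeric vector of predicted responses (raw units, e.g. km).
#' @export
predict.range_competition <- function(object, newdata = NULL,
                                      model = object$best, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- if (is.null(newdata)) object$model
        else stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  sc <- object$scaling
  Xz <- scale(X[, object$variables, drop = FALSE],
              center = sc$center[object$variables],
              scale = sc$scale[object$variables])
  cf <- object$coefficients[[model]]
  vars_m <- setdiff(names(cf), "(Intercept)")
  yhat_z <- cf[["(Intercept)"]] +
    as.numeric(Xz[, vars_m, drop = FALSE] %*% cf[vars_m])
  yhat_z * sc$scale[[".response"]] + sc$center[[".response"]]
}

#' Residuals of a competed model on the raw response scale
#'
#' @param object A [compete_ranges()] result.
#' @param model Row index of the model (default best).
#' @param ... Unused.
#' @return Numeric residual vector in response units.
#' @export
residuals.range_competition <- function(object, model = object$best, ...) {
  y <- stats::model.response(object$model)
  y - predict(object, model = model)
}

#' Simulate responses from a competed model
#'
#' Gaussian simulation from the chosen model's fitted values and residual
#' standard deviation, on the raw response scale.
#'
#' @param object A [compete_ranges()] result.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param model Row index of the model (default best).
#' @param ... Unused.
#' @return Data frame of `nsim` simulated response columns.
#' @export
simulate.range_competition <- function(object, nsim = 1, seed = NULL,
                                       model = object$best, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, model = model)
  res <- residuals(object, model = model)
  sigma <- sqrt(sum(res^2) / (object$n - sum(unlist(object$fits[model, object$variables])) - 1))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Summarise a model competition as a ranked report table
#'
#' Produces the conventional model-selection report: the four best models
#' for each model size up to `max_size` variables, plus the null model,
#' with per-variable standardised betas, R-squared, AICc, delta-AICc and
#' Akaike weights (renormalised over the displayed subset when the
#' competition was run with `weight_mode = "top_subset"`), and the
#' importance row underneath.
#'
#' @param object A [compete_ranges()] result.
#' @param max_size Largest model size shown. Default 7.
#' @param per_size Number of best models per size. Default 4.
#' @param ... Unused.
#' @return Object of class `"summary.range_competition"`: list with
#'   `table` (data frame), `rvi`, `n`, `residual_diagnostics`.
#' @export
summary.range_competition <- function(object, max_size = 7, per_size = 4,
                                      ...) {
  f <- object$fits
  pick <- integer()
  for (sz in 0:max_size) {
    rows <- which(f$k == sz)
    pick <- c(pick, utils::head(rows, per_size))
  }
  pick <- sort(unique(c(pick, which(f$k == 0))))
  sub <- f[pick, , drop = FALSE]
  w <- if (object$weight_mode == "top_subset")
    akaike_weights(sub$aicc) else sub$weight
  betas <- do.call(rbind, lapply(pick, function(m) {
    cf <- object$coefficients[[m]]
    out <- stats::setNames(rep(NA_real_, length(object$variables)),
                           object$variables)
    got <- intersect(names(cf), object$variables)
    out[got] <- cf[got]
    out
  }))
  tab <- data.frame(
    model = ifelse(sub$k == 0, "null", paste0("M", seq_along(pick))),
    n_vars = sub$k, r_squared = sub$r_squared, aicc = sub$aicc,
    delta_aicc = sub$delta_aicc, weight = w, betas,
    check.names = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, rvi = object$rvi, n = object$n,
                 residual_diagnostics = object$residual_diagnostics),
            class = "summary.range_competition")
}

#' @export
print.summary.range_competition <- function(x, digits = 3, ...) {
  cat("Ranked model competition (best models per size, plus null)\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat("\nRelative variable importance:\n")
  print(round(x$rvi, digits))
  cat(sprintf("\nn = %d; best-model residual skewness %.2f, excess kurtosis %.2f\n",
              x$n, x$residual_diagnostics[["skewness"]],
              x$residual_diagnostics[["excess_kurtosis"]]))
  invisible(x)
}

#' Plot a model competition
#'
#' Two base-graphics panels: the delta-AICc profile of the ranked models
#' (with the conventional support thresholds at 2 and 7), and the
#' relative variable importances.
#'
#' @param x A [compete_ranges()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.range_competition <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  nshow <- min(40, nrow(x$fits))
  graphics::plot(seq_len(nshow), x$fits$delta_aicc[seq_len(nshow)],
                 xlab = "model rank", ylab = expression(Delta * "AICc"),
                 pch = 16, ...)
  graphics::abline(h = c(2, 7), lty = 3)
  imp <- sort(x$rvi, decreasing = TRUE)
  graphics::barplot(imp, las = 2, ylim = c(0, 1),
                    ylab = "relative variable importance")
  invisible(x)
}
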