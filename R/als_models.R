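#' Box-Cox transformation and its inverse
#'
#' `boxcox_transform` applies `(y^lambda - 1) / lambda` (natural log at
#' `lambda = 0`, the standard limit). `boxcox_lambda` profiles the Box-Cox
#' log-likelihood of a positive sample over a search interval and returns the
#' maximising exponent, the "maximum likelihood-like" normalising choice.
#'
#' @param y Strictly positive numeric vector.
#' @param lambda Box-Cox exponent.
#' @param interval Search interval for `lambda`, default `c(-2, 2)`.
#' @return `boxcox_transform`: transformed values. `boxcox_lambda`: the
#'   maximising `lambda`.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive values", call. = FALSE)
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
boxcox_lambda <- function(y, interval = c(-2, 2)) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive values", call. = FALSE)
  if (length(y) < 10) stop("need at least 10 observations", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response: lambda is undefined", call. = FALSE)
  n <- length(y)
  slog <- sum(log(y))
  prof <- function(lambda) {
    z <- boxcox_transform(y, lambda)
    s2 <- sum((z - mean(z))^2) / n
    -n / 2 * log(s2) + (lambda - 1) * slog
  }
  stats::optimize(prof, interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

# adjusted R^2 of a least-squares fit with p regressors (+ intercept)
adj_r2 <- function(rss, tss, n, p) {
  if (tss <= 0) return(0)
  1 - (rss / (n - p - 1)) / (tss / (n - 1))
}

# least-squares fit of y on columns `sub` of the matrix Xm, returns rss + coef
ls_fit <- function(Xm, y, sub) {
  M <- cbind(`(Intercept)` = 1, Xm[, sub, drop = FALSE])
  f <- stats::lm.fit(M, y)
  list(coef = f$coefficients, rss = sum(f$residuals^2), rank = f$rank)
}

#' Best-subset linear prediction model for a stand variable
#'
#' Searches for the linear regression with the highest adjusted R^2 using at
#' most `max_vars` of the candidate ALS metrics, optionally after a log
#' transformation of all variables or a Box-Cox transformation of the
#' response. The search is exhaustive when the candidate pool has at most
#' `exhaustive_limit` metrics and greedy-forward otherwise; the strategy used
#' is recorded in the fitted model. Ties are broken by enumeration order
#' (smaller subsets first, then column order), which makes selection
#' deterministic.
#'
#' The residual variance `v` on the transformed scale (denominator
#' `n - p - 1`) is stored for the back-transformation bias corrections.
#'
#' @param X Data frame of candidate metrics (plots in rows).
#' @param y Response values (stand variable).
#' @param max_vars Maximum number of selected metrics, default 6.
#' @param transform One of `"none"`, `"log"` (all variables), `"boxcox"`
#'   (response only).
#' @param exhaustive_limit Candidate-pool size up to which the subset search
#'   is exhaustive. Default 12.
#' @return An object of class `als_model`: list with `form` (`"linear"`,
#'   `"log"` or `"boxcox"`), `metrics`, `coef`, `lambda`, `v`, `n_obs`,
#'   `adj_r2`, `search`.
#' @export
fit_linear_best_subset <- function(X, y, max_vars = 6,
                                   transform = c("none", "log", "boxcox"),
                                   exhaustive_limit = 12) {
  transform <- match.arg(transform)
  X <- as.data.frame(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n <= max_vars + 1) {
    stop("insufficient observations (", n, ") for max_vars = ", max_vars,
         call. = FALSE)
  }
  lambda <- NA_real_
  if (transform == "log") {
    bad <- names(X)[vapply(X, function(col) any(col <= 0), logical(1))]
    if (length(bad)) {
      stop("log transform requires positive values; offending columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(y <= 0)) stop("log transform requires a positive response", call. = FALSE)
    Xm <- log(as.matrix(X)); ty <- log(y)
  } else if (transform == "boxcox") {
    lambda <- boxcox_lambda(y)
    Xm <- as.matrix(X); ty <- boxcox_transform(y, lambda)
  } else {
    Xm <- as.matrix(X); ty <- y
  }
  p <- ncol(Xm)
  kmax <- min(max_vars, p, n - 2)
  tss <- sum((ty - mean(ty))^2)

  best <- list(sub = integer(0), adj = 0,
               fit = list(coef = c(`(Intercept)` = mean(ty)),
                          rss = tss))
  if (p <= exhaustive_limit) {
    search <- "exhaustive"
    for (k in seq_len(kmax)) {
      subs <- utils::combn(p, k)
      for (j in seq_len(ncol(subs))) {
        sub <- subs[, j]
        f <- ls_fit(Xm, ty, sub)
        a <- adj_r2(f$rss, tss, n, k)
        if (a > best$adj + 1e-12) best <- list(sub = sub, adj = a, fit = f)
      }
    }
  } else {
    search <- "greedy-forward"
    current <- integer(0)
    repeat {
      if (length(current) >= kmax) break
      cand <- setdiff(seq_len(p), current)
      step_best <- NULL
      for (j in cand) {
        sub <- c(current, j)
        f <- ls_fit(Xm, ty, sub)
        a <- adj_r2(f$rss, tss, n, length(sub))
        if (is.null(step_best) || a > step_best$adj + 1e-12) {
          step_best <- list(sub = sub, adj = a, fit = f)
        }
      }
      if (step_best$adj > best$adj + 1e-12) {
        best <- step_best
        current <- step_best$sub
      } else break
    }
  }
  psel <- length(best$sub)
  v <- best$fit$rss / (n - psel - 1)
  structure(list(
    form = switch(transform, none = "linear", log = "log", boxcox = "boxcox"),
    metrics = colnames(Xm)[best$sub],
    coef = best$fit$coef,
    lambda = lambda,
    v = v,
    n_obs = n,
    adj_r2 = best$adj,
    search = search
  ), class = "als_model")
}

# linear predictor a0 + sum(ai * xi) on the (possibly transformed) scale
linear_predictor <- function(model, X, log_x = FALSE) {
  miss <- setdiff(model$metrics, names(X))
  if (length(miss)) {
    stop("missing metric columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  Xm <- as.matrix(as.data.frame(X)[, model$metrics, drop = FALSE])
  if (log_x) {
    if (any(Xm <= 0)) stop("log-form model requires positive metrics", call. = FALSE)
    Xm <- log(Xm)
  }
  unname(drop(cbind(1, Xm) %*% model$coef))
}

#' Predictions from the untransformed linear model
#'
#' @param model An `als_model` with `form = "linear"`.
#' @param X Data frame of metrics.
#' @return Predicted values `a0 + sum(ai * xi)`.
#' @export
predict_linear <- function(model, X) {
  stopifnot(model$form == "linear")
  linear_predictor(model, X)
}

#' Bias-corrected predictions from the all-log model
#'
#' Back-transforms the log-scale fit and applies the lognormal bias
#' correction: `P = exp(a0) * prod(xi^ai) * exp(v / 2)` with `v` the residual
#' variance on the log scale.
#'
#' @inheritParams predict_linear
#' @export
predict_log <- function(model, X) {
  stopifnot(model$form == "log")
  exp(linear_predictor(model, X, log_x = TRUE) + model$v / 2)
}

# inverse Box-Cox with second-order bias correction; lambda ~ 0 falls back to
# the log limit. Values where lambda*Yhat + 1 <= 0 are clamped (with warning).
boxcox_inverse <- function(Yhat, lambda, v) {
  if (abs(lambda) < 1e-8) {
    return(exp(Yhat) * (1 + v / 2))
  }
  t <- lambda * Yhat + 1
  if (any(t <= 0)) {
    warning("inverse Box-Cox undefined for ", sum(t <= 0),
            " prediction(s); clamped to the domain boundary", call. = FALSE)
    t <- pmax(t, 1e-8)
  }
  t^(1 / lambda) * (1 + v / 2 * (1 - lambda) / t^2)
}

#' Bias-corrected predictions from the Box-Cox model
#'
#' Applies the inverse Box-Cox transformation to the fitted values and the
#' second-order bias correction
#' `P = (lambda*Yhat + 1)^(1/lambda) * (1 + v/2 * (1 - lambda) / (lambda*Yhat + 1)^2)`.
#' At `lambda = 0` the log-limit `exp(Yhat) * (1 + v/2)` is used.
#'
#' @inheritParams predict_linear
#' @export
predict_boxcox <- function(model, X) {
  stopifnot(model$form == "boxcox")
  boxcox_inverse(linear_predictor(model, X), model$lambda, model$v)
}

#' Broadleaf-proportion GLM
#'
#' Fits the logit-link binomial model for the broadleaf basal-area proportion
#' with the plots' basal areas as binomial weights, starting from the full
#' metric set and reducing it by both-direction stepwise AIC selection.
#' Predictions are guaranteed to lie in (0, 1) by the link. When the fit is
#' separated (degenerate fitted proportions), a ridge-penalised fit is used
#' instead and a warning is emitted.
#'
#' @param X Data frame of candidate metrics.
#' @param bab Broadleaf proportions in \[0, 1\].
#' @param weights Positive binomial totals (stand basal areas).
#' @return An `als_model` with `form = "binomial-logit"`.
#' @export
fit_bab_glm <- function(X, bab, weights) {
  X <- as.data.frame(X)
  stopifnot(length(bab) == nrow(X), length(weights) == nrow(X))
  if (any(bab < 0 | bab > 1)) stop("bab values must lie in [0, 1]", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  dat <- data.frame(.bab = bab, X, check.names = FALSE)
  dat$.w <- weights
  full <- suppressWarnings(
    stats::glm(.bab ~ . - .w, family = stats::binomial(), data = dat,
               weights = .w)
  )
  fit <- suppressWarnings(MASS::stepAIC(full, direction = "both", trace = 0))
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    warning("separation detected in broadleaf GLM; using ridge-penalised fit",
            call. = FALSE)
    xm <- as.matrix(X)
    counts <- cbind(weights * (1 - bab), weights * bab)
    rf <- glmnet::glmnet(xm, counts, family = "binomial", alpha = 0,
                         lambda = 0.01)
    cf <- as.numeric(glmnet::coef.glmnet(rf, s = 0.01))
    names(cf) <- c("(Intercept)", colnames(xm))
    coefs <- cf
    mets <- colnames(xm)
  } else {
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    coefs <- cf
    mets <- setdiff(names(cf), "(Intercept)")
  }
  structure(list(
    form = "binomial-logit",
    metrics = mets,
    coef = coefs,
    lambda = NA_real_,
    v = NA_real_,
    n_obs = nrow(X),
    adj_r2 = NA_real_,
    search = "stepAIC-both"
  ), class = "als_model")
}

#' Predict from a fitted ALS model
#'
#' Dispatches on the model form (`linear`, `log`, `boxcox`,
#' `binomial-logit`), applying the matching back-transformation and bias
#' correction.
#'
#' @param object An `als_model`.
#' @param newdata Data frame containing the model's metric columns.
#' @param ... Unused.
#' @return Predicted values on the original variable scale.
#' @export
predict.als_model <- function(object, newdata, ...) {
  switch(object$form,
    linear = predict_linear(object, newdata),
    log = predict_log(object, newdata),
    boxcox = predict_boxcox(object, newdata),
    `binomial-logit` = {
      if (length(object$metrics)) {
        stats::plogis(linear_predictor(object, newdata))
      } else {
        rep(stats::plogis(object$coef[["(Intercept)"]]), nrow(newdata))
      }
    },
    stop("unknown model form: ", object$form)
  )
}

#' @export
print.als_model <- function(x, ...) {
  cat("ALS prediction model (", x$form, ")\n", sep = "")
  cat("  metrics:", if (length(x$metrics)) paste(x$metrics, collapse = ", ")
      else "(intercept only)", "\n")
  cat("  n =", x$n_obs, " adj-R2 =", round(x$adj_r2, 4),
      " search =", x$search, "\n")
  invisible(x)
}

# fit one stratum for one variable with fixed settings
fit_stratum_model <- function(dat, variable, metric_cols, transform, max_vars,
                              exhaustive_limit) {
  X <- dat[, metric_cols, drop = FALSE]
  if (variable == "BA_b") {
    keep <- dat$BA > 0
    fit_bab_glm(X[keep, , drop = FALSE], dat$BA_b[keep], dat$BA[keep])
  } else if (transform == "auto") {
    forms <- c("none", "log", "boxcox")
    y <- dat[[variable]]
    rmses <- vapply(forms, function(f) {
      tryCatch({
        errs <- vapply(seq_len(nrow(dat)), function(i) {
          m <- fit_linear_best_subset(X[-i, , drop = FALSE], y[-i],
                                      max_vars = max_vars, transform = f,
                                      exhaustive_limit = exhaustive_limit)
          stats::predict(m, X[i, , drop = FALSE]) - y[i]
        }, numeric(1))
        sqrt(mean(errs^2))
      }, error = function(e) Inf)
    }, numeric(1))
    best <- forms[which.min(rmses)]  # which.min takes the first: simpler form wins ties
    fit_linear_best_subset(X, y, max_vars = max_vars, transform = best,
                           exhaustive_limit = exhaustive_limit)
  } else {
    fit_linear_best_subset(X, dat[[variable]], max_vars = max_vars,
                           transform = transform,
                           exhaustive_limit = exhaustive_limit)
  }
}

#' Stratified model set for one stand variable
#'
#' Fits one prediction model per stratum. Strata with fewer than `min_plots`
#' calibration plots are merged into a single pooled fallback stratum; if no
#' stratum reaches the minimum a single pooled model is fitted (with a
#' warning). A model fitted on all plots is always kept as the fallback for
#' unknown strata at prediction time.
#'
#' @param data Plot-level data frame containing the response column
#'   (`BA`, `Dg` or `BA_b`; `BA_b` fits also need `BA` for the binomial
#'   weights), a stratum column and the metric columns.
#' @param variable One of `"BA"`, `"Dg"`, `"BA_b"`.
#' @param metric_cols Names of the candidate metric columns.
#' @param stratum_col Name of the stratum column, default `"stratum"`.
#' @param min_plots Minimum plots per stratum, default 30.
#' @param transform Transformation for BA/Dg models: `"none"`, `"log"`,
#'   `"boxcox"` or `"auto"` (lowest leave-one-out RMSE, ties to the simpler
#'   form). Ignored for `BA_b`.
#' @param max_vars,exhaustive_limit Passed to [fit_linear_best_subset()].
#' @return Object of class `stratified_models`.
#' @export
fit_stratified <- function(data, variable, metric_cols,
                           stratum_col = "stratum", min_plots = 30,
                           transform = "none", max_vars = 6,
                           exhaustive_limit = 12) {
  stopifnot(variable %in% c("BA", "Dg", "BA_b"))
  strata <- as.character(data[[stratum_col]])
  counts <- table(strata)
  big <- names(counts)[counts >= min_plots]
  small <- setdiff(names(counts), big)
  models <- list()
  for (s in big) {
    models[[s]] <- fit_stratum_model(data[strata == s, , drop = FALSE],
                                     variable, metric_cols, transform,
                                     max_vars, exhaustive_limit)
  }
  if (length(big) == 0) {
    warning("no stratum reaches min_plots = ", min_plots,
            "; fitting a single pooled model", call. = FALSE)
  }
  pooled <- NULL
  if (length(small)) {
    pooled <- fit_stratum_model(data[strata %in% small, , drop = FALSE],
                                variable, metric_cols, transform, max_vars,
                                exhaustive_limit)
  }
  fallback <- fit_stratum_model(data, variable, metric_cols, transform,
                                max_vars, exhaustive_limit)
  structure(list(
    variable = variable,
    models = models,
    pooled = pooled,
    pooled_strata = small,
    fallback = fallback,
    min_plots = min_plots,
    settings = list(metric_cols = metric_cols, transform = transform,
                    max_vars = max_vars, exhaustive_limit = exhaustive_limit,
                    stratum_col = stratum_col)
  ), class = "stratified_models")
}

#' Predict a stand variable from a stratified model set
#'
#' Rows whose stratum has its own model use it; strata merged at fit time use
#' the pooled model; unknown strata fall back to the all-plots model (their
#' count is reported via the `n_fallback` attribute).
#'
#' @param object A `stratified_models` object.
#' @param newdata Data frame with metric columns and the stratum column.
#' @param ... Unused.
#' @return Predicted values with attribute `n_fallback`.
#' @export
predict.stratified_models <- function(object, newdata, ...) {
  strata <- as.character(newdata[[object$settings$stratum_col]])
  out <- numeric(nrow(newdata))
  n_fb <- 0L
  for (s in unique(strata)) {
    rows <- which(strata == s)
    m <- object$models[[s]]
    if (is.null(m) && s %in% object$pooled_strata) m <- object$pooled
    if (is.null(m)) {
      m <- object$fallback
      n_fb <- n_fb + length(rows)
    }
    out[rows] <- stats::predict(m, newdata[rows, , drop = FALSE])
  }
  attr(out, "n_fallback") <- n_fb
  out
}

#' Wall-to-wall mapping of the three stand variables
#'
#' Applies the fitted stratified model sets to every forest cell of the
#' prediction table, producing the BA / Dg / BA_b raster attributes of the
#' landscape. Non-forest cells get `NA`. Negative BA predictions are floored
#' at 0 and Dg predictions at the minimum inventoried diameter (the
#' downscaling step divides by Dg and matches on it).
#'
#' @param model_sets Named list with elements `BA`, `Dg`, `BA_b`, each a
#'   `stratified_models` object.
#' @param cell_metrics Data frame with `cellID25`, the stratum column, the
#'   metric columns and (optionally) a logical `forest` column.
#' @param dbh_min Floor for Dg predictions in cm, default 7.5.
#' @return Data frame `cellID25`, `BA`, `Dg`, `BA_b`.
#' @export
map_predict <- function(model_sets, cell_metrics, dbh_min = 7.5) {
  stopifnot(all(c("BA", "Dg", "BA_b") %in% names(model_sets)))
  forest <- if ("forest" %in% names(cell_metrics)) cell_metrics$forest
            else rep(TRUE, nrow(cell_metrics))
  out <- data.frame(cellID25 = cell_metrics$cellID25,
                    BA = NA_real_, Dg = NA_real_, BA_b = NA_real_)
  if (any(forest)) {
    sub <- cell_metrics[forest, , drop = FALSE]
    out$BA[forest] <- pmax(0, predict(model_sets$BA, sub))
    out$Dg[forest] <- pmax(dbh_min, predict(model_sets$Dg, sub))
    out$BA_b[forest] <- as.numeric(predict(model_sets$BA_b, sub))
  }
  out
}

#' Leave-one-out RMSE of a stratified prediction model
#'
#' Refits the whole stratified model (same subset-selection settings) with
#' each plot left out in turn, predicts the held-out plot, and returns the
#' root mean square error of those predictions. Folds whose refit fails are
#' skipped and counted.
#'
#' @inheritParams fit_stratified
#' @return List with `rmse`, `predicted`, `observed`, `n_skipped`.
#' @export
loocv_rmse <- function(data, variable, metric_cols, stratum_col = "stratum",
                       min_plots = 30, transform = "none", max_vars = 6,
                       exhaustive_limit = 12) {
  n <- nrow(data)
  pred <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    pred[i] <- tryCatch({
      set <- fit_stratified(data[-i, , drop = FALSE], variable, metric_cols,
                            stratum_col = stratum_col, min_plots = min_plots,
                            transform = transform, max_vars = max_vars,
                            exhaustive_limit = exhaustive_limit)
      as.numeric(predict(set, data[i, , drop = FALSE]))
    }, error = function(e) {
      NA_real_
    })
    if (is.na(pred[i])) skipped <- skipped + 1L
  }
  obs <- data[[variable]]
  ok <- !is.na(pred)
  list(rmse = sqrt(mean((obs[ok] - pred[ok])^2)),
       predicted = pred, observed = obs, n_skipped = skipped)
}
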