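test_that("best-subset search recovers a noiseless linear relation", {
  set.seed(1)
  X <- data.frame(a = runif(40, 1, 5), b = runif(40, 1, 5), c = runif(40, 1, 5))
  y <- 2 + 3 * X$b
  m <- fit_linear_best_subset(X, y, max_vars = 2)
  expect_equal(m$metrics, "b")
  expect_equal(unname(m$coef), c(2, 3), tolerance = 1e-8)
  expect_equal(m$adj_r2, 1, tolerance = 1e-8)
  expect_lt(m$v, 1e-12)
})

test_that("coefficients are recovered within sampling error under noise", {
  set.seed(2)
  n <- 50
  X <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  y <- 2 + 3 * X$x1 + rnorm(n, 0, 0.1)
  m <- fit_linear_best_subset(X, y, max_vars = 1)
  expect_equal(m$metrics, "x1")
  se <- 0.1 / sqrt(sum((X$x1 - mean(X$x1))^2))
  expect_lt(abs(m$coef[["x1"]] - 3), 3 * se)
})

test_that("selected subset beats every other subset on adjusted R2", {
  set.seed(3)
  n <- 60
  X <- as.data.frame(matrix(runif(n * 5, 1, 4), n, 5))
  y <- 1 + 2 * X$V2 - 1.5 * X$V4 + rnorm(n, 0, 0.5)
  m <- fit_linear_best_subset(X, y, max_vars = 3)
  expect_equal(m$search, "exhaustive")
  # brute-force oracle over all subsets of size <= 3
  best <- 0
  for (k in 1:3) {
    for (j in seq_len(ncol(utils::combn(5, k)))) {
      sub <- utils::combn(5, k)[, j]
      f <- stats::lm(y ~ ., data = X[, sub, drop = FALSE])
      best <- max(best, summary(f)$adj.r.squared)
    }
  }
  expect_equal(m$adj_r2, best, tolerance = 1e-10)
})

test_that("equally predictive duplicate metrics break ties by column order", {
  set.seed(4)
  x <- runif(30, 1, 5)
  X <- data.frame(first = x, second = x)
  y <- 1 + 2 * x + rnorm(30, 0, 0.2)
  m <- fit_linear_best_subset(X, y, max_vars = 1)
  expect_equal(m$metrics, "first")
})

test_that("insufficient observations and nonpositive values raise errors", {
  X <- data.frame(a = c(1, 2, 3), b = c(2, 1, 4))
  expect_error(fit_linear_best_subset(X, c(1, 2, 3), max_vars = 6),
               "insufficient")
  Xn <- data.frame(a = c(1, -2, 3, 4, 5, 6, 7, 8))
  expect_error(
    fit_linear_best_subset(Xn, rep(2, 8), max_vars = 1, transform = "log"),
    "a")
})

test_that("log-model bias correction beats the naive back-transform", {
  # lognormal simulation: the corrected predictor's mean bias must be smaller
  set.seed(10)
  n <- 2000
  x <- runif(n, 1, 5)
  v_true <- 0.5
  y <- exp(1 + 0.8 * log(x) + rnorm(n, 0, sqrt(v_true)))
  m <- fit_linear_best_subset(data.frame(x = x), y,
                              max_vars = 1, transform = "log")
  p_corr <- predict_log(m, data.frame(x = x))
  p_naive <- p_corr / exp(m$v / 2)
  true_mean <- exp(1 + 0.8 * log(x) + v_true / 2)
  expect_lt(abs(mean(p_corr - true_mean)), abs(mean(p_naive - true_mean)))
})

test_that("Box-Cox lambda estimates track the generating transform", {
  set.seed(11)
  y_log <- exp(rnorm(500, 1, 0.4))
  expect_lt(abs(boxcox_lambda(y_log)), 0.3)
  y_norm <- rnorm(500, 50, 5)
  expect_lt(abs(boxcox_lambda(y_norm) - 1), 0.5)
  expect_error(boxcox_lambda(rep(3, 20)), "constant")
  expect_error(boxcox_lambda(c(-1, 2, 3)), "positive")
})

test_that("Box-Cox lambda agrees with the car::powerTransform oracle", {
  skip_if_not_installed("car")
  set.seed(12)
  y <- exp(rnorm(300, 2, 0.3))
  lam_car <- car::powerTransform(y)$lambda
  expect_equal(boxcox_lambda(y), unname(lam_car), tolerance = 0.02)
})

test_that("inverse Box-Cox identities hold at lambda = 1 and the log limit", {
  m <- structure(list(form = "boxcox", metrics = character(0),
                      coef = c(`(Intercept)` = 2), lambda = 1, v = 0),
                 class = "als_model")
  X <- data.frame(row.names = 1)
  expect_equal(predict_boxcox(m, X), 3)  # Yhat + 1 at lambda = 1, v = 0

  m$lambda <- 0.5
  expect_equal(predict_boxcox(m, X), 4)  # (0.5*2 + 1)^2

  # lambda -> 0 converges to the log-model back-transform on the same Yhat
  v <- 1e-3
  m_log <- structure(list(form = "log", metrics = character(0),
                          coef = c(`(Intercept)` = 0.8), lambda = NA, v = v),
                     class = "als_model")
  m$coef <- c(`(Intercept)` = 0.8)
  m$lambda <- 1e-6; m$v <- v
  expect_equal(predict_boxcox(m, X), predict_log(m_log, X), tolerance = 1e-6)
})

test_that("broadleaf GLM recovers a known logit relation and stays in (0,1)", {
  set.seed(13)
  n <- 300
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  eta <- -0.3 + 1.2 * X$x1
  w <- runif(n, 20, 45)
  bab <- stats::plogis(eta + rnorm(n, 0, 0.3))
  m <- fit_bab_glm(X, bab, w)
  expect_true("x1" %in% m$metrics)
  expect_lt(abs(m$coef[["x1"]] - 1.2), 3 * 0.15)
  p <- predict(m, data.frame(x1 = c(-10, 0, 10), x2 = 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("uninformative metrics leave an intercept-only broadleaf model", {
  set.seed(14)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  m <- fit_bab_glm(X, rep(0.5, n), runif(n, 10, 30))
  expect_length(m$metrics, 0)
  expect_equal(unname(predict(m, X)[1]), 0.5, tolerance = 1e-6)
})

test_that("stratified fitting recovers per-stratum slopes and merges small strata", {
  set.seed(15)
  n <- 80
  dat <- data.frame(
    m1 = runif(2 * n, 1, 5),
    stratum = rep(c("A", "B"), each = n)
  )
  dat$BA <- ifelse(dat$stratum == "A", 2 + 3 * dat$m1, 10 + 1 * dat$m1) +
    rnorm(2 * n, 0, 0.2)
  set <- fit_stratified(dat, "BA", "m1", min_plots = 30)
  expect_equal(set$models[["A"]]$coef[["m1"]], 3, tolerance = 0.1)
  expect_equal(set$models[["B"]]$coef[["m1"]], 1, tolerance = 0.1)

  # a stratum below the minimum is pooled
  dat2 <- dat
  dat2$stratum[1:10] <- "C"
  set2 <- fit_stratified(dat2, "BA", "m1", min_plots = 30)
  expect_true("C" %in% set2$pooled_strata)
  p <- predict(set2, data.frame(m1 = 3, stratum = "C"))
  expect_true(is.finite(p))

  # unknown stratum at prediction time falls back, with a count
  p2 <- predict(set, data.frame(m1 = 3, stratum = "ZZ"))
  expect_equal(attr(p2, "n_fallback"), 1L)

  # one-level stratification is a pooled fit
  dat3 <- dat; dat3$stratum <- "only"
  set3 <- fit_stratified(dat3, "BA", "m1", min_plots = 30)
  expect_equal(names(set3$models), "only")
})

test_that("mapping floors predictions and masks non-forest cells", {
  set.seed(16)
  n <- 60
  dat <- data.frame(m1 = runif(n, 1, 5), stratum = "S")
  dat$BA <- pmax(0.5, 3 * dat$m1 + rnorm(n, 0, 1))
  dat$Dg <- 15 + 2 * dat$m1 + rnorm(n, 0, 0.5)
  dat$BA_b <- stats::plogis(dat$m1 - 3 + rnorm(n, 0, 0.2))
  sets <- list(
    BA = fit_stratified(dat, "BA", "m1", min_plots = 30),
    Dg = fit_stratified(dat, "Dg", "m1", min_plots = 30),
    BA_b = fit_stratified(dat, "BA_b", "m1", min_plots = 30))
  cells <- data.frame(cellID25 = 1:3, m1 = c(-5, 3, 4), stratum = "S",
                      forest = c(TRUE, TRUE, FALSE))
  pred <- map_predict(sets, cells)
  expect_gte(pred$BA[1], 0)
  expect_gte(pred$Dg[1], 7.5)
  expect_true(is.na(pred$BA[3]))
  expect_true(pred$BA_b[2] > 0 && pred$BA_b[2] < 1)
})

test_that("LOOCV RMSE is near zero for a perfect relation and near sigma for noise", {
  set.seed(17)
  n <- 60
  dat <- data.frame(m1 = runif(n, 1, 5), stratum = "S")
  dat$BA <- 2 + 3 * dat$m1
  cv <- loocv_rmse(dat, "BA", "m1", min_plots = 30)
  expect_lt(cv$rmse, 1e-8)

  set.seed(18)
  n <- 200
  dat2 <- data.frame(m1 = rnorm(n), stratum = "S")
  dat2$BA <- 20 + rnorm(n, 0, 2)   # metrics carry no signal
  cv2 <- loocv_rmse(dat2, "BA", "m1", min_plots = 30)
  expect_gt(cv2$rmse, 2 * 0.93)
  expect_lt(cv2$rmse, 2 * 1.15)
})

test_that("model sets serialize to JSON and reproduce predictions exactly", {
  set.seed(19)
  n <- 40
  dat <- data.frame(m1 = runif(n, 1, 5), m2 = runif(n, 2, 7), stratum = "S")
  dat$BA <- exp(0.5 + 0.8 * log(dat$m1) + rnorm(n, 0, 0.1))
  set <- fit_stratified(dat, "BA", c("m1", "m2"), min_plots = 10,
                        transform = "log")
  path <- tempfile(fileext = ".json")
  write_model_set(set, path)
  back <- read_model_set(path)
  newd <- data.frame(m1 = c(1.5, 4.2), m2 = c(3, 5), stratum = "S")
  expect_equal(as.numeric(predict(back, newd)),
               as.numeric(predict(set, newd)), tolerance = 1e-12)
})
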