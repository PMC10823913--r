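test_that("published parameter sets carry the printed values", {
  b <- published_height_params("bauges")
  expect_equal(unname(b$alpha_sp["Pi.ab."]), 55.11821)
  expect_equal(unname(b$beta_sp["Fa.sy."]), 1.71474)
  expect_equal(b$gamma, 1.42595)
  m <- published_height_params("milicz")
  expect_equal(unname(m$beta_sp["Pi.sy."]), 2.73192)
  expect_equal(m$var_power, 0.16)
  s <- published_height_params("sneznik")
  # the Sneznik set borrows beta_sp and gamma from the Bauges fit
  expect_equal(s$gamma, b$gamma)
  expect_equal(unname(s$beta_sp["Ab.al."]), unname(b$beta_sp["Ab.al."]))
  expect_equal(s$borrowed$params, c("beta_sp", "gamma"))
  expect_equal(s$var_power, -0.56)
})

test_that("height predictions match a frozen direct evaluation", {
  b <- published_height_params("bauges")
  # Fa.sy., dbh = 30, Dg = 30, population level: frozen regression value
  expect_equal(predict_height(30, 30, "Fa.sy.", b), 22.642343512,
               tolerance = 1e-9)
  m <- published_height_params("milicz")
  expect_equal(predict_height(25, 20, "Pi.sy.", m), 21.9135717084,
               tolerance = 1e-9)
})

test_that("the curve passes through breast height and saturates", {
  for (site in c("bauges", "milicz", "sneznik")) {
    p <- published_height_params(site)
    for (sp in names(p$alpha_sp)) {
      expect_lt(abs(predict_height(1e-8, 25, sp, p) - 1.3), 1e-6)
      asym <- 1.3 + p$alpha_sp[[sp]] * (1 - exp(-p$alpha1 * 25^p$alpha2))
      expect_equal(predict_height(1e5, 25, sp, p), asym, tolerance = 1e-6)
    }
  }
})

test_that("height is strictly increasing in dbh at fixed Dg", {
  p <- published_height_params("bauges")
  for (sp in names(p$alpha_sp)) {
    for (dg in c(12, 25, 40)) {
      h <- predict_height(seq(1, 80, by = 0.5), dg, sp, p)
      expect_true(all(diff(h) > 0))
    }
  }
})

test_that("unknown species fall back to OtherSp. or fail without one", {
  b <- published_height_params("bauges")
  expect_equal(predict_height(30, 25, "Zz.zz.", b),
               predict_height(30, 25, "OtherSp.", b))
  s <- published_height_params("sneznik")
  expect_error(predict_height(30, 25, "Zz.zz.", s), "OtherSp")
})

test_that("the mixed-effects fit recovers known parameters", {
  set.seed(51)
  true <- height_params(
    alpha_sp = c(A = 40, B = 50), beta_sp = c(A = 1.7, B = 1.0),
    alpha1 = 0.016, alpha2 = 1.26, gamma = 1.43,
    var_power = 0.5, re_sd = 0.1, resid_sd = 0.5)
  np <- 50; nt <- 20
  plot_id <- rep(seq_len(np), each = nt)
  dg <- rep(seq(10, 55, length.out = np), each = nt)
  sp <- sample(c("A", "B"), np * nt, replace = TRUE)
  dbh <- pmax(5, dg * rlnorm(np * nt, 0, 0.35))
  u <- rep(rnorm(np, 0, true$re_sd), each = nt)
  mu <- vapply(seq_along(dbh), function(i)
    predict_height(dbh[i], dg[i], sp[i], true, site_effect = u[i]), numeric(1))
  h <- mu + rnorm(np * nt, 0, true$resid_sd * (mu / 20)^true$var_power)
  fit <- fit_height_model(
    data.frame(height = h, dbh = dbh, dg = dg, species = sp, plot_id = plot_id),
    min_obs = 50)
  expect_lt(max(abs(fit$alpha_sp / true$alpha_sp - 1)), 0.1)
  expect_lt(max(abs(fit$beta_sp / true$beta_sp - 1)), 0.1)
  expect_lt(abs(fit$var_power - true$var_power), 0.3)
})

test_that("fixing beta and gamma estimates only the remaining parameters", {
  set.seed(52)
  true <- height_params(
    alpha_sp = c(A = 45, B = 55), beta_sp = c(A = 1.6, B = 1.1),
    alpha1 = 0.02, alpha2 = 1.1, gamma = 1.4,
    var_power = 0.3, re_sd = 0.08, resid_sd = 0.4)
  np <- 50; nt <- 20
  plot_id <- rep(seq_len(np), each = nt)
  dg <- rep(seq(10, 55, length.out = np), each = nt)
  sp <- sample(c("A", "B"), np * nt, replace = TRUE)
  dbh <- pmax(5, dg * rlnorm(np * nt, 0, 0.3))
  u <- rep(rnorm(np, 0, true$re_sd), each = nt)
  mu <- vapply(seq_along(dbh), function(i)
    predict_height(dbh[i], dg[i], sp[i], true, site_effect = u[i]), numeric(1))
  h <- mu + rnorm(np * nt, 0, true$resid_sd * (mu / 20)^true$var_power)
  fit <- fit_height_model(
    data.frame(height = h, dbh = dbh, dg = dg, species = sp, plot_id = plot_id),
    min_obs = 50,
    fixed = list(beta_sp = true$beta_sp, gamma = true$gamma))
  expect_identical(unname(fit$beta_sp), unname(true$beta_sp[names(fit$beta_sp)]))
  expect_identical(fit$gamma, true$gamma)
  expect_lt(max(abs(fit$alpha_sp / true$alpha_sp - 1)), 0.1)
  # the fitted population-level curve tracks the truth
  grid <- expand.grid(dbh = c(15, 30, 45), dg = c(15, 30, 45))
  for (s in c("A", "B")) {
    ph <- predict_height(grid$dbh, grid$dg, rep(s, nrow(grid)), fit)
    th <- predict_height(grid$dbh, grid$dg, rep(s, nrow(grid)), true)
    expect_lt(max(abs(ph / th - 1)), 0.05)
  }
})

test_that("near-noiseless data gives near-exact recovery", {
  set.seed(53)
  true <- height_params(alpha_sp = c(A = 42), beta_sp = c(A = 1.5),
                        alpha1 = 0.018, alpha2 = 1.2, gamma = 1.45)
  np <- 30; nt <- 15
  plot_id <- rep(seq_len(np), each = nt)
  dg <- rep(seq(10, 55, length.out = np), each = nt)
  dbh <- pmax(5, dg * rlnorm(np * nt, 0, 0.3))
  mu <- predict_height(dbh, dg, rep("A", np * nt), true)
  h <- mu + rnorm(np * nt, 0, 1e-4)
  fit <- fit_height_model(
    data.frame(height = h, dbh = dbh, dg = dg, species = "A",
               plot_id = plot_id), min_obs = 10)
  expect_lt(abs(fit$alpha_sp[["A"]] - 42), 0.1)
  expect_lt(fit$resid_sd, 0.01)
})

test_that("assigned heights are deterministic and cell-Dg-consistent", {
  tt <- data.frame(cellID25 = c(1, 1, 1, 2), sp = c("Fa.sy.", "Fa.sy.", "Pi.ab.", "Fa.sy."),
                   n = c(2L, 1L, 1L, 3L), dbh = c(20, 30, 40, 25))
  b <- published_height_params("bauges")
  out <- assign_heights(tt, b)
  dg1 <- sqrt(sum(tt$n[1:3] * tt$dbh[1:3]^2) / sum(tt$n[1:3]))
  expect_equal(out$h[1], predict_height(20, dg1, "Fa.sy.", b))
  expect_equal(out$h[4], predict_height(25, 25, "Fa.sy.", b))
  # same-species heights are monotone in dbh within a cell
  expect_true(out$h[2] > out$h[1])
  # empty table passes through
  empty <- assign_heights(tt[0, ], b)
  expect_equal(nrow(empty), 0)
})
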