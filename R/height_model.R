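#' Predict tree height from diameter and stand quadratic mean diameter
#'
#' Evaluates the asymptotic species-specific diameter-height model
#' \deqn{h = 1.3 + (1 + u) \alpha_{sp} (1 - e^{-\alpha_1 Dg^{\alpha_2}})
#'       (1 - e^{-\beta_{sp} \, dbh / Dg})^{\gamma}}
#' where the `dbh/Dg` ratio carries the tree's social status, the stand `Dg`
#' its development stage, and `u` is the plot/site random effect (0 for
#' population-level prediction). The curve passes through breast height
#' (h -> 1.3 m as dbh -> 0), increases monotonically in dbh and saturates at
#' `1.3 + alpha_sp * (1 - exp(-alpha1 * Dg^alpha2))`.
#'
#' @param dbh Tree diameter at breast height (cm, > 0); vectorised.
#' @param dg Stand quadratic mean diameter (cm, > 0); scalar or vector.
#' @param species Species codes; unknown codes use the `OtherSp.` row when
#'   the parameter set has one, otherwise an error is raised.
#' @param params A `height_params` object.
#' @param site_effect Random-effect value `u`, default 0.
#' @return Predicted total heights (m).
#' @export
predict_height <- function(dbh, dg, species, params, site_effect = 0) {
  stopifnot(inherits(params, "height_params"), all(dbh > 0), all(dg > 0))
  sp <- as.character(species)
  known <- sp %in% names(params$alpha_sp)
  if (!all(known)) {
    if ("OtherSp." %in% names(params$alpha_sp)) {
      sp[!known] <- "OtherSp."
    } else {
      stop("species without height parameters and no OtherSp. row: ",
           paste(unique(sp[!known]), collapse = ", "), call. = FALSE)
    }
  }
  asp <- params$alpha_sp[sp]
  bsp <- params$beta_sp[sp]
  unname(1.3 + (1 + site_effect) * asp *
         (1 - exp(-params$alpha1 * dg^params$alpha2)) *
         (1 - exp(-bsp * dbh / dg))^params$gamma)
}

#' Fit the mixed-effects diameter-height model
#'
#' Fits the model of [predict_height()] by maximum likelihood with
#' [nlme::nlme()]: species-specific fixed effects `alpha_sp` and `beta_sp`,
#' shared `alpha1`, `alpha2`, `gamma`, a multiplicative plot-level random
#' effect `(1 + u)`, and residual errors heteroscedastic as a power of the
#' fitted values (`varPower`). Starting values come from a preliminary
#' fixed-effects `nls` fit (`port` algorithm, bounded), seeded with each
#' species' maximum observed height as the asymptote guess, `beta = 1.5`,
#' `gamma = 1.4`.
#'
#' Species with fewer than `min_obs` height observations are pooled into the
#' `OtherSp.` category before fitting. Passing `fixed` (named list with any
#' of `beta_sp`, `gamma`) freezes those parameters at the supplied values and
#' estimates only the remainder — the borrowing scheme used when a site's
#' height sample covers only dominant trees.
#'
#' @param data Data frame with columns `height` (m, > 1.3), `dbh` (cm),
#'   `dg` (stand quadratic mean diameter, cm), `species`, `plot_id`.
#' @param min_obs Minimum observations for a species-specific parameter pair,
#'   default 100.
#' @param fixed Optional named list: `beta_sp` (named vector covering every
#'   fitted species) and/or `gamma` to hold fixed.
#' @return A `height_params` object with a `fit` attribute carrying the
#'   `nlme` object and convergence information.
#' @export
fit_height_model <- function(data, min_obs = 100, fixed = NULL) {
  stopifnot(all(c("height", "dbh", "dg", "species", "plot_id") %in% names(data)))
  if (any(data$height <= 1.3)) stop("heights must exceed 1.3 m", call. = FALSE)
  d <- data.frame(h = data$height, dbh = data$dbh, dg = data$dg,
                  sp = as.character(data$species),
                  plot = factor(data$plot_id), stringsAsFactors = FALSE)
  counts <- table(d$sp)
  rare <- names(counts)[counts < min_obs]
  if (length(rare)) d$sp[d$sp %in% rare] <- "OtherSp."
  d$sp <- factor(d$sp)
  species <- levels(d$sp)
  ns <- length(species)

  fix_beta <- !is.null(fixed$beta_sp)
  fix_gamma <- !is.null(fixed$gamma)
  if (fix_beta) {
    miss <- setdiff(species, names(fixed$beta_sp))
    if (length(miss)) stop("fixed beta_sp misses species: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    d$bfix <- fixed$beta_sp[as.character(d$sp)]
  }
  if (fix_gamma) d$gfix <- fixed$gamma

  # indicator columns for the nls starting fit
  for (i in seq_len(ns)) d[[paste0(".i", i)]] <- as.numeric(d$sp == species[i])
  asum <- function(pfx) paste(sprintf("%s%d*.i%d", pfx, seq_len(ns), seq_len(ns)),
                              collapse = "+")
  bterm <- if (fix_beta) "bfix" else paste0("(", asum("bsp"), ")")
  gterm <- if (fix_gamma) "gfix" else "gg"
  nls_form <- stats::as.formula(paste0(
    "h ~ 1.3 + (", asum("asp"), ")*(1-exp(-pa1*dg^pa2))*",
    "(1-exp(-", bterm, "*dbh/dg))^", gterm))
  start <- c(stats::setNames(as.numeric(tapply(d$h, d$sp, max)) * 1.1,
                             paste0("asp", seq_len(ns))),
             pa1 = 0.02, pa2 = 1.1)
  lower <- c(rep(5, ns), 1e-4, 0.3)
  upper <- c(rep(120, ns), 0.5, 3)
  if (!fix_beta) {
    start <- c(start, stats::setNames(rep(1.5, ns), paste0("bsp", seq_len(ns))))
    lower <- c(lower, rep(0.2, ns)); upper <- c(upper, rep(6, ns))
  }
  if (!fix_gamma) {
    start <- c(start, gg = 1.4)
    lower <- c(lower, 0.5); upper <- c(upper, 4)
  }
  pre <- stats::nls(nls_form, data = d, start = as.list(start),
                    algorithm = "port", lower = lower, upper = upper,
                    control = stats::nls.control(maxiter = 500, warnOnly = TRUE))
  cf <- stats::coef(pre)

  # nlme fit with the multiplicative plot-level random effect
  sp_form <- if (ns > 1) "~ sp - 1" else "~ 1"
  fx <- list()
  fx$asp <- stats::as.formula(paste("asp", sp_form))
  if (!fix_beta) fx$bsp <- stats::as.formula(paste("bsp", sp_form))
  fx <- c(fx, list(stats::as.formula(
    paste("a1 + a2", if (!fix_gamma) "+ g" else "", "~ 1"))))
  model_rhs <- paste0(
    "1.3 + (1+uu)*asp*(1-exp(-a1*dg^a2))*(1-exp(-",
    if (fix_beta) "bfix" else "bsp", "*dbh/dg))^",
    if (fix_gamma) "gfix" else "g")
  nlme_start <- c(cf[paste0("asp", seq_len(ns))],
                  if (!fix_beta) cf[paste0("bsp", seq_len(ns))],
                  cf["pa1"], cf["pa2"],
                  if (!fix_gamma) cf["gg"])
  fit <- nlme::nlme(
    stats::as.formula(paste("h ~", model_rhs)),
    fixed = fx,
    random = uu ~ 1 | plot,
    start = unname(nlme_start),
    data = d,
    weights = nlme::varPower(form = ~fitted(.)),
    method = "ML",
    control = nlme::nlmeControl(maxIter = 300, msMaxIter = 300,
                                pnlsTol = 1e-3, returnObject = TRUE)
  )
  fe <- nlme::fixef(fit)
  fe_names <- function(pfx) if (ns > 1) paste0(pfx, ".sp", species) else pfx
  alpha_sp <- stats::setNames(fe[fe_names("asp")], species)
  beta_sp <- if (fix_beta) fixed$beta_sp[species]
             else stats::setNames(fe[fe_names("bsp")], species)
  out <- height_params(
    alpha_sp = alpha_sp,
    beta_sp = stats::setNames(beta_sp, species),
    alpha1 = unname(fe["a1"]), alpha2 = unname(fe["a2"]),
    gamma = if (fix_gamma) fixed$gamma else unname(fe["g"]),
    var_power = as.numeric(stats::coef(fit$modelStruct$varStruct)),
    re_sd = as.numeric(nlme::VarCorr(fit)[1, "StdDev"]),
    resid_sd = fit$sigma,
    borrowed = if (fix_beta || fix_gamma)
      list(from = "fixed", params = c(if (fix_beta) "beta_sp",
                                      if (fix_gamma) "gamma"))
  )
  attr(out, "fit") <- fit
  out
}

#' Assign heights to a generated tree table
#'
#' Computes each cell's quadratic mean diameter from its generated tree list
#' (weights `n`) and predicts every tree's height with the population-level
#' diameter-height model (`site_effect = 0`), so the output is deterministic.
#' Optional residual noise (sd proportional to `fitted^var_power`) can be
#' added for stochastic applications.
#'
#' @param tree_table Data frame `cellID25`, `sp`, `n`, `dbh` as produced by
#'   [generate_landscape()].
#' @param params A `height_params` object.
#' @param add_noise Add varPower residual noise? Default `FALSE`.
#' @return The table with an added `h` column (m).
#' @export
assign_heights <- function(tree_table, params, add_noise = FALSE) {
  if (nrow(tree_table) == 0) {
    tree_table$h <- numeric(0)
    return(tree_table)
  }
  dg2 <- tapply(tree_table$n * tree_table$dbh^2, tree_table$cellID25, sum) /
    tapply(tree_table$n, tree_table$cellID25, sum)
  dg_cell <- sqrt(dg2)[as.character(tree_table$cellID25)]
  h <- predict_height(tree_table$dbh, as.numeric(dg_cell), tree_table$sp, params)
  if (add_noise) {
    scale <- params$resid_sd * abs(h)^params$var_power
    h <- pmax(1.31, h + stats::rnorm(length(h), 0, scale))
  }
  tree_table$h <- h
  tree_table
}
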