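#' Root mean square error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Stem-weighted quantile
#'
#' Left-continuous inverse of the weighted empirical distribution function:
#' the smallest data value whose cumulative weight share reaches the target
#' probability. Used for the diameter and height quantile comparisons, with
#' per-hectare weights on the observed side and integer cell weights on the
#' generated side.
#'
#' @param x Values.
#' @param w Positive weights.
#' @param probs Probabilities in \[0, 1\].
#' @return Quantile values.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Dominant height of a generated cell
#'
#' The mean height of the six highest trees of the cell, a tree row with
#' count `n` contributing `n` copies; with fewer than six trees the mean of
#' all of them. Mirrors the ALS-side dominant height computed from CHM local
#' maxima ([hdom_als()]).
#'
#' @param cell_trees Data frame with columns `h` and `n`.
#' @return Dominant height (m) or `NA_real_` for an empty cell.
#' @export
hdom_t <- function(cell_trees) {
  if (is.null(cell_trees) || nrow(cell_trees) == 0) return(NA_real_)
  h <- rep(cell_trees$h, cell_trees$n)
  k <- min(6L, length(h))
  mean(sort(h, decreasing = TRUE)[seq_len(k)])
}

#' Compare generated and ALS dominant heights
#'
#' Ordinary least squares of the tree-list dominant height on the ALS
#' dominant height, with R-squared and RMSE. Note that this comparison has
#' some circularity when the stand-variable models include height metrics,
#' so it must be interpreted with caution (the returned `caveat` restates
#' this).
#'
#' @param hdom_als_values Per-cell ALS dominant heights.
#' @param hdom_t_values Paired per-cell generated-tree dominant heights.
#' @return List with `r_squared`, `rmse`, `slope`, `intercept`, `n`,
#'   `caveat`.
#' @export
hdom_comparison <- function(hdom_als_values, hdom_t_values) {
  ok <- !is.na(hdom_als_values) & !is.na(hdom_t_values)
  x <- hdom_als_values[ok]; y <- hdom_t_values[ok]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(
    r_squared = suppressWarnings(summary(fit)$r.squared),
    rmse = rmse(x, y),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x),
    caveat = paste("ALS metrics entering the stand-variable models may",
                   "correlate with the ALS dominant height; interpret with",
                   "caution.")
  )
}

#' Species abundance comparison at the landscape level
#'
#' Total basal area per species in the observed plots versus the generated
#' cells, optionally restricted to trees above a dbh floor (as when small
#' trees were only tallied by class in the field). Pseudo-species rows
#' marking counted-but-not-measured classes are excluded.
#'
#' @param observed Data frame of observed trees: `species`, `dbh`, `weight`
#'   (per-ha) columns.
#' @param generated Data frame of generated trees: `sp`, `dbh`, `n` columns
#'   (per-cell counts).
#' @param dbh_min Optional dbh floor (cm) applied to both sides.
#' @param classes Species classification table (for the pseudo-species flag).
#' @return Data frame `species`, `observed_ba`, `generated_ba` (m^2, cell
#'   counts scaled by the 1/16 ha cell area).
#' @export
species_abundance <- function(observed, generated, dbh_min = NULL,
                              classes = default_species_classes()) {
  pseudo <- classes$species[classes$counted_class]
  obs <- observed[!(observed$species %in% pseudo), , drop = FALSE]
  gen <- generated[!(generated$sp %in% pseudo), , drop = FALSE]
  if (!is.null(dbh_min)) {
    obs <- obs[obs$dbh > dbh_min, , drop = FALSE]
    gen <- gen[gen$dbh > dbh_min, , drop = FALSE]
  }
  oba <- if (nrow(obs)) tapply(tree_basal_area(obs$dbh) * obs$weight,
                               obs$species, sum) else numeric(0)
  gba <- if (nrow(gen)) tapply(tree_basal_area(gen$dbh) * gen$n / 16,
                               gen$sp, sum) else numeric(0)
  species <- sort(union(names(oba), names(gba)))
  data.frame(
    species = species,
    observed_ba = as.numeric(oba[species]),
    generated_ba = as.numeric(gba[species]),
    row.names = NULL
  )
}

# most abundant species (by BA) of a tree list; ties broken by species code order
main_species <- function(species, ba) {
  tot <- tapply(ba, species, sum)
  names(tot)[order(-tot, names(tot))][1]
}

#' Frequency of correct main-species prediction
#'
#' Share of plot/cell pairs whose most abundant species (by basal area)
#' coincides. Ties are broken by species-code order.
#'
#' @param observed_list List of observed tree data frames (`species`, `dbh`,
#'   `weight`).
#' @param generated_list Paired list of generated tree data frames (`sp`,
#'   `dbh`, `n`).
#' @return Match frequency in percent.
#' @export
main_species_match <- function(observed_list, generated_list) {
  stopifnot(length(observed_list) == length(generated_list))
  ok <- 0L; n <- 0L
  for (i in seq_along(observed_list)) {
    obs <- observed_list[[i]]; gen <- generated_list[[i]]
    if (is.null(obs) || is.null(gen) || nrow(obs) == 0 || nrow(gen) == 0) next
    mo <- main_species(obs$species, tree_basal_area(obs$dbh) * obs$weight)
    mg <- main_species(gen$sp, tree_basal_area(gen$dbh) * gen$n)
    n <- n + 1L
    if (identical(mo, mg)) ok <- ok + 1L
  }
  if (n == 0) return(NA_real_)
  100 * ok / n
}

#' Leave-one-out cross-validation of the whole workflow
#'
#' For each field plot in turn: refit the stratified ALS models without it,
#' predict its BA, Dg and BA_b from its co-located metrics, remove it from
#' the matching pool, run the downscaling on the predicted triple, generate
#' trees and assign heights, and compare observed against generated values.
#' The held-out plot is never seen by either the model fits or the matching
#' pool. Reported are the RMSEs of BA, Dg, BA_b, the stem-weighted 95th
#' diameter percentile and (when observed heights exist) the 50th and 95th
#' height percentiles, plus the landscape-level species-abundance table and
#' the main-species match frequency. Folds whose generated stand is empty
#' (predicted BA at or below zero) enter the BA comparison with BA = 0;
#' their Dg, BA_b and quantiles are undefined and excluded from those
#' comparisons.
#'
#' With `refit_models = FALSE` the models are fitted once on all plots and
#' only the matching pool excludes the held-out plot (a faster variant).
#'
#' @param plots List of field plots ([split_plots()] layout); tree lists may
#'   carry a `height` column.
#' @param plot_metrics Data frame with one row per plot (same order):
#'   metric columns and `stratum`.
#' @param metric_cols Candidate metric column names.
#' @param height_params `height_params` object used for generated heights.
#' @param seed Integer seed for the rounding draws.
#' @param min_plots,transform,max_vars,exhaustive_limit Model-fit settings,
#'   see [fit_stratified()].
#' @param refit_models Refit the ALS models per fold? Default `TRUE`.
#' @param classes Species classification table.
#' @return List of class `validation_report`: `rmse` (named vector),
#'   `abundance`, `main_species_match_pct`, `model_rmse` (pure ALS-model
#'   LOOCV RMSEs for BA, Dg, BA_b), `n_folds`, `n_failed`.
#' @export
loocv_workflow <- function(plots, plot_metrics, metric_cols, height_params,
                           seed = 1L, min_plots = 30, transform = "none",
                           max_vars = 6, exhaustive_limit = 12,
                           refit_models = TRUE,
                           classes = default_species_classes()) {
  n <- length(plots)
  stopifnot(nrow(plot_metrics) == n)
  psum <- do.call(rbind, lapply(plots, function(p) {
    s <- stand_summary(p$trees, classes)
    data.frame(BA = s$BA, Dg = s$Dg, BA_b = s$BA_b)
  }))
  pdata <- cbind(psum, plot_metrics)

  fit_sets <- function(dat) {
    list(
      BA = fit_stratified(dat, "BA", metric_cols, min_plots = min_plots,
                          transform = transform, max_vars = max_vars,
                          exhaustive_limit = exhaustive_limit),
      Dg = fit_stratified(dat, "Dg", metric_cols, min_plots = min_plots,
                          transform = transform, max_vars = max_vars,
                          exhaustive_limit = exhaustive_limit),
      BA_b = fit_stratified(dat, "BA_b", metric_cols, min_plots = min_plots,
                            max_vars = max_vars,
                            exhaustive_limit = exhaustive_limit)
    )
  }
  all_sets <- if (!refit_models) fit_sets(pdata) else NULL

  obs <- pred <- matrix(NA_real_, n, 6,
                        dimnames = list(NULL, c("BA", "Dg", "BA_b",
                                                "dbhQ95", "hQ50", "hQ95")))
  gen_cells <- vector("list", n)
  failed <- 0L
  failure_messages <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sets <- if (refit_models) fit_sets(pdata[-i, , drop = FALSE]) else all_sets
      newd <- pdata[i, , drop = FALSE]
      cell <- list(BA = max(0, as.numeric(predict(sets$BA, newd))),
                   Dg = max(7.5, as.numeric(predict(sets$Dg, newd))),
                   BA_b = as.numeric(predict(sets$BA_b, newd)))
      pool <- plots[-i]
      pool_sum <- do.call(rbind, lapply(pool, function(p) {
        s <- stand_summary(p$trees, classes)
        data.frame(plot_id = p$plot_id, BA = s$BA, Dg = s$Dg, BA_b = s$BA_b,
                   forest_type = NA_character_, stringsAsFactors = FALSE)
      }))
      sc <- joint_minmax_scale(
        data.frame(BA = cell$BA, Dg = cell$Dg, BA_b = cell$BA_b),
        pool_sum[, c("BA", "Dg", "BA_b")])
      space <- cbind(sc$plots, plot_id = pool_sum$plot_id,
                     forest_type = pool_sum$forest_type)
      m <- match_plot(as.numeric(sc$cells[1, ]), space)
      matched <- pool[[which(pool_sum$plot_id == m$plot_id)[1]]]
      gen <- with_local_seed(cell_seed(seed, i),
                             generate_cell(cell, matched$trees, classes))
      gen$cellID25 <- rep(i, nrow(gen))
      gen <- assign_heights(gen, height_params)
      list(cell = cell, gen = gen)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed <- failed + 1L
      failure_messages <- c(failure_messages, paste0("fold ", i, ": ", res))
      next
    }
    gen <- res$gen
    gen_cells[[i]] <- gen
    s_obs <- stand_summary(plots[[i]]$trees, classes)
    obs[i, 1:3] <- c(s_obs$BA, s_obs$Dg, s_obs$BA_b)
    if (nrow(gen)) {
      s_gen <- stand_summary(
        data.frame(species = gen$sp, dbh = gen$dbh, weight = gen$n * 16),
        classes)
      pred[i, 1:3] <- c(s_gen$BA, s_gen$Dg, s_gen$BA_b)
    } else {
      # an empty generated stand has BA 0, but its Dg and BA_b are
      # undefined and excluded from those comparisons
      pred[i, "BA"] <- 0
    }
    if (nrow(gen)) {
      obs[i, "dbhQ95"] <- weighted_quantile(plots[[i]]$trees$dbh,
                                            plots[[i]]$trees$weight, 0.95)
      pred[i, "dbhQ95"] <- weighted_quantile(gen$dbh, gen$n, 0.95)
      if ("height" %in% names(plots[[i]]$trees) &&
          !anyNA(plots[[i]]$trees$height)) {
        oq <- weighted_quantile(plots[[i]]$trees$height,
                                plots[[i]]$trees$weight, c(0.5, 0.95))
        gq <- weighted_quantile(gen$h, gen$n, c(0.5, 0.95))
        obs[i, c("hQ50", "hQ95")] <- oq
        pred[i, c("hQ50", "hQ95")] <- gq
      }
    }
  }

  rmse_vec <- vapply(colnames(obs), function(v) {
    ok <- !is.na(obs[, v]) & !is.na(pred[, v])
    if (!any(ok)) return(NA_real_)
    rmse(obs[ok, v], pred[ok, v])
  }, numeric(1))

  model_rmse <- c(
    BA = loocv_rmse(pdata, "BA", metric_cols, min_plots = min_plots,
                    transform = transform, max_vars = max_vars,
                    exhaustive_limit = exhaustive_limit)$rmse,
    Dg = loocv_rmse(pdata, "Dg", metric_cols, min_plots = min_plots,
                    transform = transform, max_vars = max_vars,
                    exhaustive_limit = exhaustive_limit)$rmse,
    BA_b = loocv_rmse(pdata, "BA_b", metric_cols, min_plots = min_plots,
                      max_vars = max_vars,
                      exhaustive_limit = exhaustive_limit)$rmse
  )

  obs_list <- lapply(plots, `[[`, "trees")
  all_gen <- do.call(rbind, gen_cells[!vapply(gen_cells, is.null, logical(1))])
  structure(list(
    rmse = rmse_vec,
    model_rmse = model_rmse,
    abundance = species_abundance(
      do.call(rbind, obs_list),
      if (is.null(all_gen)) data.frame(sp = character(0), dbh = numeric(0),
                                       n = integer(0)) else all_gen,
      classes = classes),
    main_species_match_pct = main_species_match(obs_list, gen_cells),
    observed = obs, predicted = pred,
    n_folds = n, n_failed = failed,
    failure_messages = failure_messages
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Whole-workflow leave-one-out cross-validation\n")
  cat("  folds:", x$n_folds, " failed:", x$n_failed, "\n  RMSE:\n")
  print(round(x$rmse, 3))
  cat("  ALS-model LOOCV RMSE (BA, Dg, BA_b):\n")
  print(round(x$model_rmse, 3))
  cat("  main species matched:",
      round(x$main_species_match_pct, 1), "%\n")
  invisible(x)
}
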