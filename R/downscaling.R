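#' Joint min-max scaling of the matching space
#'
#' Scales BA, Dg and BA_b of the raster cells and the field plots jointly to
#' \[0, 1\], so the two sets share a common range in each coordinate of the
#' three-dimensional matching space. A coordinate that is constant over the
#' joint set maps to 0 everywhere.
#'
#' @param cells Data frame of cell summaries with columns `BA`, `Dg`, `BA_b`.
#' @param plots Data frame of plot summaries with the same columns.
#' @return List with `cells`, `plots` (same rows, scaled columns) and
#'   `ranges` (2 x 3 matrix of joint minima and maxima).
#' @export
joint_minmax_scale <- function(cells, plots) {
  stopifnot(nrow(cells) >= 1, nrow(plots) >= 1)
  vars <- c("BA", "Dg", "BA_b")
  ranges <- sapply(vars, function(v) range(c(cells[[v]], plots[[v]])))
  rownames(ranges) <- c("min", "max")
  scale1 <- function(df) {
    for (v in vars) {
      lo <- ranges["min", v]; hi <- ranges["max", v]
      df[[v]] <- if (hi > lo) (df[[v]] - lo) / (hi - lo) else 0
    }
    df
  }
  list(cells = scale1(cells), plots = scale1(plots), ranges = ranges)
}

#' Nearest-plot matching in the scaled stand-variable space
#'
#' Associates a cell with the field plot at minimal Euclidean distance in the
#' scaled (BA, Dg, BA_b) space. When a forest type is supplied, only plots of
#' that type are candidates; if none exists the match falls back to the full
#' pool with a warning. Equidistant plots are resolved to the smallest
#' `plot_id`, making the match deterministic.
#'
#' @param cell Numeric vector of length 3: the cell's scaled (BA, Dg, BA_b).
#' @param plot_space Data frame of scaled plot summaries with columns `BA`,
#'   `Dg`, `BA_b`, `plot_id` and optionally `forest_type`.
#' @param forest_type Optional forest-type label constraining the candidates.
#' @return List with `plot_id` and `distance`.
#' @export
match_plot <- function(cell, plot_space, forest_type = NULL) {
  cand <- plot_space
  if (!is.null(forest_type) && !is.na(forest_type)) {
    sel <- !is.na(cand$forest_type) & cand$forest_type == forest_type
    if (any(sel)) {
      cand <- cand[sel, , drop = FALSE]
    } else {
      warning("no plot of forest type '", forest_type,
              "'; matching against all plots", call. = FALSE)
    }
  }
  if (nrow(cand) == 0) stop("empty matching pool", call. = FALSE)
  d <- sqrt((cand$BA - cell[1])^2 + (cand$Dg - cell[2])^2 +
            (cand$BA_b - cell[3])^2)
  best <- which(d <= min(d) + 1e-12)
  pick <- best[order(cand$plot_id[best])][1]
  list(plot_id = cand$plot_id[pick], distance = d[pick])
}

#' Diameter correction coefficient
#'
#' The multiplier `alpha = Dg_ALS / Dg_F` applied to every tree diameter of
#' the matched field plot, so that the plot's quadratic mean diameter reaches
#' the cell's ALS-predicted value exactly.
#'
#' @param dg_als Cell Dg from the ALS mapping (cm, > 0).
#' @param dg_f Field-plot Dg (cm, > 0).
#' @return The scalar multiplier.
#' @export
alpha_dg <- function(dg_als, dg_f) {
  if (any(dg_f <= 0)) stop("field-plot Dg must be > 0 (empty plots must not be matched)", call. = FALSE)
  if (any(dg_als <= 0)) stop("cell Dg must be > 0", call. = FALSE)
  dg_als / dg_f
}

#' Per-tree target basal area
#'
#' Splits the cell's ALS-predicted basal area down to each tree of the
#' matched plot through three nested proportions:
#' `ba_tree = BA_ALS * Prop_BC * Prop_Sp * Prop_tree`, where `Prop_BC` is the
#' cell's broadleaf (resp. coniferous) BA share, `Prop_Sp` the species' BA
#' share within its class on the plot, and `Prop_tree` the tree's BA share
#' within its species. The targets sum to `BA_ALS` exactly whenever both
#' classes are represented on the plot.
#'
#' When the cell assigns positive BA to a class absent from the matched plot,
#' that share is reallocated to the available class (with a warning), keeping
#' the total exact.
#'
#' @param ba_als Cell total BA (m^2/ha).
#' @param bab_als Cell broadleaf BA proportion in \[0, 1\].
#' @param trees Matched plot's tree list (`species`, `dbh`, `weight`).
#' @param classes Species classification table.
#' @return Numeric vector of per-tree target basal areas (m^2/ha), aligned
#'   with `trees` rows.
#' @export
tree_target_ba <- function(ba_als, bab_als, trees, classes = default_species_classes()) {
  stopifnot(nrow(trees) >= 1, ba_als >= 0, bab_als >= 0, bab_als <= 1)
  broad <- species_broadleaf(trees$species, classes)
  ba <- tree_basal_area(trees$dbh) * trees$weight
  class_share <- ifelse(broad, bab_als, 1 - bab_als)
  # reallocate a missing class's share to the other class
  if (!any(broad) && bab_als > 0) {
    warning("cell assigns broadleaf BA but matched plot has no broadleaf tree; reallocating to conifers", call. = FALSE)
    class_share <- rep(1, nrow(trees))
  }
  if (all(broad) && bab_als < 1) {
    if (bab_als > 0 || ba_als > 0)
      warning("cell assigns coniferous BA but matched plot has no conifer; reallocating to broadleaves", call. = FALSE)
    class_share <- rep(1, nrow(trees))
  }
  class_ba <- ifelse(broad, sum(ba[broad]), sum(ba[!broad]))
  sp_ba <- stats::ave(ba, trees$species, FUN = sum)
  prop_sp <- sp_ba / class_ba
  prop_tree <- ba / sp_ba
  ba_als * class_share * prop_sp * prop_tree
}

#' Continuous per-hectare weight of a transformed tree
#'
#' The stem density (stems/ha) at which trees of corrected diameter
#' `alpha * dbh_F` reach the target basal area:
#' `omega = 40000 / pi * ba_tree / (alpha * dbh_F)^2`.
#'
#' @param ba_tree Per-tree target basal area (m^2/ha).
#' @param alpha Diameter correction coefficient.
#' @param dbh_f Field-plot dbh (cm).
#' @return Weight in stems/ha.
#' @export
continuous_weight <- function(ba_tree, alpha, dbh_f) {
  stopifnot(all(ba_tree >= 0), all(alpha > 0), all(dbh_f > 0))
  40000 / pi * ba_tree / (alpha * dbh_f)^2
}

#' Per-cell weight from a per-hectare weight
#'
#' Divides by 16, the surface-area ratio between 1 ha and a 25 x 25 m cell.
#' One fully enumerated tree on a 400 m^2 plot (25 stems/ha) always yields a
#' per-cell weight of 1.5625.
#'
#' @param omega Per-hectare weight (stems/ha, >= 0).
#' @return Stems per 25 x 25 m cell.
#' @export
cell_weight <- function(omega) {
  stopifnot(all(omega >= 0))
  omega / 16
}

#' Unbiased stochastic rounding of tree weights
#'
#' Rounds a (possibly fractional) per-cell weight to an integer by a
#' Bernoulli draw on its decimal part: a weight of 1.56 becomes 2 with
#' probability 0.56 and 1 with probability 0.44, so the expected integer
#' weight equals the continuous weight. Nearest-integer rounding would be
#' biased, because the decimal part is set by the plot-to-cell area ratio,
#' not by chance.
#'
#' Draws come from the R random number generator; seed the stream (or use
#' [generate_landscape()]'s per-cell substreams) for reproducibility.
#'
#' @param weight Non-negative per-cell weights.
#' @return Integer weights with `E[result] = weight`.
#' @export
bernoulli_round <- function(weight) {
  stopifnot(all(weight >= 0))
  base <- floor(weight)
  frac <- weight - base
  as.integer(base + stats::rbinom(length(weight), 1L, frac))
}

#' Final tree diameter after weight rounding
#'
#' Rounding the weights slightly changes the generated basal area, so the
#' diameters are transformed once more to reach the target exactly:
#' `dbh_final = sqrt(40000 / pi * ba_tree / (16 * omega_int))`. When the
#' integer weight equals the unrounded per-cell weight this reduces to
#' `alpha * dbh_F`, so the change is minor.
#'
#' @param ba_tree Per-tree target basal area (m^2/ha).
#' @param omega_int Integer per-cell weights (>= 1; zero-weight trees are
#'   dropped before this step).
#' @return Final diameters (cm) satisfying
#'   `16 * omega_int * tree_basal_area(dbh_final) == ba_tree`.
#' @export
final_dbh <- function(ba_tree, omega_int) {
  stopifnot(all(omega_int >= 1), all(ba_tree > 0))
  sqrt(40000 / pi * ba_tree / (16 * omega_int))
}

#' Generate the tree list of one cell
#'
#' Runs the full per-cell transformation of the matched plot: diameter
#' correction to the cell Dg, per-tree basal-area targets honouring the cell
#' BA and broadleaf share, continuous weights, Bernoulli rounding, and the
#' final diameter adjustment. Trees whose integer weight is 0 are dropped and
#' their basal area reported as lost (not redistributed).
#'
#' @param cell List or one-row data frame with `BA`, `Dg`, `BA_b` (the ALS
#'   predictions for the cell).
#' @param trees Matched plot's tree list (`species`, `dbh`, `weight`).
#' @param classes Species classification table.
#' @return Data frame with columns `sp`, `n` (integer >= 1), `dbh` (cm), one
#'   row per generated tree record, with attribute `lost_ba` (m^2/ha dropped
#'   with zero-weight trees).
#' @export
generate_cell <- function(cell, trees, classes = default_species_classes()) {
  if (cell$BA <= 0) {
    out <- data.frame(sp = character(0), n = integer(0), dbh = numeric(0))
    attr(out, "lost_ba") <- 0
    return(out)
  }
  stopifnot(nrow(trees) >= 1)
  dg_f <- stand_summary(trees, classes)$Dg
  a <- alpha_dg(cell$Dg, dg_f)
  ba_tree <- tree_target_ba(cell$BA, cell$BA_b, trees, classes)
  w <- continuous_weight(ba_tree, a, trees$dbh)
  wc <- cell_weight(w)
  wi <- bernoulli_round(wc)
  keep <- wi >= 1L
  lost <- sum(ba_tree[!keep])
  out <- data.frame(sp = trees$species[keep],
                    n = wi[keep],
                    dbh = if (any(keep)) final_dbh(ba_tree[keep], wi[keep]) else numeric(0),
                    stringsAsFactors = FALSE)
  attr(out, "lost_ba") <- lost
  out
}

# deterministic per-cell seed derived from the global seed and the cell id;
# keeps results independent of the order in which cells are processed.
cell_seed <- function(seed, cell_id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(cell_id) * 16807) %% 2147483629)
}

# run code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the tree lists of a whole landscape
#'
#' Matches every forest cell to its nearest field plot in the jointly scaled
#' (BA, Dg, BA_b) space (optionally constrained to plots of the same forest
#' type) and generates its tree list. Randomness is confined to the Bernoulli
#' weight rounding; each cell uses a private substream derived from the seed
#' and its `cellID25`, so the output is identical whatever the processing
#' order.
#'
#' @param cells Data frame with `cellID25`, `BA`, `Dg`, `BA_b` and optionally
#'   `forest_type`. Cells with `NA` or zero BA yield no trees.
#' @param plots List of field plots as produced by [split_plots()] (each with
#'   `plot_id`, `trees`, optional `forest_type`). Empty plots are excluded
#'   from the matching pool.
#' @param seed Integer seed for the rounding draws.
#' @param classes Species classification table.
#' @param use_forest_type Constrain matches to plots sharing the cell's
#'   forest type? Default `FALSE`.
#' @return List with `trees` (data frame `cellID25`, `sp`, `n`, `dbh`) and
#'   `diagnostics` (per cell: matched `plot_id`, `distance`, `lost_ba`).
#' @export
generate_landscape <- function(cells, plots, seed = 1L,
                               classes = default_species_classes(),
                               use_forest_type = FALSE) {
  plots <- Filter(function(p) nrow(p$trees) > 0, plots)
  stopifnot(length(plots) > 0)
  psum <- do.call(rbind, lapply(plots, function(p) {
    s <- stand_summary(p$trees, classes)
    data.frame(plot_id = p$plot_id, BA = s$BA, Dg = s$Dg, BA_b = s$BA_b,
               forest_type = if (is.null(p$forest_type)) NA_character_ else p$forest_type,
               stringsAsFactors = FALSE)
  }))
  live <- !is.na(cells$BA) & cells$BA > 0
  sc <- joint_minmax_scale(cells[, c("BA", "Dg", "BA_b")], psum)
  plot_space <- cbind(sc$plots, plot_id = psum$plot_id)
  plot_space$forest_type <- psum$forest_type
  by_id <- stats::setNames(plots, vapply(plots, function(p) as.character(p$plot_id), ""))

  res <- vector("list", nrow(cells))
  diag <- data.frame(cellID25 = cells$cellID25, plot_id = NA,
                     distance = NA_real_, lost_ba = NA_real_)
  for (i in which(live)) {
    ft <- if (use_forest_type && "forest_type" %in% names(cells))
            cells$forest_type[i] else NULL
    m <- match_plot(c(sc$cells$BA[i], sc$cells$Dg[i], sc$cells$BA_b[i]),
                    plot_space, forest_type = ft)
    plot <- by_id[[as.character(m$plot_id)]]
    gen <- with_local_seed(
      cell_seed(seed, cells$cellID25[i]),
      generate_cell(list(BA = cells$BA[i], Dg = cells$Dg[i],
                         BA_b = cells$BA_b[i]), plot$trees, classes)
    )
    diag$plot_id[i] <- m$plot_id
    diag$distance[i] <- m$distance
    diag$lost_ba[i] <- attr(gen, "lost_ba")
    if (nrow(gen)) {
      res[[i]] <- cbind(cellID25 = cells$cellID25[i], gen)
    }
  }
  trees <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(trees)) {
    trees <- data.frame(cellID25 = integer(0), sp = character(0),
                        n = integer(0), dbh = numeric(0))
  }
  rownames(trees) <- NULL
  list(trees = trees, diagnostics = diag)
}
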