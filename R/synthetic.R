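#' Configuration of the synthetic landscape generator
#'
#' Bundles the knobs of the self-consistent synthetic data used to exercise
#' the whole workflow without any acquisition: landscape size, stratification,
#' spatial smoothness of the true stand fields, plot sample size, the species
#' pool with broadleaf flags and relative abundances, the Weibull diameter
#' distribution, the diameter-height parameter set used to give plot trees
#' heights, and the noise levels tying the synthetic ALS metrics to the true
#' fields.
#'
#' Defaults emulate a mid-elevation mixed landscape: a 20 x 20 cell block
#' (25 ha), two acquisition strata, a calibration network of 300 plots of
#' roughly 18 trees (plot networks supporting area-based inventories number
#' in the hundreds of plots), BA centred near 30 m^2/ha, Dg spanning roughly
#' 12-45 cm, four species (beech, sessile oak, spruce, silver fir), a
#' Weibull(2) relative diameter distribution, and metric noise calibrated so
#' plot-level LOOCV RMSEs land near 6 m^2/ha for BA, 3-4 cm for Dg and
#' 10-15 percentage points for BA_b — the accuracy regime reported for
#' operational area-based inventories.
#'
#' @param nx,ny Landscape size in 25 m cells.
#' @param n_plots Number of field plots.
#' @param n_strata Number of acquisition strata (vertical bands).
#' @param smooth_passes Moving-average passes for spatial correlation.
#' @param species Species pool data frame (`species`, `broadleaf`,
#'   `abundance` summing to 1).
#' @param weibull_shape Shape of the relative diameter distribution.
#' @param trees_per_plot Nominal tree count per plot.
#' @param metric_noise_sd Gaussian sd added to the informative metrics.
#' @param height_params `height_params` set used for plot-tree heights.
#' @param height_noise Add varPower residual noise to plot heights?
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(nx = 20, ny = 20, n_plots = 300, n_strata = 2,
                             smooth_passes = 3,
                             species = data.frame(
                               species = c("Fa.sy.", "Qu.pe.", "Pi.ab.", "Ab.al."),
                               broadleaf = c(TRUE, TRUE, FALSE, FALSE),
                               abundance = c(0.35, 0.15, 0.3, 0.2),
                               stringsAsFactors = FALSE),
                             weibull_shape = 2,
                             trees_per_plot = 18,
                             metric_noise_sd = 0.3,
                             height_params = published_height_params("bauges"),
                             height_noise = TRUE) {
  stopifnot(abs(sum(species$abundance) - 1) < 1e-8, metric_noise_sd >= 0)
  structure(list(nx = nx, ny = ny, n_plots = n_plots, n_strata = n_strata,
                 smooth_passes = smooth_passes, species = species,
                 weibull_shape = weibull_shape,
                 trees_per_plot = trees_per_plot,
                 metric_noise_sd = metric_noise_sd,
                 height_params = height_params,
                 height_noise = height_noise),
            class = "synthetic_config")
}

# one smoothing pass: 3x3 moving average with edge replication
smooth_once <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
  }
  acc / 9
}

smooth_field <- function(m, passes) {
  for (k in seq_len(passes)) m <- smooth_once(m)
  m
}

#' Simulate spatially structured true stand fields
#'
#' Draws independent Gaussian white-noise grids, low-pass filters them with
#' repeated 3 x 3 moving averages (re-standardised), and maps them to the
#' three stand variables: BA around 30 m^2/ha, Dg around 27 cm and BA_b
#' squashed to (0, 1) through the logistic function. Strata are vertical
#' bands of the landscape. Deterministic under a fixed seed.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @return List with `cells` (data frame `cellID25`, `row`, `col`, `BA`,
#'   `Dg`, `BA_b`, `stratum`) and the field matrices.
#' @export
simulate_true_fields <- function(config, seed = 1L) {
  set.seed(seed)
  nx <- config$nx; ny <- config$ny
  zfield <- function() {
    z <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx),
                      config$smooth_passes)
    if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
  }
  BA <- pmax(30 + 9 * zfield(), 5)
  Dg <- pmin(pmax(27 + 7 * zfield(), 12), 45)
  BA_b <- stats::plogis(1.1 * zfield())
  stratum <- matrix(paste0("S", pmin(config$n_strata,
                                     1 + (col(BA) - 1) %/%
                                       ceiling(nx / config$n_strata))),
                    ny, nx)
  cells <- data.frame(
    cellID25 = seq_len(ny * nx),
    row = as.vector(row(BA)), col = as.vector(col(BA)),
    BA = as.vector(BA), Dg = as.vector(Dg), BA_b = as.vector(BA_b),
    stratum = as.vector(stratum), stringsAsFactors = FALSE
  )
  list(cells = cells, BA = BA, Dg = Dg, BA_b = BA_b, stratum = stratum)
}

#' Simulate one field plot matching a target stand summary
#'
#' Draws relative diameters from the configured Weibull distribution,
#' assigns species (broadleaf trees according to the target BA_b, species
#' within class by their configured abundances), then applies three exact
#' closed-form rescalings: class-wise weight scaling fixes the broadleaf BA
#' share, a global diameter scaling fixes Dg (preserving the share), and a
#' global weight scaling fixes total BA (preserving both). The realized
#' summary therefore matches the target triple up to floating-point error.
#'
#' @param target List or row with `BA` (> 0), `Dg`, `BA_b`.
#' @param config A `synthetic_config`.
#' @return Tree data frame (`species`, `dbh`, `weight`).
#' @export
simulate_plot <- function(target, config) {
  stopifnot(target$BA > 0, target$Dg > 0)
  n <- config$trees_per_plot
  rel <- stats::rweibull(n, shape = config$weibull_shape, scale = 1)
  rel <- pmax(rel, 0.2)
  dbh <- rel * target$Dg / sqrt(mean(rel^2))   # Dg of equal-weight list = target
  spp <- config$species
  broad <- stats::rbinom(n, 1, target$BA_b) == 1
  if (target$BA_b > 0 && !any(broad)) broad[sample.int(n, 1)] <- TRUE
  if (target$BA_b < 1 && all(broad)) broad[sample.int(n, 1)] <- FALSE
  pick <- function(class_broad) {
    pool <- spp[spp$broadleaf == class_broad, , drop = FALSE]
    sample(pool$species, sum(broad == class_broad), replace = TRUE,
           prob = pool$abundance)
  }
  species <- character(n)
  if (any(broad)) species[broad] <- pick(TRUE)
  if (any(!broad)) species[!broad] <- pick(FALSE)
  w <- rep(1, n)
  ba <- tree_basal_area(dbh) * w
  # class-wise weight scaling -> exact broadleaf share
  if (any(broad) && any(!broad) && target$BA_b > 0 && target$BA_b < 1) {
    w[broad] <- w[broad] * target$BA_b / sum(ba[broad])
    w[!broad] <- w[!broad] * (1 - target$BA_b) / sum(ba[!broad])
  }
  # diameter scaling -> exact Dg (shares preserved)
  dg_now <- sqrt(sum(w * dbh^2) / sum(w))
  dbh <- dbh * target$Dg / dg_now
  # uniform weight scaling -> exact BA (Dg and shares preserved)
  ba_now <- sum(tree_basal_area(dbh) * w)
  w <- w * target$BA / ba_now
  data.frame(species = species, dbh = dbh, weight = w,
             stringsAsFactors = FALSE)
}

#' Simulate field plots over the landscape
#'
#' Samples plot locations (one cell each, without replacement), generates a
#' tree list per plot matching the cell's true stand triple with
#' [simulate_plot()], and assigns heights with the configured
#' diameter-height parameters (varPower residual noise when
#' `config$height_noise`).
#'
#' @param fields Output of [simulate_true_fields()].
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @return List of plots in the [split_plots()] layout, each additionally
#'   carrying `cellID25` (its location).
#' @export
simulate_plots <- function(fields, config, seed = 1L) {
  set.seed(seed)
  cells <- fields$cells
  loc <- sample(nrow(cells), config$n_plots)
  plots <- vector("list", config$n_plots)
  for (k in seq_len(config$n_plots)) {
    i <- loc[k]
    trees <- simulate_plot(cells[i, ], config)
    dg <- sqrt(sum(trees$weight * trees$dbh^2) / sum(trees$weight))
    h <- predict_height(trees$dbh, dg, trees$species, config$height_params)
    if (config$height_noise) {
      hp <- config$height_params
      h <- pmax(1.31, h + stats::rnorm(length(h),
                                       0, hp$resid_sd * abs(h)^hp$var_power))
    }
    trees$height <- h
    plots[[k]] <- list(plot_id = k, trees = trees,
                       stratum = cells$stratum[i],
                       forest_type = NA_character_,
                       cellID25 = cells$cellID25[i])
  }
  names(plots) <- as.character(seq_len(config$n_plots))
  plots
}

#' Simulate per-cell ALS metrics from the true fields
#'
#' Each informative metric is a stratum-specific monotone function of one
#' true stand variable plus Gaussian noise, so the prediction models can
#' recover the inverse relation: `m_h` responds to Dg (a height-percentile
#' surrogate), `m_d` to log BA (a density surrogate), `m_c` to the broadleaf
#' logit (a cover/intensity surrogate). Two pure-noise metrics are appended
#' so subset selection has something to discard. Noise sd is
#' `config$metric_noise_sd` on the standardised scale of each metric.
#'
#' @param fields Output of [simulate_true_fields()].
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @return Data frame `cellID25`, `stratum`, metrics `m_h`, `m_d`, `m_c`,
#'   `m_n1`, `m_n2`.
#' @export
simulate_metrics <- function(fields, config, seed = 1L) {
  set.seed(seed + 1L)
  cells <- fields$cells
  n <- nrow(cells)
  sidx <- as.integer(factor(cells$stratum))
  nz <- function() stats::rnorm(n, 0, config$metric_noise_sd)
  m_h <- (0.6 + 0.1 * sidx) * cells$Dg / 10 + nz()
  m_d <- (0.8 + 0.15 * sidx) * log(cells$BA) + nz()
  m_c <- 0.5 * stats::qlogis(pmin(pmax(cells$BA_b, 1e-4), 1 - 1e-4)) +
    0.2 * sidx + nz()
  data.frame(cellID25 = cells$cellID25, stratum = cells$stratum,
             m_h = m_h, m_d = m_d, m_c = m_c,
             m_n1 = stats::rnorm(n), m_n2 = stats::rnorm(n),
             stringsAsFactors = FALSE)
}

#' Simulate a canopy height model for one cell's tree list
#'
#' Renders each tree as a cone whose apex equals the tree height, placed on
#' a regular lattice with enforced spacing so crowns of the tallest trees do
#' not overlap; the CHM's local maxima then equal the tree heights exactly.
#' When the cell holds more trees than lattice positions, overlap is allowed
#' and flagged.
#'
#' @param heights Tree heights (m), one per rendered stem.
#' @param cell_size Cell edge length in m, default 25.
#' @param resolution CHM resolution in m, default 1.
#' @param crown_radius Cone base radius in m, default 2.
#' @return Height matrix with attribute `overlap` (logical).
#' @export
simulate_chm <- function(heights, cell_size = 25, resolution = 1,
                         crown_radius = 2) {
  npix <- ceiling(cell_size / resolution)
  chm <- matrix(0, npix, npix)
  if (length(heights) == 0) {
    attr(chm, "overlap") <- FALSE
    return(chm)
  }
  step <- ceiling(2 * crown_radius / resolution) + 2
  pos <- expand.grid(
    row = seq(ceiling(step / 2) + 1, npix - ceiling(step / 2), by = step),
    col = seq(ceiling(step / 2) + 1, npix - ceiling(step / 2), by = step)
  )
  overlap <- length(heights) > nrow(pos)
  if (overlap) {
    pos <- expand.grid(row = seq(2, npix - 1, by = 2),
                       col = seq(2, npix - 1, by = 2))
  }
  k <- min(length(heights), nrow(pos))
  hs <- sort(heights, decreasing = TRUE)[seq_len(k)]
  rpix <- crown_radius / resolution
  for (j in seq_len(k)) {
    r0 <- pos$row[j]; c0 <- pos$col[j]
    for (dr in -ceiling(rpix):ceiling(rpix)) {
      for (dc in -ceiling(rpix):ceiling(rpix)) {
        rr <- r0 + dr; cc <- c0 + dc
        if (rr < 1 || rr > npix || cc < 1 || cc > npix) next
        d <- sqrt(dr^2 + dc^2)
        if (d > rpix) next
        val <- hs[j] * (1 - d / (rpix + 1))
        if (val > chm[rr, cc]) chm[rr, cc] <- val
      }
    }
  }
  attr(chm, "overlap") <- overlap
  chm
}
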