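# Shared in-code fixtures for the test suite. Everything is generated, no
# data files.

# a small mixed plot: two conifers, two broadleaves, equal weights
mixed_plot_trees <- function() {
  data.frame(
    species = c("Pi.ab.", "Ab.al.", "Fa.sy.", "Qu.pe."),
    dbh = c(20, 30, 25, 35),
    weight = c(25, 25, 25, 25),
    stringsAsFactors = FALSE
  )
}

# random plot with both classes present, for property-style loops
random_plot_trees <- function(n = 8) {
  sp <- sample(c("Pi.ab.", "Ab.al.", "Fa.sy.", "Qu.pe."), n, replace = TRUE)
  # force both classes
  sp[1] <- "Pi.ab."; sp[2] <- "Fa.sy."
  data.frame(
    species = sp,
    dbh = stats::runif(n, 10, 60),
    weight = stats::runif(n, 10, 60),
    stringsAsFactors = FALSE
  )
}

# a small synthetic landscape + plots + metrics, shared by slow tests
small_synth <- function(seed = 5, n_plots = 60, nx = 10, ny = 10) {
  cfg <- synthetic_config(nx = nx, ny = ny, n_plots = n_plots)
  fields <- simulate_true_fields(cfg, seed)
  plots <- simulate_plots(fields, cfg, seed)
  metrics <- simulate_metrics(fields, cfg, seed)
  pm <- metrics[match(vapply(plots, `[[`, 0, "cellID25"), metrics$cellID25), ]
  rownames(pm) <- NULL
  list(cfg = cfg, fields = fields, plots = plots, metrics = metrics, pm = pm,
       metric_cols = c("m_h", "m_d", "m_c", "m_n1", "m_n2"))
}

plot_summaries <- function(plots) {
  do.call(rbind, lapply(plots, function(p) as.data.frame(stand_summary(p$trees))))
}
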